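#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with known ground truth.
#
# Emulates the recording conditions of the capsaicin/analog experiments:
# saturating single-channel traces (+80 mV, 10 kHz sampling, 2.9 kHz
# filter corner), wild-type and reduced-Po_max (I574A-like) concentration-
# response tables, tail currents for OFF-rate fitting, and bi-ionic
# voltage-ramp currents. Everything downstream (stages 02-06) consumes
# only these files.

suppressPackageStartupMessages(library(trpv1ruler))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Study conditions. Potencies and Hill slopes are the published wild-type
# and I574A values; Po_max 0.94 at saturation; the short analog carries a
# ~10% smaller unitary conductance. Mean open dwell (10 ms) and the OFF
# time constants (analogs unbind 2-6x faster than capsaicin) are fixture
# choices on the scale of the recordings.
ligands <- data.frame(
  ligand   = c("cap", "cap_m1", "cap_p1"),
  ec50_wt  = c(0.14, 0.10, 4.31),
  hill_wt  = c(1.82, 1.20, 1.44),
  ec50_i574a = c(0.22, 2.80, 10.73),
  po_max   = c(0.94, 0.94, 0.94),
  g_pS     = c(100, 90, 100),
  tau_off_ms = c(60, 20, 12),
  sat_conc_uM = c(10, 10, 100))
write.csv(ligands, file.path(out, "study_conditions.csv"), row.names = FALSE)

message("single-channel traces at saturating agonist (20 s each) ...")
close_rate <- 0.1                      # 10 ms mean open dwell
for (i in seq_len(nrow(ligands))) {
  lg <- ligands[i, ]
  L <- lg$po_max / (1 - lg$po_max)
  model <- channel_model(K_D = lg$ec50_wt * (1 + L), L = L,
                         g = lg$g_pS, E_rev = 0)
  amp <- lg$g_pS * 80 / 1000
  sim <- simulate_single_channel(model, open_rate = close_rate * L,
                                 close_rate = close_rate, duration = 2e4,
                                 voltage = 80, noise_sd = 0.15 * amp,
                                 seed = seed + i)
  write_recording(sim$recording,
                  file.path(out, sprintf("sc_%s.tsv", lg$ligand)))
  write.table(sim$dwells, file.path(out, sprintf("sc_%s_truth.tsv", lg$ligand)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message("concentration-response tables (wild-type and reduced-Po_max) ...")
for (i in seq_len(nrow(ligands))) {
  lg <- ligands[i, ]
  cc <- exp(seq(log(lg$ec50_wt / 30), log(lg$ec50_wt * 100),
                length.out = 9))
  set.seed(seed + 10 + i)
  resp <- pmax(hill_response(cc, lg$ec50_wt, lg$hill_wt, lg$po_max) +
                 rnorm(9, 0, 0.02), 0)
  write_dose_response(dose_response_curve(cc, resp, se = 0.02, n = 5L),
                      file.path(out, sprintf("dr_wt_%s.csv", lg$ligand)))
  # reduced-Po_max background: three-state with L = 1, K_D = 2 * EC50
  m <- channel_model(K_D = lg$ec50_i574a * 2, L = 1)
  crv <- simulate_dose_response(
    m, exp(seq(log(lg$ec50_i574a / 30), log(lg$ec50_i574a * 100),
               length.out = 9)),
    noise_sd = 0.03, seed = seed + 20 + i)
  crv$response <- pmax(crv$response, 0)
  write_dose_response(crv, file.path(out, sprintf("dr_i574a_%s.csv", lg$ligand)))
}

message("tail currents for OFF-rate fitting ...")
for (i in seq_len(nrow(ligands))) {
  lg <- ligands[i, ]
  tl <- simulate_tail_current(amplitude = 200, tau = lg$tau_off_ms,
                              duration = 8 * lg$tau_off_ms,
                              noise_sd = 4, seed = seed + 30 + i)
  write_recording(tl, file.path(out, sprintf("tail_%s.tsv", lg$ligand)))
}

message("bi-ionic voltage ramps (140 Na out vs 70 Ca or Mg in) ...")
# relative permeabilities: divalent-over-sodium ratios typical of this
# cation channel family (fixture values; the recovery analysis in stage
# 05 measures them back from the ramps)
ramps <- list(Ca = c(Na = 1, Ca = 9.6), Mg = c(Na = 1, Mg = 5.0))
for (ion in names(ramps)) {
  ions <- ion_conditions(data.frame(
    name = c("Na", ion), valence = c(1, 2),
    conc_in = c(0, 70), conc_out = c(140, 0)))
  rec <- simulate_ramp_iv(ramps[[ion]], ions, g_scale = 0.5,
                          v_start = -100, v_end = 100, duration = 500,
                          noise_sd = 1, seed = seed + 40 + match(ion, names(ramps)))
  write_recording(rec, file.path(out, sprintf("ramp_%s.tsv", ion)))
  cat(sprintf("  %s ramp: generating E_rev = %.3f mV\n", ion,
              attr(rec, "erev_mV")))
}

message("done; wrote ", length(list.files(out)), " files under ", out)
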