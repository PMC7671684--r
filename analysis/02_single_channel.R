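#!/usr/bin/env Rscript
# Stage 2: single-channel analysis of the saturating traces from stage 1.
#
# For each ligand: all-point histogram, double-Gaussian level fit,
# half-amplitude idealization with the 0.3 ms dead time, then Po,
# unitary amplitude and chord conductance at +80 mV. The recovered Po is
# compared against the generating dwell ground truth.

suppressPackageStartupMessages(library(trpv1ruler))
indir <- "results/data"
dir.create("results", showWarnings = FALSE)

conds <- read.csv(file.path(indir, "study_conditions.csv"))
rows <- list()
for (i in seq_len(nrow(conds))) {
  lg <- conds$ligand[i]
  rec <- read_recording(file.path(indir, sprintf("sc_%s.tsv", lg)))
  truth <- read.delim(file.path(indir, sprintf("sc_%s_truth.tsv", lg)))
  hf <- amplitude_histogram_fit(rec)
  ev <- idealize_events(rec, hf$fit, dead_time = 0.3)
  write_event_list(ev, sprintf("results/events_%s.tsv", lg),
                   i_pA = hf$fit$amplitude_pA)
  po_true <- sum(truth$duration_ms[truth$level == "open"]) /
    sum(truth$duration_ms)
  rows[[i]] <- data.frame(
    ligand = lg,
    i_pA = hf$fit$amplitude_pA,
    g_pS = conductance(hf$fit$amplitude_pA, V = 80, E_rev = 0),
    po = open_probability(ev),
    po_truth = po_true,
    n_events = nrow(ev))
}
tab <- do.call(rbind, rows)
write.table(format(tab, digits = 5), "results/single_channel_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 4)
cat("\nmax |Po - truth| =", signif(max(abs(tab$po - tab$po_truth)), 2), "\n")
cat("conductance of the short analog is ~10% below the other two, as built in.\n")
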