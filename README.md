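# trpv1ruler

Quantitative analysis of capsaicin-receptor (TRPV1) gating and of the
"molecular ruler" structural measurements used to probe its ligand-binding
pocket. The package covers the full chain from raw patch-clamp-style traces
to thermodynamic state diagrams:

- **Single-channel analysis** — all-point amplitude histograms with
  double-Gaussian level fits, 50%-amplitude threshold idealization with a
  0.3 ms dead time, open probability and chord conductance at +80 mV.
- **Concentration-response analysis** — Hill activation/inhibition fits
  (EC50/IC50, Hill coefficient, max, asymptotic SEs), single-exponential
  tail-current (OFF-rate) fits, and conductance-corrected normalization of
  macroscopic currents to the open-probability scale.
- **Allosteric decomposition** — under the three-state scheme
  C ⇌ C·L ⇌ O·L with binding constant K_D and gating constant L,

      Po(c) = L (c/K_D) / (1 + (c/K_D)(1 + L))

  so at saturation L = Po_max/(1 − Po_max) and K_D = EC50·(1 + L). The
  package implements both this two-step estimator and a direct
  least-squares three-state fit (with an explicit identifiability warning
  on the flat L–K_D ridge that appears when Po_max → 1), plus Eyring
  free-energy profiles G(CL) = −RT ln(c/K_D), G(OL) = G(CL) − RT ln L.
- **Ion selectivity** — reversal-potential extraction from voltage-ramp
  I–V data and the extended (mixed mono/divalent) Goldman–Hodgkin–Katz
  constant-field equation in both directions (E_rev from permeabilities,
  permeability ratios from E_rev).
- **Structure metrics** — fixed-column PDB input (via bio3d) and output,
  segment-anchored Kabsch superposition, per-residue backbone RMSD
  profiles, minimum inter-residue (hydrogen-bond pair) distances with
  per-subunit reporting, and HOLE-style pore-radius profiles.
- **Synthetic data** — seeded generators for every input the pipeline
  consumes (two-state Markov gating via Gillespie sampling rendered at
  10 kHz with 2.9 kHz Gaussian low-pass emulation, Hill/three-state
  concentration-response tables, exponential tails, GHK-governed ramps,
  toy structures with analytic geometry), so every estimator is testable
  against known ground truth.

## Worked example

Decompose the wild-type capsaicin response (saturating Po 0.94, EC50
0.14 µM) into its equilibrium constants, predict Po at 10 µM, and verify
the recovery of Po from a simulated 200 s single-channel recording:

```r
library(trpv1ruler)

L  <- estimate_L(0.94)$L              # 15.6667
KD <- estimate_KD(0.14, L)$K_D        # 2.3333 uM
m  <- channel_model(K_D = KD, L = L, g = 100, E_rev = 0)
predict_po(m, 10)                     # 0.9270 -- near-saturating at 10 uM

eyring_profile(m, c = 10, T = 295.15)
#>   state          G
#> 1     C  0.0000000
#> 2    CL -0.8535599
#> 3    OL -2.4673996   (kcal/mol; the open state is strongly stabilized)

sim <- simulate_single_channel(m, open_rate = 0.94/0.06 * 0.1,
                               close_rate = 0.1, duration = 2e5,
                               noise_sd = 1.2, seed = 1)
lv  <- amplitude_histogram_fit(sim$recording)$fit
ev  <- idealize_events(sim$recording, lv, dead_time = 0.3)
open_probability(ev)                  # 0.9432 -- within 0.01 of the target
conductance(lv$amplitude_pA, V = 80)  # ~98 pS
```

The `analysis/` directory holds the numbered drivers that run the whole
study on synthetic data (`01_simulate.R` … `06_structure.R`, each taking
`--seed <int>`); their tables land under `results/`.

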