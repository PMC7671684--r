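Package: trpv1ruler
Title: Allosteric Gating and Molecular-Ruler Analysis of TRPV1 Agonists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of patch-clamp recordings from the
    capsaicin receptor TRPV1 and structural measurements on its
    ligand-binding pocket. Provides two-state Markov single-channel
    simulation with realistic acquisition (sampling, low-pass filtering,
    Gaussian noise), all-point amplitude histograms with double-Gaussian
    fitting, half-amplitude threshold idealization with dead-time
    imposition, Hill concentration-response and tail-current exponential
    fitting, decomposition of agonist action into binding (K_D) and gating
    (L) equilibrium constants under a three-state allosteric scheme, Eyring
    free-energy profiles, Goldman-Hodgkin-Katz reversal-potential and
    permeability-ratio analysis for mixed mono/divalent solutions, and
    molecular-ruler structure metrics (segment-anchored Kabsch
    superposition, per-residue backbone RMSD, minimum inter-residue
    distances, HOLE-style pore-radius profiles).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
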