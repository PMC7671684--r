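---
title: "Models and methods: TRPV1 gating analysis and molecular-ruler metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpv1ruler)
```

## The scientific problem

TRPV1 is a capsaicin-gated cation channel whose agonists act
allosterically: ligand binding in a transmembrane pocket stabilizes a
permissive pocket conformation that in turn favours pore opening. A pair
of capsaicin analogs lengthened or shortened by one methylene (~1.5 Å)
acts as a set of molecular rulers for this conformational change: each
analog's potency (EC50), efficacy (maximal open probability), unbinding
kinetics (OFF rate) and induced pocket conformation (per-residue RMSD
against the agonist-bound reference structure) report on how ligand size
maps onto the ~1.3 Å movement of the S4–S5 linker. This package
implements the complete quantitative tool chain for that kind of study,
together with seeded synthetic-data generators so that every estimator is
validated against known ground truth.

## The three-state allosteric model

The gating scheme is C ⇌ C·L ⇌ O·L: a single binding step with
dissociation constant $K_D$ (µM) followed by a gating step with
equilibrium constant $L$ (dimensionless). Unliganded openings are
neglected — they are rare for this channel — so there is no direct C ⇌ O
leg. The equilibrium open probability is

$$Po(c) = \frac{L\,(c/K_D)}{1 + (c/K_D)(1+L)},$$

which is exactly a Hill curve with unit slope,
$EC_{50} = K_D/(1+L)$ and $Po_{max} = L/(1+L)$. Two estimation routes are
provided:

* **Two-step** (`estimate_L`, `estimate_KD`): $L = Po_{max}/(1-Po_{max})$
  from the saturating open probability, then $K_D = EC_{50}(1+L)$ from the
  fitted EC50. Standard errors propagate by the first-order delta method
  with $Po_{max}$ and $EC_{50}$ treated as independent;
  $SE_L = SE_{Po}/(1-Po_{max})^2$ and
  $SE_{K_D}^2 = (1+L)^2 SE_{EC50}^2 + EC_{50}^2 SE_L^2$.
* **Direct fit** (`fit_three_state`): least squares on the Po-scale curve
  with $(\log K_D, \log L)$ free.

Both share the same identifiability limit: as $Po_{max} \to 1$ the
denominator $1 - Po_{max}$ vanishes and only the ratio $K_D/(1+L)$ is
determined — a shift of the curve could equally be a change of binding or
of gating. `estimate_L` refuses $Po_{max} \ge 1$ outright;
`fit_three_state` emits a ridge warning when the fitted saturation
exceeds 0.98 or the Jacobian cross-product is ill-conditioned
(condition number above $10^8$). The experimental remedy this mirrors is
a background mutation that lowers $Po_{max}$ to about 0.5 ($L \approx 1$),
where both constants separate cleanly.

A deliberate modelling note: the three-state equilibrium forces a Hill
slope of 1, while measured activation curves can show slopes up to ~2.
The decomposition therefore uses only $Po_{max}$ and $EC_{50}$, never the
fitted slope.

Eyring profiles place the states at $G(C) = 0$,
$G(CL) = -RT\ln(c/K_D)$, $G(OL) = G(CL) - RT\ln L$ (kcal/mol, gas
constant $1.98720425\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, default
$T = 295.15$ K for the ~22 °C recordings; a $k_BT$-unit mode is
available). Energy *differences* are reference-invariant, which the test
suite checks explicitly. When an OFF rate is supplied, the unbinding
barrier height comes from the Eyring rate equation
$k = (k_B T/h)\,e^{-\Delta G^\ddagger/RT}$ with transmission coefficient
1; absolute barrier heights inherit that idealization and should be read
comparatively.

## Synthetic recordings: what is emulated, and what is not

`simulate_single_channel` draws a two-state continuous-time Markov chain
by Gillespie sampling (exponential dwells at the two rates; the
stationary open probability is `open_rate/(open_rate+close_rate)`),
renders it at the acquisition sampling rate (default 10 kHz) with unitary
amplitude $i = g(V - E_{rev})/1000$ pA, adds white Gaussian noise, and
applies a Gaussian low-pass with $\sigma_t = 0.1325/f_c$ emulating a
Bessel filter with the stated 2.9 kHz corner (the filter type beyond the
corner frequency is unspecified in such recordings; the Gaussian kernel
matches the −3 dB point and is the conventional stand-in). Fractional
dwell boundaries are assigned to the sample containing the transition
(floor convention). Defaults follow the recording protocol: +80 mV test
potential, 10 kHz sampling, 2.9 kHz corner, 22 °C.

Fixture choices the recordings do not pin down, made once: mean open
dwell 10 ms (dwell-time constants are not reported for these data; 10 ms
keeps ~40 000 events in a 200 s trace, ample for dead-time statistics);
unitary conductance 100 pS at +80 mV (an 8 pA amplitude, with 90 pS for
the ~10% smaller short-analog level); OFF time constants 60/20/12 ms
(absolute values unreported; the 3× and 5× ratios match the reported
2–6× faster unbinding of the analogs); divalent-over-sodium permeability
ratios 9.6 (Ca) and 5.0 (Mg) in the ramp generator, typical of this
channel family.

Not modelled: multi-channel patches (discarded in practice),
desensitization, baseline drift, capacitance/leak transients,
flicker/sub-conductance behaviour. Passing tests therefore demonstrate
correctness of the estimators under clean stationary gating with
realistic noise and filtering — not robustness to every pathology of real
membranes.

## Single-channel analysis choices

* **Histogram**: Freedman–Diaconis bin width by default (binning is a
  free choice; FD adapts to noise width), overridable; bins clamped to
  [20, 400]. Counts always conserve the sample count exactly.
* **Level fit**: nonlinear least squares of a two-Gaussian mixture on the
  bin counts with moment-based starts from a midrange split —
  curve-fitting on the histogram matches the field's standard tooling;
  an EM mixture fit would also do. Noiseless (delta-peak) traces skip the
  iterative fit and use exact cluster means. A fit whose means are closer
  than twice the larger component SD is reported as degenerate
  (unimodal), not returned.
* **Idealization**: threshold at the arithmetic midpoint of the fitted
  means (the 50%-amplitude rule, without hysteresis). Events shorter than
  the dead time (default 0.3 ms) are absorbed into the enclosing level by
  a shortest-first chronological re-scan to a fixed point; since events
  strictly alternate, each interior absorption fuses exactly three events.
  Shortest-first makes the result order-deterministic and idempotent
  (both tested). Edge events merge into their single neighbour.
* **Po**: pooled open time over total time per recording. Aggregation
  across patches is left to the caller (the analysis drivers report
  per-recording values); per-patch mean ± SEM is the convention to prefer
  when patches differ in length.

The 0.3 ms dead time biases recovered Po slightly upward at high Po
(brief closures are absorbed preferentially); at Po 0.94 with 10 ms open
dwells the bias is ~+0.004, comfortably inside the 0.01 agreement band
the acceptance test asserts.

## Dose-response fitting choices

Hill fits run on log-concentration internally (parameter $\log EC_{50}$)
for conditioning and report linear-scale values; starts are
$EC_{50}$ at the half-range response, slope 1, max at the observed
maximum. Unweighted by default with optional $1/SE^2$ weighting. SEs are
asymptotic (Jacobian at the optimum; delta method for the log
back-transform); the suite verifies they track a parametric bootstrap
within 20% in the reduced-Po_max scenario. Fits are rejected (not
returned) when responses are flat, fewer than 4 distinct concentrations
are given, convergence fails, or the fitted EC50 lands more than 10×
outside the sampled range. Tail currents are fit as
$I(t) = b + a\,e^{-(t-t_0)/\tau}$ with a free baseline; the OFF rate is
$1/\tau$.

The Levenberg–Marquardt front end retries from slightly nudged start
values if the underlying model constructor spuriously rejects a start
point as rank-deficient — a rare numerical artefact of its
finite-difference initial check, not of the optimization itself.

## GHK selectivity

The extended constant-field (Fatt–Ginsborg-type) flux expression handles
monovalent and divalent species uniformly; `ghk_erev` returns the unique
zero of the summed fluxes in [−200, 200] mV (series expansion near
$u = 0$ avoids the 0/0). Concentrations are used as activities — no
activity-coefficient correction is applied, as none is standard for these
solutions — and Cl⁻, EGTA and HEPES are treated as impermeant for this
cation-selective channel. The bi-ionic inversion has closed forms
(divalent-in/monovalent-out: $P_X/P_M = [M]_o e^{-u}(1+e^{-u})/(4[X]_i)$
with $u = E_{rev}F/RT$; both-monovalent: $[M]_o e^{-u}/[X]_i$); the sign
of $u$ follows from requiring zero summed flux, and the closed form,
the general numeric inversion (the flux sum is affine in the test
permeability) and the forward equation round-trip mutually to well below
0.1% — all three are compared in the tests. Ramp reversal extraction fits
a cubic within ±20 mV of the zero crossing; sign flips clustered within
one window width count as a single noisy crossing, while separated
clusters raise an ambiguity error listing candidates.

## Structure metrics

PDB parsing is delegated to bio3d behind `read_structure`, with
line-level validation first (malformed coordinate fields are reported
with their line number), only the first MODEL block kept (warning
otherwise), hydrogens dropped (cryo-EM models lack them), and alternate
locations resolved to the highest-occupancy record with ties going to
altloc A. Coordinates keep the residue numbering of the records; the
mouse-vs-rat numbering of the functional work against the reference
structures is handled by `mouse_to_rat_resno` (default offset 1, so mouse
T551/E571 map to structure 550/570).

Superposition is the SVD-based Kabsch algorithm with the proper-rotation
correction, estimated on an explicit anchor selection (e.g. the S4
backbone) and applied to all atoms; the suite checks it against an
independent closed-form quaternion solver to $10^{-6}$ Å. Per-residue
RMSD uses the backbone set N, CA, C, O by default (a CA-only mode
exists), with **no per-residue re-fitting**, and reports missing residues
as gaps rather than zeros. The exact atom pair behind the apo-vs-bound
hydrogen-bond distance is not fixed by convention, so
`residue_min_distance` takes the minimum over the supplied sidechain
oxygen subsets (threonine OG1 against both glutamate carboxylate
oxygens) and, when no chain is named, reports each subunit of the
tetramer plus their mean.

Pore profiles follow the HOLE idea in simplified form: at each axial
position the radius is the largest sphere centred on the axis
(`fixed_axis`) or at a locally optimized in-plane centre
(`optimized_center`, 0.5 Å grid then Nelder–Mead refinement) that touches
no atom, using Bondi van der Waals radii. Slices with radius above a
configurable maximum (default 10 Å) are flagged unbounded. The default
axis is the z axis through the xy centroid, with a principal-axis mode
and an explicit two-point override. Whether a published deviation of
"less than 0.4 Å" refers to radius or diameter is ambiguous; this package
always reports radii, so halve any diameter figure before comparing.

## Problem sizes and numerical tolerances

The simulation studies in the tests use sizes chosen to keep sampling
error well below the asserted bounds: $\ge 10^4$ dwells for the
exponentiality and mean-dwell checks, 200 s of simulated recording (2
million samples) for the Po round trip, 100 seeds for the
parameter-recovery studies, 150–200 replicates for the bootstrap
comparison. Root solving uses `uniroot` at $10^{-10}$ mV tolerance;
superposition agreement is asserted at $10^{-6}$ Å; pore profiles agree
with an exhaustive 0.05 Å grid search within 0.05 Å. The PDB writer
keeps the format's 3-decimal coordinate precision, which bounds the
write/read round-trip error at $5\times10^{-4}$ Å per coordinate.

## Known limitations

* The three-state decomposition ignores the measured Hill slope; systems
  with genuine binding cooperativity need a richer scheme.
* Dead-time handling is the fixed merging rule only — no missed-event
  correction of dwell-time distributions is attempted.
* The Gaussian filter emulation matches a Bessel corner's magnitude
  response, not its phase.
* `optimized_center` pore profiles search the plane perpendicular to a
  straight axis; strongly curved pores would need a bent-axis search.
* Absolute Eyring barrier heights assume unit transmission; use them for
  comparisons between ligands, not as absolute activation enthalpies.
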