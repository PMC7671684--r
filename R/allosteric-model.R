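#' Three-state allosteric gating model
#'
#' The liganded-gating scheme C <-> CL <-> OL with a binding step governed by
#' the dissociation constant `K_D` and a gating step governed by the
#' equilibrium constant `L` (open/closed ratio of the fully liganded channel).
#' Unliganded openings are neglected, so the open probability at agonist
#' concentration `c` is
#'
#'   Po(c) = L * (c / K_D) / (1 + (c / K_D) * (1 + L))
#'
#' which is exactly a Hill curve with unit slope, half-maximum at
#' EC50 = K_D / (1 + L) and saturating Po_max = L / (1 + L).
#'
#' @param K_D dissociation constant of the binding step, uM (> 0)
#' @param L gating equilibrium constant, dimensionless (>= 0)
#' @param g single-channel conductance, pS (> 0)
#' @param E_rev reversal potential, mV
#' @return an object of class `channel_model`
#' @examples
#' m <- channel_model(K_D = 2.33, L = 15.67)
#' predict_po(m, 10)
#' @export
channel_model <- function(K_D, L, g = 100, E_rev = 0) {
  stopifnot(is.numeric(K_D), length(K_D) == 1L,
            is.numeric(L), length(L) == 1L,
            is.numeric(g), length(g) == 1L)
  if (!is.finite(K_D) || K_D <= 0) stop("K_D must be a positive finite number (uM)")
  if (!is.finite(L) || L < 0) stop("L must be a non-negative finite number")
  if (!is.finite(g) || g <= 0) stop("g must be a positive conductance (pS)")
  structure(list(K_D = K_D, L = L, g = g, E_rev = E_rev),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf(
    "<channel_model> K_D = %.4g uM, L = %.4g, g = %.4g pS, E_rev = %.4g mV\n",
    x$K_D, x$L, x$g, x$E_rev))
  cat(sprintf("  EC50 = %.4g uM, Po_max = %.4g\n",
              x$K_D / (1 + x$L), x$L / (1 + x$L)))
  invisible(x)
}

#' Equilibrium open probability of the three-state scheme
#'
#' @param model a [channel_model()]
#' @param c agonist concentration(s), uM (>= 0)
#' @return open probability in `[0, L/(1+L))`, vectorized over `c`
#' @export
predict_po <- function(model, c) {
  stopifnot(inherits(model, "channel_model"), is.numeric(c))
  if (any(c < 0)) stop("negative concentration")
  x <- c / model$K_D
  model$L * x / (1 + x * (1 + model$L))
}

#' Gating equilibrium constant from the maximal open probability
#'
#' At saturating agonist, the three-state scheme reduces to CL <-> OL so
#' L = Po_max / (1 - Po_max). The standard error is propagated to first
#' order: SE_L = se / (1 - Po_max)^2.
#'
#' As Po_max approaches 1 the denominator vanishes and L (and with it K_D)
#' becomes unidentifiable from steady-state data; an error is raised rather
#' than returning an unstable estimate. A background mutation that lowers
#' Po_max (e.g. to ~0.5) restores identifiability.
#'
#' @param po_max maximal open probability, in (0, 1)
#' @param se standard error of `po_max` (default 0)
#' @return list with elements `L` and `se`
#' @export
estimate_L <- function(po_max, se = 0) {
  stopifnot(is.numeric(po_max), length(po_max) == 1L, se >= 0)
  if (po_max >= 1)
    stop("Po_max >= 1: L is unidentifiable because the denominator ",
         "(1 - Po_max) becomes very small at saturating ligand concentrations")
  if (po_max <= 0) stop("Po_max must be positive")
  list(L = po_max / (1 - po_max), se = se / (1 - po_max)^2)
}

#' Binding dissociation constant from EC50 and L
#'
#' K_D = EC50 * (1 + L). Standard errors of the two inputs are combined by
#' the first-order delta method assuming independence:
#' SE^2 = (1+L)^2 se_EC50^2 + EC50^2 se_L^2.
#'
#' @param ec50 half-activation concentration, uM (> 0)
#' @param L gating equilibrium constant (>= 0)
#' @param ec50_se,L_se standard errors (default 0)
#' @return list with elements `K_D` and `se`
#' @export
estimate_KD <- function(ec50, L, ec50_se = 0, L_se = 0) {
  stopifnot(length(ec50) == 1L, length(L) == 1L)
  if (!is.finite(ec50) || ec50 <= 0) stop("EC50 must be positive")
  if (L < 0) stop("L must be non-negative")
  se <- sqrt((1 + L)^2 * ec50_se^2 + ec50^2 * L_se^2)
  list(K_D = ec50 * (1 + L), se = se)
}

#' Fit the three-state model directly to a Po-scale concentration-response curve
#'
#' Least-squares fit of Po(c) = L (c/K_D) / (1 + (c/K_D)(1+L)) with both
#' parameters free, on log scale internally for conditioning. This is the
#' direct alternative to the two-step (Po_max, EC50) estimator and shares
#' its identifiability limit: when the fitted saturation L/(1+L) exceeds
#' ~0.98 the (K_D, L) likelihood surface has a flat ridge (only their ratio
#' EC50 = K_D/(1+L) is well determined) and a warning is issued.
#'
#' @param curve a [dose_response_curve()] with responses on the Po scale
#' @param start optional list with elements `K_D`, `L`
#' @return a [channel_model()] with attributes `se` (named vector), `rss`,
#'   and `ridge` (logical identifiability flag)
#' @export
fit_three_state <- function(curve, start = NULL) {
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentration
  po <- curve$response
  if (diff(range(po)) < 1e-12 * max(1, max(abs(po))))
    stop("identifiability error: responses are constant (all-saturated or all-zero curve)")
  if (max(po) < 0.02)
    stop("identifiability error: curve never rises appreciably above zero")
  if (is.null(start)) {
    po_top <- min(max(po), 0.99)
    L0 <- max(po_top / (1 - po_top), 0.05)
    ec50_0 <- stats::approx(po, conc, xout = max(po) / 2, ties = mean)$y
    if (is.na(ec50_0)) ec50_0 <- stats::median(conc)
    start <- list(K_D = ec50_0 * (1 + L0), L = L0)
  }
  dat <- data.frame(conc = conc, po = po)
  fit <- safe_nlsLM(
    po ~ exp(lL) * (conc / exp(lK)) / (1 + (conc / exp(lK)) * (1 + exp(lL))),
    data = dat,
    start = list(lK = log(start$K_D), lL = log(start$L)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  K_D <- exp(cf[["lK"]]); L <- exp(cf[["lL"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- c(K_D = K_D * sqrt(vc[1, 1]), L = L * sqrt(vc[2, 2]))
  po_max_hat <- L / (1 + L)
  # ridge diagnostic: saturation close to 1, or ill-conditioned Jacobian
  J <- fit$m$gradient()
  kappa_J <- tryCatch(kappa(crossprod(J)), error = function(e) Inf)
  ridge <- po_max_hat > 0.98 || !is.finite(kappa_J) || kappa_J > 1e8
  if (ridge)
    warning("flat L-K_D ridge: fitted Po_max = ", signif(po_max_hat, 3),
            "; only EC50 = K_D/(1+L) is well determined at high Po_max")
  out <- channel_model(K_D = K_D, L = L)
  attr(out, "se") <- se
  attr(out, "rss") <- sum(stats::resid(fit)^2)
  attr(out, "ridge") <- ridge
  out
}

# gas constant in kcal/mol/K
.R_KCAL <- 1.98720425e-3
# Boltzmann/Planck ratio, 1/(s*K) -- Eyring prefactor k_B T / h = .KB_OVER_H * T
.KB_OVER_H <- 2.083661912e10

#' Eyring free-energy profile of the three-state gating cycle
#'
#' State free energies relative to the unliganded closed state C at agonist
#' concentration `c`:
#'   G(C)  = 0
#'   G(CL) = -RT ln(c / K_D)
#'   G(OL) = G(CL) - RT ln(L)
#' so the open state lies below the liganded-closed state exactly when
#' L > 1. When an unbinding (OFF) rate is supplied, the barrier height for
#' the unbinding transition is placed by the Eyring rate equation
#' k = (k_B T / h) exp(-dG'/RT) with unit transmission coefficient.
#'
#' @param est list with elements `L` and `K_D` (e.g. from [estimate_L()] /
#'   [estimate_KD()]), or a [channel_model()]
#' @param c agonist concentration, uM (> 0)
#' @param T temperature, K (default 295.15, i.e. ~22 C)
#' @param off_rate optional unbinding rate, 1/ms
#' @param units `"kcal"` (kcal/mol, default) or `"kT"` (multiples of k_B T)
#' @return data.frame with columns `state` ("C", "CL", "OL") and `G`;
#'   attribute `barrier` holds the unbinding barrier height (same units)
#'   when `off_rate` is given; attribute `units` records the energy unit
#' @export
eyring_profile <- function(est, c, T = 295.15, off_rate = NULL,
                           units = c("kcal", "kT")) {
  units <- match.arg(units)
  if (inherits(est, "channel_model")) est <- list(L = est$L, K_D = est$K_D)
  stopifnot(is.numeric(c), length(c) == 1L, T > 0)
  if (c <= 0) stop("c must be positive: binding energy diverges at zero concentration")
  if (est$L <= 0) stop("L must be positive for a finite open-state energy")
  RT <- .R_KCAL * T
  g_cl <- -RT * log(c / est$K_D)
  g_ol <- g_cl - RT * log(est$L)
  scale <- if (units == "kT") 1 / RT else 1
  prof <- data.frame(state = c("C", "CL", "OL"),
                     G = c(0, g_cl, g_ol) * scale,
                     stringsAsFactors = FALSE)
  if (!is.null(off_rate)) {
    stopifnot(off_rate > 0)
    k_s <- off_rate * 1000  # 1/ms -> 1/s
    dg_unbind <- -RT * log(k_s / (.KB_OVER_H * T))
    attr(prof, "barrier") <- dg_unbind * scale
  }
  attr(prof, "units") <- if (units == "kT") "k_B T" else "kcal/mol"
  attr(prof, "concentration_uM") <- c
  attr(prof, "temperature_K") <- T
  prof
}
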