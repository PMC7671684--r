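# Hill concentration-response fitting (activation and inhibition),
# single-exponential tail-current (OFF-rate) fitting, and conversion of
# macroscopic currents to the open-probability scale by normalization to a
# saturating reference agonist.

#' Concentration-response data container
#'
#' @param concentration agonist (or antagonist) concentrations, uM,
#'   strictly increasing
#' @param response normalized current or open probability per concentration
#' @param se standard errors (same units as response), optional
#' @param n number of patches per point, optional
#' @return a `dose_response_curve` data.frame
#' @export
dose_response_curve <- function(concentration, response, se = NA_real_,
                                n = NA_integer_) {
  if (length(concentration) == 0L) stop("empty concentration list")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (length(response) != length(concentration))
    stop("response length mismatch")
  if (any(!is.finite(response))) stop("responses must be finite")
  out <- data.frame(concentration = concentration, response = response,
                    se = se, n = n)
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

#' Write / read a concentration-response table as CSV
#'
#' Columns: `concentration_uM`, `response`, `se`, `n`.
#'
#' @param curve a [dose_response_curve()]
#' @param path file path
#' @export
write_dose_response <- function(curve, path) {
  utils::write.csv(
    data.frame(concentration_uM = curve$concentration,
               response = curve$response, se = curve$se, n = curve$n),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  d <- utils::read.csv(path)
  dose_response_curve(d$concentration_uM, d$response, se = d$se, n = d$n)
}

#' Fit a Hill equation to a concentration-response curve
#'
#' Activation: R(c) = max / (1 + (EC50/c)^K); inhibition:
#' R(c) = max / (1 + (c/IC50)^K). The fit is performed on log
#' concentration internally (parameter log EC50) for conditioning and
#' reported on the linear scale; standard errors are asymptotic (from the
#' Jacobian at the optimum, delta method for EC50). Default start values:
#' EC50 at the half-range response, K = 1, max = max response.
#'
#' @param curve a [dose_response_curve()]
#' @param direction `"activation"` or `"inhibition"`
#' @param weighted if `TRUE`, weight points by 1/se^2 (requires finite
#'   `se`); default unweighted
#' @return a `hill_fit` list: `ec50`, `ec50_se`, `K`, `K_se`, `max`,
#'   `max_se`, `direction`, `residuals`, `rss`
#' @export
fit_hill <- function(curve, direction = c("activation", "inhibition"),
                     weighted = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentration
  resp <- curve$response
  if (length(unique(conc)) < 4L)
    stop("insufficient-data error: need >= 4 distinct concentrations")
  if (any(resp < -0.05 * max(abs(resp))))
    warning("negative responses present; Hill model assumes responses >= 0")
  rng <- diff(range(resp))
  if (rng < 1e-10 * max(1, max(abs(resp))))
    stop("fit-quality error: responses are constant across concentrations")
  half <- min(resp) + rng / 2
  ec50_0 <- stats::approx(resp, conc, xout = half, ties = mean)$y
  if (is.na(ec50_0)) ec50_0 <- exp(mean(log(range(conc))))
  w <- if (weighted) {
    if (any(!is.finite(curve$se)) || any(curve$se <= 0))
      stop("weighted fit requires positive finite SEs")
    1 / curve$se^2
  } else rep(1, length(conc))
  sgn <- if (direction == "activation") 1 else -1
  dat <- data.frame(lc = log(conc), resp = resp)
  fit <- safe_nlsLM(
    resp ~ rmax / (1 + exp(sgn * K * (lec50 - lc))),
    data = dat, weights = w,
    start = list(rmax = max(resp), lec50 = log(ec50_0), K = 1),
    lower = c(1e-12, -Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  if (!fit$convInfo$isConv)
    stop("fit-quality error: Hill fit did not converge")
  ec50 <- exp(cf[["lec50"]])
  if (ec50 > 10 * max(conc) || ec50 < min(conc) / 10)
    stop("fit-quality error: fitted EC50 lies more than 10x outside the ",
         "sampled concentration range")
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  structure(list(
    ec50 = ec50,
    ec50_se = ec50 * sqrt(vc[2, 2]),
    K = cf[["K"]], K_se = sqrt(vc[3, 3]),
    max = cf[["rmax"]], max_se = sqrt(vc[1, 1]),
    direction = direction,
    residuals = as.numeric(stats::resid(fit)),
    rss = sum(stats::resid(fit)^2)), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$direction == "activation") "EC50" else "IC50"
  cat(sprintf("<hill_fit> %s = %.4g +/- %.2g uM, K = %.3g +/- %.2g, max = %.4g +/- %.2g\n",
              lab, x$ec50, x$ec50_se, x$K, x$K_se, x$max, x$max_se))
  invisible(x)
}

#' Evaluate a fitted (or specified) Hill curve
#'
#' @param ec50 half-maximal concentration, uM
#' @param K Hill coefficient
#' @param max saturating response
#' @param conc concentrations at which to evaluate, uM
#' @param direction `"activation"` or `"inhibition"`
#' @return response vector
#' @export
hill_response <- function(conc, ec50, K = 1, max = 1,
                          direction = c("activation", "inhibition")) {
  direction <- match.arg(direction)
  if (direction == "activation") max / (1 + (ec50 / conc)^K)
  else max / (1 + (conc / ec50)^K)
}

#' Fit a single-exponential tail-current decay (OFF rate)
#'
#' Least-squares fit of I(t) = baseline + amplitude * exp(-(t - t0)/tau)
#' within the analysis window; the OFF rate is 1/tau.
#'
#' @param tail a [recording()] containing the deactivating tail
#' @param window optional `c(t0, t1)` analysis window, ms (defaults to the
#'   full trace)
#' @return a `tau_fit` list: `tau`, `tau_se`, `off_rate` (1/ms),
#'   `amplitude`, `baseline`, `rss`
#' @export
fit_off_rate <- function(tail, window = NULL) {
  t <- tail$time_ms; x <- tail$current_pA
  if (!is.null(window)) {
    if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9)
      stop("window outside trace")
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; x <- x[keep]
  }
  if (length(t) < 5L) stop("too few samples in window")
  t0 <- t[1]
  n <- length(x)
  head_m <- mean(x[seq_len(max(3L, n %/% 20))])
  tail_m <- mean(x[seq(n - max(3L, n %/% 20) + 1L, n)])
  if (abs(head_m - tail_m) < 1e-12 * max(1, abs(head_m)))
    stop("fit error: trace does not decay within the window")
  dat <- data.frame(tt = t - t0, x = x)
  fit <- tryCatch(
    safe_nlsLM(
      x ~ b + a * exp(-tt / tau), data = dat,
      start = list(b = tail_m, a = head_m - tail_m,
                   tau = (t[length(t)] - t0) / 3),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit error: exponential fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  structure(list(tau = cf[["tau"]], tau_se = sqrt(vc[3, 3]),
                 off_rate = 1 / cf[["tau"]],
                 amplitude = cf[["a"]], baseline = cf[["b"]],
                 rss = sum(stats::resid(fit)^2)), class = "tau_fit")
}

#' Convert a macroscopic maximal current to the open-probability scale
#'
#' Normalizes the test agonist's saturating current to that of a reference
#' agonist of known Po (the saturating-capsaicin convention), after
#' correcting for any single-channel conductance difference:
#' Po = (test / conductance_ratio) / ref * ref_po. A conductance_ratio of
#' 0.9 implements the correction for an analog whose unitary amplitude is
#' 10% smaller than the reference.
#'
#' @param test_max_current saturating current of the test agonist, pA
#' @param ref_max_current saturating current of the reference agonist, pA
#' @param ref_po open probability of the reference agonist at saturation
#' @param conductance_ratio test/reference single-channel amplitude ratio
#'   (1 when equal)
#' @return open probability (clipped to 1 with a warning if the raw value
#'   exceeds 1; the raw value is kept in attribute `raw`)
#' @export
normalize_to_po <- function(test_max_current, ref_max_current, ref_po,
                            conductance_ratio = 1) {
  if (ref_max_current <= 0) stop("reference current must be positive")
  if (ref_po <= 0 || ref_po > 1) stop("ref_po must be in (0, 1]")
  if (conductance_ratio <= 0) stop("conductance_ratio must be positive")
  po <- (test_max_current / conductance_ratio) / ref_max_current * ref_po
  if (po > 1) {
    warning("normalized Po exceeds 1 (", signif(po, 4), "); reporting 1")
    return(structure(1, raw = po))
  }
  po
}
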