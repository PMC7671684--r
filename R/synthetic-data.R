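# Synthetic-data generators emulating the recording conditions of the
# TRPV1 capsaicin-analog experiments: two-state Markov single-channel
# gating rendered at 10 kHz with a 2.9 kHz low-pass corner, Hill-shaped
# concentration-response, single-exponential tail currents and
# GHK-governed ramp I-V. Every generator is seeded and returns its ground
# truth so downstream estimators can be tested without real recordings.

# Gaussian low-pass emulating a Bessel filter with corner frequency fc (Hz):
# kernel sigma_t = 0.1325 / fc seconds (matched -3 dB point). Edges are
# handled by renormalizing the truncated kernel.
gaussian_lowpass <- function(x, sampling_hz, filter_hz) {
  sigma_s <- 0.1325 * sampling_hz / filter_hz
  half <- max(1L, ceiling(4 * sigma_s))
  k <- stats::dnorm(seq(-half, half), sd = sigma_s)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Simulate a single-channel recording with two-state Markov gating
#'
#' Continuous-time two-state (closed <-> open) Markov chain sampled by the
#' Gillespie algorithm: dwell times are exponential with rate `open_rate`
#' (closed -> open) and `close_rate` (open -> closed), so the stationary
#' open probability is `open_rate / (open_rate + close_rate)`. The dwell
#' sequence is rendered on the acquisition grid with unit amplitude
#' i = g (V - E_rev) / 1000 pA, fractional dwell boundaries assigned to the
#' sample containing the transition (floor convention), additive white
#' Gaussian noise, then Gaussian low-pass emulation of the recording
#' filter.
#'
#' @param model a [channel_model()] supplying conductance and reversal
#' @param open_rate closed->open rate, 1/ms
#' @param close_rate open->closed rate, 1/ms
#' @param duration trace length, ms
#' @param voltage test potential, mV (default +80)
#' @param noise_sd additive Gaussian noise SD before filtering, pA
#' @param seed RNG seed (required: generators are reproducible by contract)
#' @param sampling_hz sampling rate, Hz (default 10 kHz)
#' @param filter_hz low-pass corner, Hz (default 2.9 kHz)
#' @return list with `dwells` (a `dwell_sequence`: data.frame of `level`,
#'   `duration_ms` plus attributes `total_duration_ms`, `seed`) and
#'   `recording` (a [recording()])
#' @export
simulate_single_channel <- function(model, open_rate, close_rate, duration,
                                    voltage = 80, noise_sd = 1, seed,
                                    sampling_hz = 1e4, filter_hz = 2900) {
  stopifnot(inherits(model, "channel_model"))
  if (!is.finite(open_rate) || open_rate <= 0 ||
      !is.finite(close_rate) || close_rate <= 0)
    stop("rates must be positive (1/ms)")
  if (duration <= 0) stop("duration must be positive (ms)")
  if (!is.null(filter_hz) && sampling_hz <= 2 * filter_hz)
    stop("configuration error: sampling rate must exceed 2 x filter corner")
  set.seed(seed)

  # Gillespie: draw the initial state from the stationary distribution,
  # then alternate exponential dwells, sampled in vectorized blocks
  po_stat <- open_rate / (open_rate + close_rate)
  first_open <- stats::runif(1) < po_stat
  cycle_ms <- 1 / open_rate + 1 / close_rate
  durs <- numeric(0)
  repeat {
    deficit <- duration - sum(durs)
    n_blk <- ceiling(2 * deficit / cycle_ms + 6 * sqrt(2 * deficit / cycle_ms)) + 16L
    start_open <- if (length(durs) %% 2 == 0) first_open else !first_open
    rates <- rep_len(if (start_open) c(close_rate, open_rate)
                     else c(open_rate, close_rate), n_blk)
    durs <- c(durs, stats::rexp(n_blk, rates))
    if (sum(durs) >= duration) break
  }
  cs <- cumsum(durs)
  k <- which(cs >= duration)[1]
  durs <- durs[seq_len(k)]
  durs[k] <- durs[k] - (cs[k] - duration)  # truncate final dwell
  is_open <- rep_len(if (first_open) c(TRUE, FALSE) else c(FALSE, TRUE), k)
  dwells <- data.frame(level = ifelse(is_open, "open", "closed"),
                       duration_ms = durs, stringsAsFactors = FALSE)
  attr(dwells, "total_duration_ms") <- duration
  attr(dwells, "seed") <- seed
  class(dwells) <- c("dwell_sequence", "data.frame")

  rec <- render_dwells(dwells, model = model, voltage = voltage,
                       noise_sd = noise_sd, sampling_hz = sampling_hz,
                       filter_hz = filter_hz, seed = seed)
  list(dwells = dwells, recording = rec)
}

#' Render a dwell sequence into a noisy sampled recording
#'
#' Exposed separately so idealization can be tested on noiseless renders of
#' arbitrary hand-built dwell sequences. Noise and filtering are skipped
#' when `noise_sd = 0` and `filter_hz = NULL` respectively.
#'
#' @inheritParams simulate_single_channel
#' @param dwells a `dwell_sequence` (data.frame of `level`, `duration_ms`)
#' @return a [recording()]
#' @export
render_dwells <- function(dwells, model, voltage = 80, noise_sd = 0,
                          sampling_hz = 1e4, filter_hz = 2900, seed = NA) {
  stopifnot(is.data.frame(dwells), all(dwells$duration_ms > 0))
  amp <- model$g * (voltage - model$E_rev) / 1000  # pA
  dt <- 1000 / sampling_hz                         # ms per sample
  total <- sum(dwells$duration_ms)
  n <- floor(total / dt)
  if (n < 1L) stop("empty trace: duration shorter than one sample")
  # floor convention: dwell i owns samples floor(b_i/dt) .. floor(b_{i+1}/dt)-1
  bounds <- cumsum(c(0, dwells$duration_ms))
  idx <- pmin(floor(bounds / dt), n)
  counts <- diff(idx)
  lev <- rep(dwells$level == "open", counts)
  x <- amp * as.numeric(lev)
  if (noise_sd > 0) {
    # noise drawn on its own sub-stream so a render is reproducible whether
    # called directly or from simulate_single_channel
    if (!is.na(seed)) set.seed(seed + 1L)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  if (!is.null(filter_hz)) x <- gaussian_lowpass(x, sampling_hz, filter_hz)
  recording(time_ms = (seq_len(n) - 1) * dt, current_pA = x,
            voltage_mV = voltage, sampling_hz = sampling_hz,
            filter_hz = if (is.null(filter_hz)) sampling_hz / 2 - 1 else filter_hz,
            seed = seed)
}

#' Simulate a concentration-response curve from the three-state model
#'
#' Responses are the equilibrium open probability [predict_po()] at each
#' concentration plus (optionally) additive Gaussian noise expressed as a
#' fraction of the saturating response. With `noise_sd = 0` the output
#' equals `predict_po` exactly.
#'
#' @param model a [channel_model()]
#' @param concentrations agonist concentrations, uM, sorted ascending
#' @param noise_sd noise SD as a fraction of Po_max (>= 0)
#' @param seed RNG seed
#' @param n number of patches recorded per concentration (metadata)
#' @return a [dose_response_curve()]
#' @export
simulate_dose_response <- function(model, concentrations, noise_sd = 0,
                                   seed = 1, n = 5) {
  if (length(concentrations) == 0L) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be sorted strictly ascending")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  po <- predict_po(model, concentrations)
  se <- rep(noise_sd * model$L / (1 + model$L), length(po))
  if (noise_sd > 0) {
    set.seed(seed)
    po <- po + stats::rnorm(length(po), 0, se)
  }
  dose_response_curve(concentrations, po, se = se, n = n)
}

#' Simulate a single-exponential tail current
#'
#' Noiseless decay `amplitude * exp(-t / tau)`, plus additive Gaussian
#' noise, on the standard acquisition grid. Used to exercise OFF-rate
#' fitting.
#'
#' @param amplitude initial current, pA (non-zero)
#' @param tau decay time constant, ms (> 0)
#' @param duration trace length, ms (> 0)
#' @param noise_sd additive noise SD, pA
#' @param seed RNG seed
#' @inheritParams simulate_single_channel
#' @return a [recording()]
#' @export
simulate_tail_current <- function(amplitude, tau, duration, noise_sd = 0,
                                  seed = 1, voltage = 80,
                                  sampling_hz = 1e4, filter_hz = 2900) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive (ms)")
  if (amplitude == 0) stop("amplitude must be non-zero")
  dt <- 1000 / sampling_hz
  n <- floor(duration / dt)
  if (n < 1L) stop("empty trace: duration shorter than one sample")
  t <- (seq_len(n) - 1) * dt
  x <- amplitude * exp(-t / tau)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  recording(t, x, voltage_mV = voltage, sampling_hz = sampling_hz,
            filter_hz = filter_hz, seed = seed)
}

#' Simulate a voltage-ramp current under GHK selectivity
#'
#' Linear conductor model I(V) = g_scale * (V - E_rev) with the reversal
#' potential computed from the extended GHK voltage equation for the given
#' permeability ratios and ionic conditions, so the noiseless zero crossing
#' sits exactly at the GHK reversal potential. The ramp spans `v_start` to
#' `v_end` over `duration` ms.
#'
#' @param perm_ratios named numeric vector of relative permeabilities
#'   (names matching `ions$species$name`)
#' @param ions an [ion_conditions()]
#' @param g_scale chord conductance, nS (I in pA for V in mV)
#' @param v_start,v_end,duration ramp specification (mV, mV, ms)
#' @param noise_sd additive Gaussian noise SD, pA
#' @param seed RNG seed
#' @inheritParams simulate_single_channel
#' @return a [recording()] whose `time_ms` column maps linearly onto the
#'   ramp voltage; attribute `erev_mV` records the generating reversal
#'   potential and `ramp` the (v_start, v_end) pair
#' @export
simulate_ramp_iv <- function(perm_ratios, ions, g_scale = 0.5,
                             v_start = -100, v_end = 100, duration = 500,
                             noise_sd = 0, seed = 1,
                             sampling_hz = 1e4, filter_hz = 2900) {
  if (all(perm_ratios == 0)) stop("degenerate conductor: all permeabilities zero")
  if (duration <= 0) stop("ramp duration must be positive")
  erev <- ghk_erev(perm_ratios, ions)
  dt <- 1000 / sampling_hz
  n <- floor(duration / dt)
  t <- (seq_len(n) - 1) * dt
  v <- v_start + (v_end - v_start) * t / duration
  x <- g_scale * (v - erev)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  rec <- recording(t, x, voltage_mV = NA, sampling_hz = sampling_hz,
                   filter_hz = filter_hz, seed = seed)
  attr(rec, "erev_mV") <- erev
  attr(rec, "ramp") <- c(v_start = v_start, v_end = v_end,
                         duration_ms = duration)
  rec
}

#' Convert a ramp recording to an I-V relation
#'
#' @param rec a recording produced by [simulate_ramp_iv()] (or any trace
#'   with a `ramp` attribute)
#' @return a `ramp_iv` data.frame with columns `voltage_mV`, `current_pA`
#' @export
as_ramp_iv <- function(rec) {
  ramp <- attr(rec, "ramp")
  if (is.null(ramp)) stop("recording carries no ramp attribute")
  v <- ramp[["v_start"]] + (ramp[["v_end"]] - ramp[["v_start"]]) *
    rec$time_ms / ramp[["duration_ms"]]
  out <- data.frame(voltage_mV = v, current_pA = rec$current_pA)
  class(out) <- c("ramp_iv", "data.frame")
  out
}
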