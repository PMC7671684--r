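# All-point amplitude histograms, double-Gaussian level fitting,
# half-amplitude threshold idealization with dead-time imposition, and the
# derived quantities (Po, single-channel amplitude, conductance).

#' All-point histogram and double-Gaussian level fit
#'
#' Builds the all-point amplitude histogram of a recording and fits the sum
#' of two Gaussian components to the bin counts by nonlinear least squares,
#' with moment-based initial guesses from a midrange split. The
#' single-channel current amplitude is the difference of the fitted means.
#' When the two midrange clusters are already (near-)degenerate in spread
#' (e.g. a noiseless two-level trace), the exact cluster means are returned
#' without iterative fitting.
#'
#' @param rec a [recording()]
#' @param n_bins number of histogram bins; `NULL` (default) uses the
#'   Freedman-Diaconis rule
#' @return list with `histogram` (data.frame `bin_mid`, `count`, plus
#'   `bin_edges` attribute) and `fit` (a `level_fit`: list with
#'   `closed_mean`, `open_mean`, `sds`, `weights`, `amplitude_pA`)
#' @export
amplitude_histogram_fit <- function(rec, n_bins = NULL) {
  x <- rec$current_pA
  if (length(x) < 10L) stop("too few samples for a histogram")
  if (is.null(n_bins)) {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)  # Freedman-Diaconis
    if (bw <= 0) bw <- diff(range(x)) / 50
    n_bins <- max(20L, min(400L, ceiling(diff(range(x)) / bw)))
  }
  if (n_bins < 20L) stop("n_bins must be >= 20")
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  edges[1] <- edges[1] - 1e-9; edges[n_bins + 1L] <- edges[n_bins + 1L] + 1e-9
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  histo <- data.frame(bin_mid = h$mids, count = h$counts)
  attr(histo, "bin_edges") <- edges

  # moment-based initialization from a midrange split
  thr0 <- mean(range(x))
  lo <- x[x <= thr0]; hi <- x[x > thr0]
  if (length(lo) < 2L || length(hi) < 2L)
    stop("degenerate-fit error: recording is unimodal (one level only)")
  m1 <- mean(lo); m2 <- mean(hi)
  s1 <- stats::sd(lo); s2 <- stats::sd(hi)
  w1 <- length(lo) / length(x)
  binw <- diff(edges[1:2])
  n_tot <- length(x)

  make_fit <- function(m1, m2, s1, s2, w1) {
    structure(list(closed_mean = m1, open_mean = m2,
                   sds = c(closed = s1, open = s2),
                   weights = c(closed = w1, open = 1 - w1),
                   amplitude_pA = m2 - m1),
              class = "level_fit")
  }

  if (max(s1, s2, na.rm = TRUE) < binw / 10 || s1 < 1e-12 || s2 < 1e-12) {
    # delta-like peaks: iterative fitting is ill-posed, exact means suffice
    fit <- make_fit(m1, m2, s1, s2, w1)
  } else {
    dat <- data.frame(mid = histo$bin_mid, cnt = histo$count)
    nls_fit <- safe_nlsLM(
      cnt ~ n_tot * binw * (w * stats::dnorm(mid, mu1, sg1) +
                              (1 - w) * stats::dnorm(mid, mu2, sg2)),
      data = dat,
      start = list(mu1 = m1, mu2 = m2, sg1 = s1, sg2 = s2, w = w1),
      lower = c(-Inf, -Inf, 1e-6, 1e-6, 1e-6),
      upper = c(Inf, Inf, Inf, Inf, 1 - 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nls_fit)
    # report components ordered so closed is the lower mean
    if (cf[["mu1"]] <= cf[["mu2"]])
      fit <- make_fit(cf[["mu1"]], cf[["mu2"]], cf[["sg1"]], cf[["sg2"]], cf[["w"]])
    else
      fit <- make_fit(cf[["mu2"]], cf[["mu1"]], cf[["sg2"]], cf[["sg1"]], 1 - cf[["w"]])
  }
  if (abs(fit$amplitude_pA) < 2 * max(fit$sds))
    stop("degenerate-fit error: level means separated by less than twice ",
         "the larger component SD (unimodal recording)")
  list(histogram = histo, fit = fit)
}

#' Idealize a recording by half-amplitude threshold crossing
#'
#' The detection threshold is the arithmetic midpoint of the fitted closed
#' and open means (the 50% amplitude rule). Threshold crossings segment the
#' trace into alternating events; events shorter than the dead time are
#' then merged into the enclosing level by a chronological shortest-first
#' re-scan until a fixed point is reached, which makes the merging order
#' deterministic and the operation idempotent.
#'
#' @param rec a [recording()]
#' @param levels a `level_fit` from [amplitude_histogram_fit()]
#' @param dead_time minimum resolvable event duration, ms (default 0.3)
#' @return an `event_list`: data.frame `start_ms`, `duration_ms`, `level`
#'   with attributes `dead_time_ms`, `total_time_ms`, `threshold_pA`
#' @export
idealize_events <- function(rec, levels, dead_time = 0.3) {
  stopifnot(inherits(levels, "level_fit"), dead_time >= 0)
  dt <- 1000 / attr(rec, "sampling_hz")
  total <- nrow(rec) * dt
  if (dead_time >= total / 2)
    stop("no-events error: dead time is at least half the trace duration")
  thr <- (levels$closed_mean + levels$open_mean) / 2
  is_open <- rec$current_pA > thr
  r <- rle(is_open)
  lev <- r$values
  dur <- r$lengths * dt
  merged <- merge_dead_time(lev, dur, dead_time)
  ev <- data.frame(start_ms = cumsum(c(0, merged$dur[-length(merged$dur)])),
                   duration_ms = merged$dur,
                   level = ifelse(merged$lev, "open", "closed"),
                   stringsAsFactors = FALSE)
  attr(ev, "dead_time_ms") <- dead_time
  attr(ev, "total_time_ms") <- total
  attr(ev, "threshold_pA") <- thr
  class(ev) <- c("event_list", "data.frame")
  ev
}

# shortest-first dead-time merging: repeatedly absorb the shortest
# sub-dead-time event into the enclosing level (ties broken
# chronologically), coalescing equal-level neighbours, until fixed point.
# Events strictly alternate, so absorbing interior event i always fuses
# i-1, i, i+1 into one event of the enclosing level.
merge_dead_time <- function(lev, dur, dead_time) {
  repeat {
    n <- length(dur)
    if (n <= 1L) break
    short <- which(dur < dead_time)
    if (length(short) == 0L) break
    i <- short[which.min(dur[short])]
    if (i == 1L) {
      dur[2L] <- dur[2L] + dur[1L]
      dur <- dur[-1L]; lev <- lev[-1L]
    } else if (i == n) {
      dur[n - 1L] <- dur[n - 1L] + dur[n]
      dur <- dur[-n]; lev <- lev[-n]
    } else {
      dur[i - 1L] <- dur[i - 1L] + dur[i] + dur[i + 1L]
      dur <- dur[-c(i, i + 1L)]; lev <- lev[-c(i, i + 1L)]
    }
  }
  list(lev = lev, dur = dur)
}

#' Open probability from an idealized event list
#'
#' Po is the pooled open time divided by the total analyzed time.
#'
#' @param events an `event_list` from [idealize_events()]
#' @return open probability in \[0, 1\]
#' @export
open_probability <- function(events) {
  if (is.null(events) || nrow(events) == 0L) stop("empty event list")
  total <- attr(events, "total_time_ms")
  if (is.null(total)) total <- sum(events$duration_ms)
  if (total <= 0) stop("non-positive total time")
  sum(events$duration_ms[events$level == "open"]) / total
}

#' Single-channel conductance from amplitude and driving force
#'
#' g = 1000 * i / (V - E_rev), with i in pA and V in mV giving g in pS.
#'
#' @param i single-channel current amplitude, pA
#' @param V test potential, mV
#' @param E_rev reversal potential, mV (default 0)
#' @return chord conductance, pS
#' @export
conductance <- function(i, V, E_rev = 0) {
  if (any(V == E_rev)) stop("V equals E_rev: driving force is zero")
  1000 * i / (V - E_rev)
}

#' Serialize an event list as TSV plus a JSON summary
#'
#' @param events an `event_list`
#' @param path TSV output path; the JSON summary is written alongside with
#'   extension `.json` unless `json_path` is given
#' @param i_pA,V_mV,E_rev_mV optional amplitude and potentials for the
#'   conductance entry of the summary
#' @param json_path optional explicit JSON path
#' @return invisible list of the two paths
#' @export
write_event_list <- function(events, path, i_pA = NA, V_mV = 80,
                             E_rev_mV = 0, json_path = NULL) {
  utils::write.table(
    data.frame(start_ms = events$start_ms,
               duration_ms = events$duration_ms, level = events$level),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", path)
  summary <- list(
    Po = open_probability(events),
    i_pA = i_pA,
    g_pS = if (is.na(i_pA)) NA else conductance(i_pA, V_mV, E_rev_mV),
    n_events = nrow(events),
    dead_time_ms = attr(events, "dead_time_ms"))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(tsv = path, json = json_path))
}
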