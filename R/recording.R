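#' A sampled current trace with acquisition metadata
#'
#' Recordings are data.frames with columns `time_ms` and `current_pA` on a
#' uniform sampling grid, carrying voltage, sampling rate, filter corner and
#' generator seed as attributes. The sampling rate must exceed twice the
#' filter corner (the acquisition convention of 10 kHz sampling with a
#' 2.9 kHz low-pass corner satisfies this).
#'
#' @param time_ms time grid, ms (uniform)
#' @param current_pA current samples, pA
#' @param voltage_mV holding/test potential, mV
#' @param sampling_hz sampling rate, Hz
#' @param filter_hz low-pass corner frequency, Hz
#' @param seed generator seed, or NA for real data
#' @return object of class `recording` (a data.frame)
#' @export
recording <- function(time_ms, current_pA, voltage_mV, sampling_hz,
                      filter_hz, seed = NA_integer_) {
  stopifnot(length(time_ms) == length(current_pA))
  if (length(time_ms) == 0L) stop("empty trace")
  if (length(time_ms) > 2L) {
    dt <- diff(time_ms)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("non-uniform sampling grid")
  }
  if (sampling_hz <= 2 * filter_hz)
    stop("configuration error: sampling rate must exceed 2 x filter corner")
  out <- data.frame(time_ms = time_ms, current_pA = current_pA)
  attr(out, "voltage_mV") <- voltage_mV
  attr(out, "sampling_hz") <- sampling_hz
  attr(out, "filter_hz") <- filter_hz
  attr(out, "seed") <- seed
  class(out) <- c("recording", "data.frame")
  out
}

#' Write / read a recording as annotated TSV
#'
#' The on-disk format is tab-separated `time_ms`, `current_pA` preceded by
#' `# key=value` comment lines carrying the acquisition metadata
#' (voltage_mV, sampling_hz, filter_hz, seed).
#'
#' @param rec a [recording()]
#' @param path file path
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("voltage_mV", "sampling_hz", "filter_hz", "seed"))
    writeLines(sprintf("# %s=%s", key, format(attr(rec, key), digits = 15)), con)
  writeLines("time_ms\tcurrent_pA", con)
  utils::write.table(format(as.data.frame(rec), digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
  }
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  recording(dat$time_ms, dat$current_pA,
            voltage_mV = meta$voltage_mV, sampling_hz = meta$sampling_hz,
            filter_hz = meta$filter_hz,
            seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}
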