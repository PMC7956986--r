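#' Construct an RR-interval series from beat times
#'
#' The RR series is the carrier of all HRV computation in this package: an
#' ordered set of heartbeat (R-peak) times together with the inter-beat
#' intervals (IBIs) they define. Intervals outside a physiologic gate are
#' flagged, never silently dropped, so that per-trial exclusion decisions
#' stay visible downstream.
#'
#' @param beat_times_s Numeric vector of strictly increasing beat times, in
#'   seconds.
#' @param gate_ms Length-2 numeric, the physiologic plausibility gate for an
#'   interval in milliseconds. Defaults to 300--2000 ms (200 down to 30 bpm);
#'   intervals outside it get `flagged = TRUE`.
#' @return A tibble of class `rr_series` with one row per beat:
#'   `beat_time_s`, `rr_ms` (interval ending at this beat; `NA` for the first
#'   beat) and `flagged` (logical, `NA` for the first beat).
#' @examples
#' rr_series(c(0, 1, 2, 3.1))
#' @export
rr_series <- function(beat_times_s, gate_ms = c(300, 2000)) {
  if (length(beat_times_s) < 2) {
    stop("an RR series needs at least 2 beat times", call. = FALSE)
  }
  if (anyNA(beat_times_s) || any(!is.finite(beat_times_s))) {
    stop("beat times must be finite", call. = FALSE)
  }
  if (any(diff(beat_times_s) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  rr <- c(NA_real_, diff(beat_times_s) * 1000)
  out <- tibble::tibble(
    beat_time_s = as.numeric(beat_times_s),
    rr_ms = rr,
    flagged = rr < gate_ms[1] | rr > gate_ms[2]
  )
  class(out) <- c("rr_series", class(out))
  attr(out, "gate_ms") <- gate_ms
  out
}

#' Inter-beat intervals of an RR series
#'
#' @param rr An `rr_series` (or anything with an `rr_ms` column).
#' @param drop_flagged Drop intervals outside the physiologic gate?
#' @return Numeric vector of intervals in ms (length = beats - 1 when nothing
#'   is flagged).
#' @export
rr_intervals <- function(rr, drop_flagged = FALSE) {
  x <- rr$rr_ms[-1]
  if (drop_flagged) x <- x[!rr$flagged[-1]]
  x
}

#' Extract inter-beat intervals from detected beat times
#'
#' Computes the R-R temporal differences for a set of beat times, the step
#' that turns a detector's output into the series HRV metrics are computed
#' on.
#'
#' @inheritParams rr_series
#' @return An `rr_series` tibble; see [rr_series()].
#' @examples
#' extract_ibis(c(0, 0.75, 1.60))$rr_ms  # NA, 750, 850
#' @export
extract_ibis <- function(beat_times_s, gate_ms = c(300, 2000)) {
  rr_series(beat_times_s, gate_ms = gate_ms)
}

#' Restrict an RR series to a timestamped epoch
#'
#' Keeps the beats whose times fall in the half-open window
#' `[start_s, start_s + duration_s)` and recomputes the intervals from the
#' retained beats only. The half-open convention prevents a boundary beat
#' from being counted in two adjacent epochs, and makes segmentation
#' idempotent. Epoch timestamps are trusted as exact; no re-alignment is
#' attempted.
#'
#' @param rr An `rr_series`.
#' @param start_s Window start, seconds.
#' @param duration_s Window length, seconds. The study design uses 3- or
#'   5-min epochs, so by default only 180 or 300 s are accepted; pass
#'   `allowed_durations = NULL` to lift the restriction.
#' @param allowed_durations Numeric vector of permitted `duration_s` values,
#'   or `NULL` for any positive duration.
#' @return An `rr_series` for the window.
#' @export
segment_by_timestamps <- function(rr, start_s, duration_s,
                                  allowed_durations = c(180, 300)) {
  stopifnot(is.numeric(start_s), is.numeric(duration_s), duration_s > 0)
  if (!is.null(allowed_durations) && !duration_s %in% allowed_durations) {
    stop(
      "duration_s = ", duration_s, " is not one of the allowed epoch ",
      "lengths (", paste(allowed_durations, collapse = ", "),
      "); pass allowed_durations = NULL to override",
      call. = FALSE
    )
  }
  keep <- rr$beat_time_s >= start_s & rr$beat_time_s < start_s + duration_s
  if (sum(keep) < 2) {
    stop("epoch window contains fewer than 2 beats", call. = FALSE)
  }
  rr_series(rr$beat_time_s[keep], gate_ms = attr(rr, "gate_ms") %||% c(300, 2000))
}

#' Read / write RR series as two-column CSV
#'
#' The on-disk interchange format is a plain CSV with columns `beat_time_s`
#' and `rr_ms` (the first row's `rr_ms` is empty).
#'
#' @param rr An `rr_series`.
#' @param path File path.
#' @return `write_rr_csv()` returns `path` invisibly; `read_rr_csv()` returns
#'   an `rr_series`.
#' @export
write_rr_csv <- function(rr, path) {
  readr::write_csv(rr[, c("beat_time_s", "rr_ms")], path)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"beat_time_s" %in% names(df)) {
    stop("RR CSV must have a beat_time_s column", call. = FALSE)
  }
  rr_series(df$beat_time_s)
}
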