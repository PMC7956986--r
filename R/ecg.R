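#' Construct an ECG record
#'
#' @param samples_mv Numeric voltage samples in mV.
#' @param fs_hz Sampling rate in Hz (the reference recorder in the emulated
#'   study runs at 512 Hz).
#' @param start_time_s Recording clock offset of the first sample.
#' @param truth_beat_idx Optional integer vector of ground-truth beat sample
#'   indices (1-based), carried along by the renderer for round-trip tests.
#' @return A tibble of class `ecg_record` with columns `time_s`, `mv`.
#' @export
ecg_record <- function(samples_mv, fs_hz = 512, start_time_s = 0,
                       truth_beat_idx = NULL) {
  stopifnot(fs_hz > 0, is.numeric(samples_mv))
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(samples_mv) - 1) / fs_hz,
    mv = as.numeric(samples_mv)
  )
  class(out) <- c("ecg_record", class(out))
  attr(out, "fs_hz") <- fs_hz
  attr(out, "truth_beat_idx") <- truth_beat_idx
  out
}

# Ricker (Mexican-hat) wavelet, peak amplitude 1 at t = 0.
ricker <- function(t, a) (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))

#' Render a synthetic ECG from an RR series
#'
#' Places one QRS-like template at each beat time of the RR series on a
#' uniform sampling grid and adds white Gaussian noise at the requested
#' signal-to-noise ratio. The template is a Ricker (Mexican-hat) wavelet of
#' 80 ms nominal width and 1 mV peak amplitude -- a sharp biphasic shape
#' adequate for exercising peak detection; no attempt is made to reproduce
#' P or T waves. A single channel stands in for a multi-lead montage, since
#' lead placement is physical rather than computational.
#'
#' @param rr An `rr_series`.
#' @param fs_hz Sampling rate, Hz; must be at least 128 so the template is
#'   adequately sampled.
#' @param snr_db Signal-to-noise ratio in dB (power ratio of the clean
#'   rendered signal to the added noise); `Inf` adds no noise.
#' @param template_width_s Nominal QRS width in seconds (the Ricker scale is
#'   a quarter of this).
#' @param seed Seed for the noise draw.
#' @return An `ecg_record`; ground-truth beat sample indices are attached as
#'   the `truth_beat_idx` attribute.
#' @export
render_ecg <- function(rr, fs_hz = 512, snr_db = Inf,
                       template_width_s = 0.080, seed = 1L) {
  stopifnot(nrow(rr) >= 2)
  if (fs_hz < 128) {
    stop("fs_hz = ", fs_hz, " is too low to represent the QRS template; ",
         "use at least 128 Hz", call. = FALSE)
  }
  a <- template_width_s / 4
  t_end <- rr$beat_time_s[nrow(rr)] + template_width_s
  n <- ceiling(t_end * fs_hz)
  tt <- (seq_len(n) - 1) / fs_hz
  x <- numeric(n)
  half <- ceiling(3 * a * fs_hz)
  for (bt in rr$beat_time_s) {
    c_idx <- round(bt * fs_hz) + 1
    lo <- max(1, c_idx - half)
    hi <- min(n, c_idx + half)
    x[lo:hi] <- x[lo:hi] + ricker(tt[lo:hi] - bt, a)
  }
  truth_idx <- round(rr$beat_time_s * fs_hz) + 1L
  if (is.finite(snr_db)) {
    p_sig <- mean(x^2)
    sd_n <- sqrt(p_sig / 10^(snr_db / 10))
    set.seed(as.integer(seed))
    x <- x + stats::rnorm(n, 0, sd_n)
  }
  ecg_record(x, fs_hz = fs_hz, truth_beat_idx = truth_idx)
}

#' Detect R peaks in an ECG record
#'
#' A Pan-Tompkins style QRS detector: zero-phase band-pass (5--15 Hz),
#' differentiation, squaring, 150 ms moving-window integration, then
#' adaptive dual thresholds on the integrated signal with a 200 ms
#' refractory period and a search-back pass at half threshold when the
#' running RR estimate suggests a missed beat. Each accepted detection is
#' refined to the local extremum of the band-passed signal in a window
#' around it, so reported peak times align with the R wave rather than the
#' integration envelope. Detection is invariant to DC offset (removed by
#' the band-pass).
#'
#' @param ecg An `ecg_record` of at least 2 s.
#' @param refractory_s Minimum inter-peak distance, seconds.
#' @return Numeric vector of strictly increasing peak times in seconds
#'   (empty, with a warning, when nothing crosses threshold).
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.200) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- attr(ecg, "fs_hz")
  x <- ecg$mv
  if (anyNA(x) || any(!is.finite(x))) {
    stop("ECG samples must be finite", call. = FALSE)
  }
  if (length(x) < 2 * fs) {
    stop("record must be at least 2 s long for detection", call. = FALSE)
  }

  # band-pass 5-15 Hz, zero phase so peak times stay aligned
  ny <- fs / 2
  bf <- signal::butter(2, c(5, 15) / ny, type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))

  dx <- c(0, diff(xf)) * fs
  sq <- dx^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  if (max(mwi) <= 0) {
    warning("no QRS candidates found; returning no peaks")
    return(numeric(0))
  }

  # candidate local maxima of the integrated signal
  is_pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (length(is_pk) == 0) {
    warning("no QRS candidates found; returning no peaks")
    return(numeric(0))
  }

  refr <- round(refractory_s * fs)
  spki <- max(mwi[seq_len(min(length(mwi), 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(length(mwi), 2 * fs))]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  recent_rr <- numeric(0)
  last <- -Inf
  i <- 1
  while (i <= length(is_pk)) {
    p <- is_pk[i]
    v <- mwi[p]
    if (p - last >= refr && v > thr1) {
      peaks <- c(peaks, p)
      if (length(peaks) > 1) {
        recent_rr <- utils::tail(c(recent_rr, p - last), 8)
      }
      last <- p
      spki <- 0.125 * v + 0.875 * spki
    } else if (v > thr1 && p - last < refr) {
      # refractory: keep the larger of the two
      if (v > mwi[last]) {
        peaks[length(peaks)] <- p
        last <- p
        spki <- 0.125 * v + 0.875 * spki
      }
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: expected beat overdue at half threshold
      if (length(recent_rr) >= 2) {
        rr_avg <- mean(recent_rr)
        if (p - last > 1.66 * rr_avg) {
          win <- is_pk[is_pk > last + refr & is_pk < p]
          if (length(win)) {
            cand <- win[which.max(mwi[win])]
            if (mwi[cand] > 0.5 * thr1) {
              peaks <- c(peaks, cand)
              recent_rr <- utils::tail(c(recent_rr, cand - last), 8)
              last <- cand
              spki <- 0.125 * mwi[cand] + 0.875 * spki
            }
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1
  }
  if (length(peaks) == 0) {
    warning("no peaks crossed the adaptive threshold")
    return(numeric(0))
  }

  # refine: local max of band-passed signal within the integration lag
  half_w <- w
  refined <- vapply(peaks, function(p) {
    lo <- max(1, p - half_w)
    hi <- min(length(xf), p)
    lo - 1L + which.max(xf[lo:hi])
  }, numeric(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  refined <- refined[keep]
  ecg$time_s[refined]
}

#' Read / write an ECG record as CSV
#'
#' Plain two-column interchange (`time_s`, `mv`); the sampling rate is
#' recovered from the time grid on read.
#'
#' @param ecg An `ecg_record`.
#' @param path File path.
#' @export
write_ecg_csv <- function(ecg, path) {
  readr::write_csv(ecg[, c("time_s", "mv")], path)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time_s", "mv") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  ecg_record(df$mv, fs_hz = fs, start_time_s = df$time_s[1])
}
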