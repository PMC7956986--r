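#' Configuration for the ground-truth RR generator
#'
#' The generator uses a direct modulation model: the interval ending a beat
#' at time `t` is
#' `RR(t) = base + lf sin(2 pi f_lf t) + hf sin(2 pi f_hf t) +
#'  vlf sin(2 pi f_vlf t) + e`, `e ~ N(0, jitter_sd^2)`,
#' with `base = 60000 / mean_hr_bpm`. This is the simplest model whose rMSSD
#' has a closed form (see [simulate_rr_series()]), which is what makes the
#' target calibratable; it is not an integral-pulse-frequency model and does
#' not claim physiological realism beyond band structure.
#'
#' @param duration_s Length of the series, seconds.
#' @param mean_hr_bpm Target mean heart rate, beats/min, in (30, 220).
#' @param rmssd_target_ms Target rMSSD in ms, or `NULL` to use the
#'   amplitudes as given without calibration.
#' @param lf_amp_ms,hf_amp_ms Low- and high-frequency sinusoidal modulation
#'   amplitudes, ms.
#' @param lf_freq_hz,hf_freq_hz Modulation frequencies, Hz (defaults 0.10
#'   and 0.25, the centres of the LF and HF HRV bands).
#' @param vlf_drift_ms,vlf_freq_hz Slow-trend amplitude (ms) and frequency
#'   (Hz); emulates the very-low-frequency drift that detrending removes.
#' @param jitter_sd_ms White beat-to-beat component, ms.
#' @param seed Integer seed; identical configs with identical seeds give
#'   bitwise-identical series.
#' @return A list of class `rr_truth_config`.
#' @export
rr_truth_config <- function(duration_s = 300, mean_hr_bpm = 60,
                            rmssd_target_ms = 50,
                            lf_amp_ms = 10, hf_amp_ms = 20,
                            lf_freq_hz = 0.10, hf_freq_hz = 0.25,
                            vlf_drift_ms = 15, vlf_freq_hz = 0.015,
                            jitter_sd_ms = 10, seed = 1L) {
  stopifnot(duration_s > 0,
            mean_hr_bpm >= 30, mean_hr_bpm <= 220,
            lf_amp_ms >= 0, hf_amp_ms >= 0, vlf_drift_ms >= 0,
            jitter_sd_ms >= 0,
            is.null(rmssd_target_ms) || rmssd_target_ms >= 0)
  structure(
    list(duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
         rmssd_target_ms = rmssd_target_ms,
         lf_amp_ms = lf_amp_ms, hf_amp_ms = hf_amp_ms,
         lf_freq_hz = lf_freq_hz, hf_freq_hz = hf_freq_hz,
         vlf_drift_ms = vlf_drift_ms, vlf_freq_hz = vlf_freq_hz,
         jitter_sd_ms = jitter_sd_ms, seed = as.integer(seed)),
    class = "rr_truth_config"
  )
}

# Closed-form rMSSD of the modulation model. A sinusoid of amplitude A and
# frequency f sampled at beats ~T_bar seconds apart contributes
# 2 A^2 sin^2(pi f T_bar) to the mean squared successive difference
# (uniform-phase average); independent white jitter contributes 2 sigma^2.
closed_form_rmssd <- function(cfg, scale = 1) {
  t_bar <- 60 / cfg$mean_hr_bpm
  sin_term <- function(amp, f) 2 * amp^2 * sin(pi * f * t_bar)^2
  fixed <- sin_term(cfg$lf_amp_ms, cfg$lf_freq_hz) +
    sin_term(cfg$vlf_drift_ms, cfg$vlf_freq_hz)
  scaled <- 2 * cfg$jitter_sd_ms^2 + sin_term(cfg$hf_amp_ms, cfg$hf_freq_hz)
  sqrt(fixed + scale^2 * scaled)
}

#' Simulate a ground-truth RR-interval series
#'
#' Generates beat times by iterating the modulation model of
#' [rr_truth_config()]. When `rmssd_target_ms` is set, the high-frequency
#' amplitude and white-jitter SD are jointly rescaled by a factor found by
#' bisection against the model's closed-form rMSSD, so that the realized
#' rMSSD lands near the target (within about 10% across seeds); the LF and
#' VLF components are left untouched, since they represent trend rather than
#' beat-to-beat variability. An unreachable target (the untouched components
#' alone already exceed it, or the scalable components are all zero) raises
#' a calibration-failure error.
#'
#' @param config An [rr_truth_config()].
#' @return An `rr_series` starting at time 0 and spanning approximately
#'   `duration_s`.
#' @export
simulate_rr_series <- function(config) {
  stopifnot(inherits(config, "rr_truth_config"))
  cfg <- config
  if (!is.null(cfg$rmssd_target_ms)) {
    target <- cfg$rmssd_target_ms
    fixed <- closed_form_rmssd(cfg, scale = 0)
    if (fixed > target * 1.0000001) {
      stop("calibration failure: LF/VLF components alone give rMSSD ",
           signif(fixed, 4), " ms, above the target ", target, " ms",
           call. = FALSE)
    }
    scalable <- closed_form_rmssd(cfg, scale = 1)^2 - fixed^2
    if (target > fixed && scalable <= 0) {
      stop("calibration failure: no HF or jitter component to scale ",
           "toward the rMSSD target", call. = FALSE)
    }
    scale <- 0
    if (target > fixed) {
      hi <- 1
      while (closed_form_rmssd(cfg, hi) < target) {
        hi <- hi * 2
        if (hi > 1e6) stop("calibration failure: rMSSD target unreachable",
                           call. = FALSE)
      }
      scale <- stats::uniroot(
        function(s) closed_form_rmssd(cfg, s) - target,
        lower = 0, upper = hi, tol = 1e-10
      )$root
    }
    cfg$hf_amp_ms <- cfg$hf_amp_ms * scale
    cfg$jitter_sd_ms <- cfg$jitter_sd_ms * scale
  }

  base_ms <- 60000 / cfg$mean_hr_bpm
  n_max <- ceiling(cfg$duration_s / (base_ms / 1000)) + 50
  set.seed(cfg$seed)
  eps <- stats::rnorm(n_max, 0, cfg$jitter_sd_ms)
  times <- numeric(n_max)
  t <- 0
  i <- 1
  times[1] <- 0
  while (t < cfg$duration_s && i < n_max) {
    rr_ms <- base_ms +
      cfg$lf_amp_ms * sin(2 * pi * cfg$lf_freq_hz * t) +
      cfg$hf_amp_ms * sin(2 * pi * cfg$hf_freq_hz * t) +
      cfg$vlf_drift_ms * sin(2 * pi * cfg$vlf_freq_hz * t) +
      eps[i]
    rr_ms <- max(rr_ms, 250)  # hard floor: keep the series monotone
    t <- t + rr_ms / 1000
    i <- i + 1
    times[i] <- t
  }
  beat_times <- times[seq_len(i)]
  if (length(beat_times) < 2) {
    stop("configuration produced fewer than 2 beats", call. = FALSE)
  }
  rr_series(beat_times)
}

#' Error model for a simulated commercial device
#'
#' Describes how a commercial off-the-shelf (COTS) device corrupts the true
#' cardiac signal before reporting its summary values. Beat-level corruption
#' (timing jitter, missed and spurious beats) is applied first to a copy of
#' the truth series; the device's summary HR and rMSSD are then recomputed
#' from the corrupted series, and finally the summary-level errors
#' (proportional noise, additive bias, integer rounding) are applied. The
#' order is fixed so it is testable.
#'
#' @param label Device identifier string.
#' @param additive_hr_bias_bpm,additive_rmssd_bias_ms Systematic offsets
#'   added to the reported summaries.
#' @param proportional_noise_cv Coefficient of variation of multiplicative
#'   reading noise. A single number applies to both metrics; a named vector
#'   `c(hr = ..., rmssd = ...)` sets them separately (typical for PPG apps,
#'   whose rMSSD error far exceeds their HR error).
#' @param beat_jitter_sd_ms SD of Gaussian timing noise on detected beats.
#' @param missed_beat_prob,extra_beat_prob Per-beat probabilities of
#'   dropping a true beat or inserting a spurious one.
#' @param epoch_s Device recording window, 180 or 300 s.
#' @param reports_min_hr_not_mean Device reports minimum (not mean) HR over
#'   its window, as ring-type devices do; such devices are excluded from
#'   mean-HR comparisons downstream.
#' @param hr_integer_rounding Device rounds HR to whole bpm.
#' @return A list of class `device_error_model`.
#' @export
device_error_model <- function(label,
                               additive_hr_bias_bpm = 0,
                               additive_rmssd_bias_ms = 0,
                               proportional_noise_cv = 0,
                               beat_jitter_sd_ms = 0,
                               missed_beat_prob = 0,
                               extra_beat_prob = 0,
                               epoch_s = 300,
                               reports_min_hr_not_mean = FALSE,
                               hr_integer_rounding = FALSE) {
  cv <- proportional_noise_cv
  if (length(cv) == 1 && is.null(names(cv))) cv <- c(hr = cv, rmssd = cv)
  stopifnot(all(c("hr", "rmssd") %in% names(cv)), all(cv >= 0),
            missed_beat_prob >= 0, missed_beat_prob <= 1,
            extra_beat_prob >= 0, extra_beat_prob <= 1,
            epoch_s %in% c(180, 300))
  structure(
    list(label = label,
         additive_hr_bias_bpm = additive_hr_bias_bpm,
         additive_rmssd_bias_ms = additive_rmssd_bias_ms,
         proportional_noise_cv = cv,
         beat_jitter_sd_ms = beat_jitter_sd_ms,
         missed_beat_prob = missed_beat_prob,
         extra_beat_prob = extra_beat_prob,
         epoch_s = epoch_s,
         reports_min_hr_not_mean = reports_min_hr_not_mean,
         hr_integer_rounding = hr_integer_rounding),
    class = "device_error_model"
  )
}

#' Default seven-device panel
#'
#' A panel of seven device error models emulating the mix of chest-strap
#' ECG, finger-camera PPG and ring devices a resting-state validation study
#' compares. Biases and noise levels are chosen to span the spectrum from a
#' near-perfect chest strap (small HR error, moderate rMSSD error, integer
#' HR rounding) to a camera-PPG app whose rMSSD error exceeds 100%; one
#' ring-type member reports minimum rather than mean HR over a 5-min window
#' and so drops out of mean-HR comparisons. All panel members use
#' summary-level error only (no beat corruption) by default.
#'
#' @return Named list of [device_error_model()] objects.
#' @export
cots_device_panel <- function() {
  panel <- list(
    device_error_model("FSTBT",
      additive_hr_bias_bpm = 0, additive_rmssd_bias_ms = -7.4,
      proportional_noise_cv = c(hr = 0, rmssd = 0.22),
      epoch_s = 180, hr_integer_rounding = TRUE),
    device_error_model("ELT/ECG",
      additive_hr_bias_bpm = -0.32, additive_rmssd_bias_ms = -7.0,
      proportional_noise_cv = c(hr = 0.013, rmssd = 0.24),
      epoch_s = 300, hr_integer_rounding = TRUE),
    device_error_model("HRV4TR/ECG",
      additive_hr_bias_bpm = -0.97, additive_rmssd_bias_ms = -0.74,
      proportional_noise_cv = c(hr = 0.017, rmssd = 0.075),
      epoch_s = 300),
    device_error_model("ELT/PPG",
      additive_hr_bias_bpm = 0.34, additive_rmssd_bias_ms = 3.6,
      proportional_noise_cv = c(hr = 0.021, rmssd = 0.13),
      epoch_s = 300, hr_integer_rounding = TRUE),
    device_error_model("HRV4TR/PPG",
      additive_hr_bias_bpm = -0.10, additive_rmssd_bias_ms = 3.0,
      proportional_noise_cv = c(hr = 0.025, rmssd = 0.23),
      epoch_s = 300),
    device_error_model("CAMHRV",
      additive_hr_bias_bpm = 11.14, additive_rmssd_bias_ms = 78.3,
      proportional_noise_cv = c(hr = 0.15, rmssd = 1.19),
      epoch_s = 180),
    device_error_model("OURA",
      additive_hr_bias_bpm = 0, additive_rmssd_bias_ms = -2.33,
      proportional_noise_cv = c(hr = 0.02, rmssd = 0.13),
      epoch_s = 300, reports_min_hr_not_mean = TRUE,
      hr_integer_rounding = TRUE)
  )
  stats::setNames(panel, vapply(panel, `[[`, "", "label"))
}

#' Simulate a device's summary reading from the true RR series
#'
#' Applies the device's beat-level corruption to a copy of the truth series
#' truncated to its epoch, recomputes the summary metrics with the package's
#' own HRV operations, then applies summary-level errors. The truth series
#' is never modified.
#'
#' @param rr_truth An `rr_series` spanning at least `model$epoch_s`.
#' @param model A [device_error_model()].
#' @param seed Integer seed for the corruption draws.
#' @param detrend [detrend_config()] used for the device rMSSD computation.
#' @return One-row tibble: `device_label`, `hr_bpm`, `hr_is_min`,
#'   `rmssd_ms`, `epoch_s`.
#' @export
simulate_device_reading <- function(rr_truth, model, seed = 1L,
                                    detrend = detrend_config()) {
  stopifnot(inherits(model, "device_error_model"))
  t0 <- rr_truth$beat_time_s[1]
  span <- rr_truth$beat_time_s[nrow(rr_truth)] - t0
  if (span < model$epoch_s) {
    stop("truth series spans ", round(span, 1), " s, shorter than the ",
         "device epoch of ", model$epoch_s, " s", call. = FALSE)
  }
  rr <- segment_by_timestamps(rr_truth, t0, model$epoch_s,
                              allowed_durations = NULL)
  set.seed(as.integer(seed))
  times <- rr$beat_time_s
  # beat-level corruption: jitter, missed, extra
  if (model$beat_jitter_sd_ms > 0) {
    times <- sort(times + stats::rnorm(length(times), 0,
                                       model$beat_jitter_sd_ms / 1000))
  }
  if (model$missed_beat_prob > 0 && length(times) > 2) {
    interior <- seq(2, length(times) - 1)
    drop <- interior[stats::runif(length(interior)) < model$missed_beat_prob]
    if (length(drop)) times <- times[-drop]
  }
  if (model$extra_beat_prob > 0) {
    mids <- (times[-1] + times[-length(times)]) / 2
    add <- mids[stats::runif(length(mids)) < model$extra_beat_prob]
    if (length(add)) times <- sort(c(times, add))
  }
  rr_dev <- rr_series(times)

  hr <- if (model$reports_min_hr_not_mean) min_hr(rr_dev) else mean_hr(rr_dev)
  rm <- rmssd(rr_dev, detrend)

  cv <- model$proportional_noise_cv
  hr <- hr * (1 + cv[["hr"]] * stats::rnorm(1)) + model$additive_hr_bias_bpm
  rm <- rm * (1 + cv[["rmssd"]] * stats::rnorm(1)) +
    model$additive_rmssd_bias_ms
  rm <- max(rm, 0)
  if (model$hr_integer_rounding) hr <- round(hr)

  tibble::tibble(
    device_label = model$label,
    hr_bpm = hr,
    hr_is_min = model$reports_min_hr_not_mean,
    rmssd_ms = rm,
    epoch_s = model$epoch_s
  )
}

#' Study design for the synthetic validation study
#'
#' Defines the shape of the simulated study: number of subjects, total
#' trials, the device panel, the between- and within-subject distributions
#' of resting heart rate and rMSSD, and the master seed everything derives
#' from. Defaults emulate a small resting-state validation study: 5 healthy
#' young adults, 148 trials total, a 7-device panel. Per-device trial counts
#' are not published by such studies; the default allocation gives the
#' larger shares to 3-min and ring devices (which accumulate trials faster)
#' and splits the remainder nearly equally.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_total Total trials across devices.
#' @param device_panel Named list of [device_error_model()]s.
#' @param allocation Optional named integer vector of trials per device
#'   label, summing to `n_trials_total`; `NULL` uses the default scheme.
#' @param hr_mean_bpm,hr_between_sd_bpm Population mean and between-subject
#'   SD of resting HR.
#' @param rmssd_mean_ms,rmssd_between_sd_ms Same for resting rMSSD.
#' @param hr_within_sd_bpm,rmssd_within_sd_ms Trial-to-trial (within
#'   subject) SDs.
#' @param master_seed Integer master seed.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_subjects = 5, n_trials_total = 148,
                         device_panel = cots_device_panel(),
                         allocation = NULL,
                         hr_mean_bpm = 65, hr_between_sd_bpm = 7,
                         rmssd_mean_ms = 60, rmssd_between_sd_ms = 18,
                         hr_within_sd_bpm = 3, rmssd_within_sd_ms = 8,
                         master_seed = 20260101L) {
  stopifnot(n_trials_total >= n_subjects, length(device_panel) >= 1)
  labels <- vapply(device_panel, `[[`, "", "label")
  if (is.null(allocation)) {
    allocation <- default_allocation(labels, n_trials_total)
  }
  if (sum(allocation) != n_trials_total ||
      !setequal(names(allocation), labels)) {
    stop("allocation must cover exactly the panel labels and sum to ",
         "n_trials_total", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_trials_total = n_trials_total,
         device_panel = device_panel, allocation = allocation,
         hr_mean_bpm = hr_mean_bpm, hr_between_sd_bpm = hr_between_sd_bpm,
         rmssd_mean_ms = rmssd_mean_ms,
         rmssd_between_sd_ms = rmssd_between_sd_ms,
         hr_within_sd_bpm = hr_within_sd_bpm,
         rmssd_within_sd_ms = rmssd_within_sd_ms,
         master_seed = as.integer(master_seed)),
    class = "study_design"
  )
}

# Near-equal split with the 3-min / ring devices taking the extra trials
# (they accumulate trials faster in a fixed-length session).
default_allocation <- function(labels, n_total) {
  k <- length(labels)
  base <- n_total %/% k
  alloc <- stats::setNames(rep(base, k), labels)
  short <- c("FSTBT", "CAMHRV", "OURA")
  extra_order <- c(intersect(short, labels), setdiff(labels, short))
  rem <- n_total - base * k
  i <- 1
  while (rem > 0) {
    alloc[extra_order[(i - 1) %% k + 1]] <-
      alloc[extra_order[(i - 1) %% k + 1]] + 1
    rem <- rem - 1
    i <- i + 1
  }
  alloc
}

#' Generate the full synthetic trial dataset
#'
#' Draws per-subject resting HR and rMSSD from the between-subject
#' distributions, assigns trials to devices per the allocation and to
#' subjects in rotation, simulates each trial's ground-truth RR series and
#' the paired device reading, and returns everything as one tidy table.
#' Fully reproducible from `master_seed`.
#'
#' @param design A [study_design()].
#' @return A tibble of class `trial_dataset`, one row per trial:
#'   `trial_id`, `subject_id`, `device_label`, `epoch_start_s`, `epoch_s`,
#'   device reading columns (`hr_bpm`, `hr_is_min`, `rmssd_ms`) and the
#'   ground-truth series in the list-column `rr_truth`.
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$master_seed)
  subj <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(design$n_subjects)),
    hr_bpm = stats::rnorm(design$n_subjects, design$hr_mean_bpm,
                          design$hr_between_sd_bpm),
    rmssd_ms = pmax(stats::rnorm(design$n_subjects, design$rmssd_mean_ms,
                                 design$rmssd_between_sd_ms), 15)
  )
  labels <- rep(names(design$allocation), design$allocation)
  n <- length(labels)
  subject_ids <- subj$subject_id[((seq_len(n) - 1) %% design$n_subjects) + 1]
  trial_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)

  rows <- purrr::map(seq_len(n), function(i) {
    model <- design$device_panel[[labels[i]]]
    s <- subj[subj$subject_id == subject_ids[i], ]
    hr_i <- min(max(s$hr_bpm + stats::rnorm(1, 0, design$hr_within_sd_bpm),
                    40), 120)
    rm_i <- max(s$rmssd_ms + stats::rnorm(1, 0, design$rmssd_within_sd_ms),
                10)
    cfg <- rr_truth_config(duration_s = model$epoch_s + 10,
                           mean_hr_bpm = hr_i, rmssd_target_ms = rm_i,
                           seed = trial_seeds[2 * i - 1])
    truth <- simulate_rr_series(cfg)
    reading <- simulate_device_reading(truth, model,
                                       seed = trial_seeds[2 * i])
    tibble::tibble(
      trial_id = sprintf("T%03d", i),
      subject_id = subject_ids[i],
      device_label = labels[i],
      epoch_start_s = 0,
      epoch_s = model$epoch_s,
      hr_bpm = reading$hr_bpm,
      hr_is_min = reading$hr_is_min,
      rmssd_ms = reading$rmssd_ms,
      rr_truth = list(truth)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trial_dataset", class(out))
  attr(out, "master_seed") <- design$master_seed
  out
}
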