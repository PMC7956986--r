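`%||%` <- function(x, y) if (is.null(x)) y else x

# Build an rr_series directly from a vector of intervals (ms), first beat at 0.
rr_from_intervals <- function(rr_ms) {
  rr_series(cumsum(c(0, rr_ms)) / 1000)
}

# Brute-force loop oracle for rMSSD, kept deliberately naive.
naive_rmssd <- function(x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n - 1)) acc <- acc + (x[i + 1] - x[i])^2
  sqrt(acc / (n - 1))
}

# A quick calibrated truth series for pipeline-level tests.
quick_truth <- function(seed, duration_s = 190, hr = 65, rmssd_ms = 50) {
  simulate_rr_series(rr_truth_config(
    duration_s = duration_s, mean_hr_bpm = hr, rmssd_target_ms = rmssd_ms,
    seed = seed
  ))
}

# Assemble a trial_dataset by simulating `n` trials of one device model.
make_trials <- function(model, n, seed0 = 1000, hr = 65, rmssd_ms = 50,
                        duration_s = NULL) {
  dur <- duration_s %||% (model$epoch_s + 10)
  rows <- lapply(seq_len(n), function(i) {
    truth <- quick_truth(seed0 + 2 * i, duration_s = dur, hr = hr,
                         rmssd_ms = rmssd_ms)
    reading <- simulate_device_reading(truth, model, seed = seed0 + 2 * i + 1)
    tibble::tibble(
      trial_id = sprintf("T%04d", i), subject_id = "S01",
      device_label = model$label, epoch_start_s = 0,
      epoch_s = model$epoch_s, hr_bpm = reading$hr_bpm,
      hr_is_min = reading$hr_is_min, rmssd_ms = reading$rmssd_ms,
      rr_truth = list(truth)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trial_dataset", class(out))
  out
}
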