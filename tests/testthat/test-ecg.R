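test_that("rendering places one template per beat on the sample grid", {
  rr <- rr_from_intervals(rep(1000, 10))  # beats at 0..10 s
  ecg <- render_ecg(rr, fs_hz = 512, snr_db = Inf)
  expect_equal(attr(ecg, "fs_hz"), 512)
  n_expected <- ceiling((10 + 0.080) * 512)
  expect_equal(nrow(ecg), n_expected)
  idx <- attr(ecg, "truth_beat_idx")
  expect_equal(idx, round(rr$beat_time_s * 512) + 1L)
  # clean signal: every interior truth index is a local maximum ~1 mV
  interior <- idx[idx > 30 & idx < nrow(ecg) - 30]
  expect_true(all(abs(ecg$mv[interior] - 1) < 1e-6))
})

test_that("rendering refuses a sampling rate too low for the template", {
  rr <- rr_from_intervals(rep(1000, 5))
  expect_error(render_ecg(rr, fs_hz = 64), "too low")
})

test_that("clean 60 bpm render is re-detected beat for beat", {
  rr <- rr_from_intervals(rep(1000, 60))
  ecg <- render_ecg(rr, fs_hz = 512, snr_db = Inf)
  pk <- detect_r_peaks(ecg)
  expect_true(abs(length(pk) - nrow(rr)) <= 1)
  err <- vapply(pk, function(p) min(abs(rr$beat_time_s - p)), numeric(1))
  expect_true(all(err <= 0.010))
})

test_that("re-detected intervals match the generator to sample resolution", {
  rr <- quick_truth(21, duration_s = 60)
  ecg <- render_ecg(rr, fs_hz = 512, snr_db = Inf)
  pk <- detect_r_peaks(ecg)
  expect_equal(length(pk), nrow(rr))
  rr2 <- extract_ibis(pk)
  # per-interval agreement within +/- 2 sample periods (one per endpoint)
  expect_true(all(abs(rr_intervals(rr2) - rr_intervals(rr)) <=
                    2 * 1000 / 512 + 1e-9))
})

test_that("an all-zero signal yields zero peaks with a warning", {
  ecg <- ecg_record(rep(0, 512 * 5), fs_hz = 512)
  expect_warning(pk <- detect_r_peaks(ecg), "no")
  expect_length(pk, 0)
})

test_that("non-finite samples are an error, short records are an error", {
  bad <- ecg_record(c(rep(0.1, 512 * 3), NA), fs_hz = 512)
  expect_error(detect_r_peaks(bad), "finite")
  short <- ecg_record(rep(0.1, 256), fs_hz = 512)
  expect_error(detect_r_peaks(short), "2 s")
})

test_that("detection is invariant to a DC offset", {
  rr <- quick_truth(22, duration_s = 30)
  ecg <- render_ecg(rr, fs_hz = 512, snr_db = Inf)
  shifted <- ecg_record(ecg$mv + 0.7, fs_hz = 512)
  expect_equal(detect_r_peaks(ecg), detect_r_peaks(shifted))
})

test_that("detection stays near-perfect at 10 dB SNR", {
  rr <- quick_truth(23, duration_s = 60)
  ecg <- render_ecg(rr, fs_hz = 512, snr_db = 10, seed = 31)
  pk <- detect_r_peaks(ecg)
  truth <- rr$beat_time_s
  sens <- mean(vapply(truth, function(t) min(abs(pk - t)), numeric(1)) <= 0.05)
  ppv <- mean(vapply(pk, function(p) min(abs(truth - p)), numeric(1)) <= 0.05)
  expect_gte(sens, 0.99)
  expect_gte(ppv, 0.99)
})

test_that("interval extraction matches hand-computed differences", {
  expect_equal(rr_intervals(extract_ibis(c(0, 1, 2))), c(1000, 1000))
  expect_equal(rr_intervals(extract_ibis(c(0, 0.75, 1.60))), c(750, 850))
  expect_error(extract_ibis(1.0), "at least 2")
  expect_error(extract_ibis(c(1, 0.5)), "strictly increasing")
})

test_that("out-of-gate intervals are flagged, not dropped", {
  rr <- rr_from_intervals(c(800, 2500, 810, 150))
  expect_equal(rr$flagged[-1], c(FALSE, TRUE, FALSE, TRUE))
  expect_length(rr_intervals(rr), 4)
  expect_length(rr_intervals(rr, drop_flagged = TRUE), 2)
})

test_that("epoch segmentation uses a half-open window", {
  rr <- rr_from_intervals(rep(1000, 600))  # beats at 0..600 s
  seg <- segment_by_timestamps(rr, 0, 300)
  expect_true(all(seg$beat_time_s < 300))
  expect_equal(nrow(seg), 300)  # beat at exactly 300 s is excluded
  expect_equal(max(seg$beat_time_s), 299)
})

test_that("segmentation is idempotent and recomputes intervals", {
  rr <- quick_truth(24, duration_s = 250)
  seg <- segment_by_timestamps(rr, 0, 180)
  seg2 <- segment_by_timestamps(seg, 0, 180)
  expect_equal(seg2$beat_time_s, seg$beat_time_s)
  expect_equal(seg2$rr_ms, seg$rr_ms)
  expect_equal(rr_intervals(seg), diff(seg$beat_time_s) * 1000)
})

test_that("segmentation guards epoch lengths and sparse windows", {
  rr <- rr_from_intervals(rep(1000, 400))
  expect_error(segment_by_timestamps(rr, 0, 240), "allowed epoch")
  expect_silent(segment_by_timestamps(rr, 0, 240, allowed_durations = NULL))
  expect_error(segment_by_timestamps(rr, 399.5, 300), "fewer than 2")
})

test_that("ECG and RR CSV round-trips preserve the data", {
  rr <- quick_truth(25, duration_s = 30)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rr, tmp)
  rr2 <- read_rr_csv(tmp)
  expect_equal(rr2$beat_time_s, rr$beat_time_s, tolerance = 1e-9)
  ecg <- render_ecg(rr, fs_hz = 256, snr_db = 20, seed = 3)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(ecg, tmp2)
  ecg2 <- read_ecg_csv(tmp2)
  expect_equal(attr(ecg2, "fs_hz"), 256, tolerance = 1e-6)
  expect_equal(ecg2$mv, ecg$mv, tolerance = 1e-9)
})
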