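#' Configuration for a validation run
#'
#' Collects every analysis knob in one place so a run is reproducible from
#' (dataset, config) alone.
#'
#' @param detrend [detrend_config()] for the reference and device rMSSD, or
#'   `NULL` for raw rMSSD.
#' @param hr_convention Mean-HR convention, see [mean_hr()].
#' @param min_hr_window_s Window for ring-type minimum HR, see [min_hr()].
#' @param fence_k Tukey fence multiplier (3 = outer fence).
#' @param quartile_type Quantile algorithm for fences and IQR.
#' @param alpha Significance level on adjusted p-values.
#' @param bonferroni_m Named numeric `c(HR = ..., rMSSD = ...)` family
#'   sizes, or `NULL` to use the number of devices present per metric.
#' @param round_reference Round the reference HR to integer bpm before
#'   comparison (integer-vs-integer mode for devices that report whole
#'   bpm)? Default compares device values as reported against un-rounded
#'   reference.
#' @param reference_source `"rr"` compares against metrics computed on the
#'   exact ground-truth RR series; `"ecg"` first renders the reference ECG
#'   and re-detects beats, exercising the full signal path.
#' @param ecg_fs_hz,ecg_snr_db Rendering parameters when
#'   `reference_source = "ecg"`.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(detrend = detrend_config(),
                              hr_convention = "elapsed",
                              min_hr_window_s = 10,
                              fence_k = 3,
                              quartile_type = 7,
                              alpha = 0.05,
                              bonferroni_m = NULL,
                              round_reference = FALSE,
                              reference_source = c("rr", "ecg"),
                              ecg_fs_hz = 512,
                              ecg_snr_db = Inf) {
  structure(
    list(detrend = detrend, hr_convention = hr_convention,
         min_hr_window_s = min_hr_window_s, fence_k = fence_k,
         quartile_type = quartile_type, alpha = alpha,
         bonferroni_m = bonferroni_m, round_reference = round_reference,
         reference_source = match.arg(reference_source),
         ecg_fs_hz = ecg_fs_hz, ecg_snr_db = ecg_snr_db),
    class = "validation_config"
  )
}

#' Compute reference metrics and pair them with device readings
#'
#' For each trial, restricts the ground-truth RR series to the exact epoch
#' window, optionally routes it through ECG rendering and re-detection, and
#' computes the criterion mean HR and (detrended) rMSSD. Devices that
#' report minimum rather than mean HR contribute no HR pair -- the
#' quantities are not comparable -- but keep their rMSSD pair.
#'
#' @param trials A `trial_dataset` from [generate_study()] or
#'   [load_trials()].
#' @param config A [validation_config()].
#' @return A tibble of paired measurements, one row per trial x metric:
#'   `trial_id`, `subject_id`, `device_label`, `metric` (`"HR"` or
#'   `"rMSSD"`), `device_value`, `reference_value`.
#' @export
compute_reference <- function(trials, config = validation_config()) {
  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    rr <- segment_by_timestamps(tr$rr_truth[[1]], tr$epoch_start_s,
                                tr$epoch_s, allowed_durations = NULL)
    if (config$reference_source == "ecg") {
      ecg <- render_ecg(rr, fs_hz = config$ecg_fs_hz,
                        snr_db = config$ecg_snr_db,
                        seed = i)
      pk <- detect_r_peaks(ecg)
      rr <- extract_ibis(pk)
    }
    ref_hr <- mean_hr(rr, convention = config$hr_convention)
    if (config$round_reference) ref_hr <- round(ref_hr)
    ref_rmssd <- rmssd(rr, config$detrend)
    out <- tibble::tibble(
      trial_id = tr$trial_id, subject_id = tr$subject_id,
      device_label = tr$device_label,
      metric = c("HR", "rMSSD"),
      device_value = c(tr$hr_bpm, tr$rmssd_ms),
      reference_value = c(ref_hr, ref_rmssd)
    )
    if (tr$hr_is_min) out <- out[out$metric != "HR", ]
    out
  })
  dplyr::bind_rows(rows)
}

#' Run the full agreement analysis
#'
#' The statistical chain in the study order: per-trial absolute percent
#' errors, one-shot Tukey outer-fence removal per device/metric group, APE
#' summaries, Lin's concordance, Bland-Altman limits of agreement, and
#' Bonferroni-corrected paired bias tests -- all downstream statistics are
#' computed on the outlier-free pairs. Groups that fail (e.g. empty after
#' removal) are recorded as errors and the run continues.
#'
#' @param trials A `trial_dataset` (with ground-truth `rr_truth`
#'   list-column) or an already-paired tibble with columns `device_label`,
#'   `metric`, `device_value`, `reference_value`.
#' @param config A [validation_config()].
#' @return An `agreement_report` object: a list with tibbles `pairs`
#'   (including `ape_pct` and `outlier` flags), `ape`, `ba`, `ccc`, a
#'   character vector `errors`, and `meta`.
#' @export
run_validation <- function(trials, config = validation_config()) {
  pairs <- if ("rr_truth" %in% names(trials)) {
    compute_reference(trials, config)
  } else {
    need <- c("device_label", "metric", "device_value", "reference_value")
    if (!all(need %in% names(trials))) {
      stop("paired input must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    trials
  }
  if (nrow(pairs) == 0) stop("no pairs to analyze", call. = FALSE)

  pairs$ape_pct <- absolute_percent_error(pairs$device_value,
                                          pairs$reference_value)
  pairs <- pairs |>
    dplyr::group_by(.data$device_label, .data$metric) |>
    dplyr::mutate(outlier = suppressWarnings(
      tukey_extreme_outliers(.data$ape_pct, k = config$fence_k,
                             quartile_type = config$quartile_type))) |>
    dplyr::ungroup()

  kept <- pairs[!pairs$outlier, ]
  fam <- table(unique(kept[, c("device_label", "metric")])$metric)
  bonf <- function(metric) {
    if (!is.null(config$bonferroni_m)) config$bonferroni_m[[metric]]
    else as.numeric(fam[[metric]])
  }

  errors <- character(0)
  groups <- kept |> dplyr::group_by(.data$metric, .data$device_label)
  keys <- dplyr::group_keys(groups)
  splits <- dplyr::group_split(groups)

  ape_rows <- list(); ba_rows <- list(); ccc_rows <- list()
  for (j in seq_along(splits)) {
    g <- splits[[j]]
    lab <- paste0(keys$device_label[j], "/", keys$metric[j])
    res <- tryCatch({
      ape <- ape_summary(g$ape_pct, quartile_type = config$quartile_type)
      ba <- bland_altman(g$device_value, g$reference_value)
      tt <- tryCatch(
        paired_bias_test(g$device_value - g$reference_value,
                         n_comparisons = bonf(keys$metric[j])),
        error = function(e) tibble::tibble(n = nrow(g), t = NA_real_,
                                           p = NA_real_, p_adj = NA_real_,
                                           significant = FALSE)
      )
      ccc <- tryCatch(
        lin_ccc(g$device_value, g$reference_value),
        error = function(e) tibble::tibble(n = nrow(g), ccc = NA_real_)
      )
      id <- tibble::tibble(metric = keys$metric[j],
                           device_label = keys$device_label[j])
      list(ape = dplyr::bind_cols(id, ape),
           ba = dplyr::bind_cols(id, ba,
                                 tt[, c("p", "p_adj", "significant")]),
           ccc = dplyr::bind_cols(id, ccc))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(lab, ": ", conditionMessage(res)))
    } else {
      ape_rows[[lab]] <- res$ape
      ba_rows[[lab]] <- res$ba
      ccc_rows[[lab]] <- res$ccc
    }
  }

  ape_tbl <- dplyr::bind_rows(ape_rows) |>
    dplyr::arrange(.data$metric, .data$mape_pct)
  ba_tbl <- dplyr::bind_rows(ba_rows) |>
    dplyr::arrange(.data$metric, .data$loa_range)
  ccc_tbl <- dplyr::bind_rows(ccc_rows) |>
    dplyr::arrange(.data$metric, dplyr::desc(.data$ccc))

  structure(
    list(pairs = pairs, ape = ape_tbl, ba = ba_tbl, ccc = ccc_tbl,
         errors = errors,
         meta = list(
           seed = attr(trials, "master_seed"),
           config_hash = rlang::hash(config),
           version = as.character(utils::packageVersion("hrvagree")),
           n_trials = length(unique(pairs$trial_id %||%
                                      seq_len(nrow(pairs)))),
           reference_source = config$reference_source
         )),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", nrow(x$pairs), " pairs, ",
      sum(x$pairs$outlier), " extreme outliers removed\n", sep = "")
  cat("APE summaries:\n")
  print(x$ape, n = Inf)
  cat("Bland-Altman:\n")
  print(x$ba[, c("metric", "device_label", "n", "bias", "lower_loa",
                 "upper_loa", "loa_range", "p_adj")], n = Inf)
  if (length(x$errors)) cat("errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits the five tables of a device-validation report as CSV with the
#' conventional column headings (APE summaries per metric, Bland-Altman per
#' metric, concordance for rMSSD), plus a `report.json` holding the
#' full-precision tables and run metadata. APE tables are sorted ascending
#' by MAPE and BA tables by LOA range; values in the CSVs are rounded to
#' 2 decimals.
#'
#' @param report An `agreement_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  r2 <- function(x) round(x, 2)
  fmt_ci <- function(est, lo, hi) {
    sprintf("%s (%s, %s)", r2(est), r2(lo), r2(hi))
  }
  fmt_p <- function(p, sig) {
    ifelse(is.na(p), "NA",
           ifelse(p < 0.001, "<0.001*",
                  paste0(r2(p), ifelse(sig, "*", ""))))
  }

  paths <- character(0)
  for (m in c("HR", "rMSSD")) {
    suffix <- if (m == "HR") "hr" else "rmssd"
    a <- report$ape[report$ape$metric == m, ]
    if (nrow(a)) {
      out <- tibble::tibble(
        Metric = a$metric, Device = a$device_label, n = a$n,
        `MAPE (%)` = r2(a$mape_pct), `Min. (%)` = r2(a$min_pct),
        `Median (%)` = r2(a$median_pct), `Max. (%)` = r2(a$max_pct),
        `IQR (%)` = r2(a$iqr_pct)
      )
      p <- file.path(out_dir, paste0("ape_", suffix, ".csv"))
      readr::write_csv(out, p); paths <- c(paths, p)
    }
    b <- report$ba[report$ba$metric == m, ]
    if (nrow(b)) {
      out <- tibble::tibble(
        Metric = b$metric, Device = b$device_label, n = b$n,
        `Bias (95% CI)` = fmt_ci(b$bias, b$bias_lo, b$bias_hi),
        `Adjusted p-value` = fmt_p(b$p_adj, b$significant),
        `Lower LOA (95% CI)` = fmt_ci(b$lower_loa, b$lower_loa_lo,
                                      b$lower_loa_hi),
        `Upper LOA (95% CI)` = fmt_ci(b$upper_loa, b$upper_loa_lo,
                                      b$upper_loa_hi),
        `LOA range` = r2(b$loa_range)
      )
      p <- file.path(out_dir, paste0("ba_", suffix, ".csv"))
      readr::write_csv(out, p); paths <- c(paths, p)
    }
  }
  cc <- report$ccc[report$ccc$metric == "rMSSD", ]
  if (nrow(cc)) {
    out <- tibble::tibble(Metric = cc$metric, Device = cc$device_label,
                          n = cc$n, Concordance = r2(cc$ccc))
    p <- file.path(out_dir, "ccc_rmssd.csv")
    readr::write_csv(out, p); paths <- c(paths, p)
  }
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(meta = report$meta, ape = report$ape, ba = report$ba,
         ccc = report$ccc, errors = report$errors),
    jp, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(paths, jp))
}

#' Re-read a written report.json
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A list with tibbles `ape`, `ba`, `ccc` and the `meta` list.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ape <- tibble::as_tibble(x$ape)
  x$ba <- tibble::as_tibble(x$ba)
  x$ccc <- tibble::as_tibble(x$ccc)
  x
}

#' Write / load a trial dataset as plain CSV
#'
#' `write_trials()` writes `trials.csv` (one row per trial with the device
#' reading) and one `rr/<trial_id>.csv` RR series per trial.
#' `load_trials()` validates and re-assembles the dataset, naming the
#' offending row on schema violations.
#'
#' @param trials A `trial_dataset`.
#' @param dir Directory to write into / read from.
#' @return `write_trials()` the directory, invisibly; `load_trials()` a
#'   `trial_dataset`.
#' @export
write_trials <- function(trials, dir) {
  dir.create(file.path(dir, "rr"), recursive = TRUE, showWarnings = FALSE)
  meta <- trials[, setdiff(names(trials), "rr_truth")]
  meta$rr_path <- file.path("rr", paste0(trials$trial_id, ".csv"))
  readr::write_csv(meta, file.path(dir, "trials.csv"))
  purrr::walk2(trials$rr_truth, meta$rr_path,
               ~ write_rr_csv(.x, file.path(dir, .y)))
  invisible(dir)
}

#' @rdname write_trials
#' @export
load_trials <- function(dir) {
  path <- file.path(dir, "trials.csv")
  if (!file.exists(path)) stop("no trials.csv in ", dir, call. = FALSE)
  meta <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("trial_id", "subject_id", "device_label", "epoch_start_s",
            "epoch_s", "hr_bpm", "hr_is_min", "rmssd_ms", "rr_path")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("trials.csv is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(meta))) {
    if (!meta$epoch_s[i] %in% c(180, 300)) {
      stop("row ", i, " (", meta$trial_id[i], "): epoch_s = ",
           meta$epoch_s[i], " is not 180 or 300", call. = FALSE)
    }
    if (is.na(meta$rr_path[i]) ||
        !file.exists(file.path(dir, meta$rr_path[i]))) {
      stop("row ", i, " (", meta$trial_id[i],
           "): reference RR file missing", call. = FALSE)
    }
  }
  meta$rr_truth <- purrr::map(meta$rr_path,
                              ~ read_rr_csv(file.path(dir, .x)))
  meta$rr_path <- NULL
  class(meta) <- c("trial_dataset", class(meta))
  meta
}
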