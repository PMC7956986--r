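Package: hrvagree
Title: Simulated Validation of Wearable Heart-Rate and HRV Devices Against
    Reference ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico validation pipeline for commercial heart-rate and
    heart-rate-variability (HRV) wearables. Simulates ground-truth RR-interval
    series with controllable rMSSD, renders reference ECG at 512 Hz, detects
    R peaks with a Pan-Tompkins style detector, computes smoothing-priors
    detrended rMSSD and mean heart rate, and quantifies device agreement with
    absolute percent error summaries after Tukey outer-fence outlier removal,
    Lin's concordance correlation coefficient, Bland-Altman limits of
    agreement, and Bonferroni-corrected paired bias tests. Works on tidy data
    frames throughout and reports the standard method-comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
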