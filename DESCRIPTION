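Package: dielphage
Title: Diel Transcriptional Rhythms of Viral Genes in Metatranscriptomic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects diurnally rhythmic viral genes in diel metatranscriptomic
    time series and estimates and compares their peak expression times. Provides
    best-hit read assignment with tie discarding and ortholog binning, a
    rank-based umbrella test for 24-hour periodicity with Benjamini-Hochberg
    false discovery rate control, Poisson log-linear harmonic (cosinor)
    regression with a library-size offset for peak-time estimation, exhaustive
    delete-2 jackknife confidence intervals for peak times, and two-sample
    comparisons of early, middle and late phage gene classes. A synthetic-data
    generator with known ground truth emulates a multi-day field sampling
    design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
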