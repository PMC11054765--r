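Package: cptstress
Title: Cumulative Plantar Tissue Stress from Multi-Sensor Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compute cumulative plantar tissue stress (CPTS) at a
    foot ulcer site by fusing four wearable sensor streams: in-shoe or
    platform plantar pressure (peak pressure and pressure-time integral),
    trunk accelerometry (daily stride counts and valid monitoring days),
    in-device temperature logs (offloading-device wear intervals and
    adherence), and pre/post-walk plantar thermography (thermal stress
    response, a surrogate for shear stress). Includes a synthetic
    multi-sensor cohort generator with a ground-truth manifest for
    parameter-recovery testing, per-participant and cohort pipeline
    drivers, and the nonparametric group-comparison statistics used for
    small clinical cohorts (Mann-Whitney U with effect size r = |z|/sqrt(n),
    Pearson chi-square, pooled t-test, median with interquartile range).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
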