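Package: lmsgrowth
Title: Age- and Sex-Specific Anthropometric Growth References by the LMS Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct age- and sex-specific growth references for height,
    weight and body mass index from cross-sectional cohort data using the LMS
    (Box-Cox Cole-Green) method. Provides centile and z-score transforms,
    per-group maximum-likelihood fitting of the L, M and S parameters,
    optional smoothing of parameter series across age, back-substitution
    cross-validation with MAPE accuracy classification, comparison of local
    medians against external reference standards, percentile chart rendering,
    and a synthetic-cohort generator that emulates a stratified school survey
    of adolescents so the whole pipeline can be exercised without access to
    raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
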