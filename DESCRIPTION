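Package: popfert
Title: Population and Fertility Estimation by Demographic Balancing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a cohort-component population and
    fertility estimation pipeline. From census counts, fertility observations
    (vital registration, complete and summary birth histories), and abridged
    period life tables, the package estimates age-specific fertility rates by
    Gaussian-process regression, sex ratio at birth, census completeness and
    age-heaping corrections, single-year life tables graduated from abridged
    tables, net migration via a Bayesian demographic balancing model, and
    single-year age-sex population series with out-of-sample uncertainty.
    Summary indicators (TFR, TFU25, TFO30, NRR, growth rates, working-age
    proportion, Socio-demographic Index) are computed from the estimates. A
    synthetic-data generator with known truth supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    pracma,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
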