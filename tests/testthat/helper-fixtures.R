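# shared fixtures, built once per test run

.fix <- new.env()

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fix, inherits = FALSE))
    assign(name, builder(), envir = .fix)
  get(name, envir = .fix, inherits = FALSE)
}

small_truth <- function() {
  get_fixture("small_truth",
              function() make_true_country(list(years = 1950:1980), seed = 42))
}

lt_library <- function() {
  get_fixture("lt_library", function() make_lifetable_library(60, seed = 7))
}

qx_coeffs <- function() {
  get_fixture("qx_coeffs", function() fit_qx_regression(lt_library()))
}

# survivorship pair with no mortality at all (including the open interval)
unit_surv <- function() {
  one <- list(newborn = 1, s = rep(1, 95), open = 1)
  list(female = one, male = one)
}

# noise-free census list from a truth (perfect completeness, no heaping)
perfect_censuses <- function(truth, years) {
  oc <- obs_config(census_years = years, heaping_strength = 0,
                   completeness_curve = function(sdi, age)
                     rep(1, length(age)))
  lapply(years, function(y) {
    cn <- observe_census(truth, y, oc)
    cn$counts$adjusted <- cn$counts$value
    cn
  })
}
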