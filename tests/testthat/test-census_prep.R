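test_that("completeness model: perfect enumeration gives identity adjustments", {
  pes <- data.frame(completeness = rep(1, 8), sdi = seq(0.1, 0.9, length.out = 8))
  m <- suppressWarnings(fit_completeness_model(pes))
  expect_equal(unname(predict_completeness(m, c(0.2, 0.5, 0.9))), rep(1, 3),
               tolerance = 1e-8)
  expect_equal(m$age_mult, rep(1, 96))
})

test_that("completeness model recovers a known logistic curve within 2 SE", {
  set.seed(14)
  sdi <- stats::runif(60, 0.05, 0.95)
  eta <- 0.8 + 2.0 * sdi
  comp <- pmin(1.05 * stats::plogis(eta) * exp(stats::rnorm(60, 0, 0.01)), 1.04)
  m <- fit_completeness_model(data.frame(completeness = comp, sdi = sdi))
  se <- sqrt(diag(m$vcov))
  expect_lt(abs(m$coef[1] - 0.8), 2 * se[1] + 0.05)
  expect_lt(abs(m$coef[2] - 2.0), 2 * se[2] + 0.05)
  # monotone link: higher SDI -> no lower completeness when slope >= 0
  p <- predict_completeness(m, seq(0, 1, 0.1))
  expect_true(all(diff(p) >= -1e-12))
})

test_that("completeness model input validation", {
  expect_error(fit_completeness_model(
    data.frame(completeness = c(0.9, 0.95), sdi = c(0.2, 0.4))), "at least 3")
  expect_error(fit_completeness_model(
    data.frame(completeness = c(0.9, 0.95, 0.97), sdi = rep(0.5, 3))),
    "identical SDI")
})

test_that("age pattern of enumeration is recovered as mean-1 multipliers", {
  set.seed(4)
  ages <- rep(seq(2, 92, 5), 3)
  true_mult <- 1 - 0.08 * pmax(1 - ages / 5, 0) - 0.1 * pmax(ages - 65, 0) / 30
  ap <- data.frame(age = ages,
                   ratio = true_mult * exp(stats::rnorm(length(ages), 0, 0.005)),
                   variance = rep(1e-4, length(ages)))
  pes <- data.frame(completeness = seq(0.9, 1.0, length.out = 5),
                    sdi = seq(0.2, 0.8, length.out = 5))
  m <- fit_completeness_model(pes, age_pattern = ap)
  expect_equal(mean(m$age_mult), 1, tolerance = 1e-12)
  expect_true(all(m$age_mult > 0))
  # the deficit at old ages is reproduced (relative ordering)
  expect_lt(m$age_mult[91], m$age_mult[41])
})

test_that("census adjustment divides by completeness and is scale-equivariant", {
  tr <- small_truth()
  oc <- obs_config(census_years = 1970, heaping_strength = 0,
                   completeness_curve = function(sdi, age)
                     rep(0.95, length(age)))
  cen <- observe_census(tr, 1970, oc)
  pes <- data.frame(completeness = rep(0.95, 6), sdi = seq(0.1, 0.9,
                                                           length.out = 6))
  m <- suppressWarnings(fit_completeness_model(pes))
  adj <- adjust_census(cen, m, sdi = 0.5, sdi_group = "high-middle")
  expect_equal(adj$counts$adjusted, adj$counts$value / 0.95, tolerance = 1e-6)
  expect_false(adj$drop_under5)
  # scaling raw counts by k scales adjusted counts by k
  cen2 <- cen; cen2$counts$value <- cen2$counts$value * 3
  adj2 <- adjust_census(cen2, m, sdi = 0.5, sdi_group = "high-middle")
  expect_equal(adj2$counts$adjusted, 3 * adj$counts$adjusted)
  # under-5 exclusion flag for low/middle SDI
  expect_true(adjust_census(cen, m, 0.5, "middle")$drop_under5)
  # own PES wins in high-SDI locations
  own <- adjust_census(cen, m, 0.5, "high", own_pes = list(completeness = 0.9))
  expect_equal(own$counts$adjusted, own$counts$value / 0.9, tolerance = 1e-6)
  cen$outlier <- TRUE
  expect_error(adjust_census(cen, m, 0.5, "middle"), "outlier")
})

test_that("adjusted synthetic censuses land within 1% of the truth", {
  tr <- small_truth()
  oc <- obs_config(census_years = 1970, heaping_strength = 0,
                   completeness_curve = function(sdi, age)
                     rep(default_completeness(sdi, 30), length(age)))
  cen <- observe_census(tr, 1970, oc)
  set.seed(6)
  sdis <- stats::runif(40, 0.1, 0.9)
  pes <- data.frame(completeness = default_completeness(sdis, 30), sdi = sdis)
  m <- fit_completeness_model(pes)
  i <- match(1970, tr$years)
  adj <- adjust_census(cen, m, sdi = tr$sdi[i], sdi_group = "high-middle")
  expect_lt(abs(sum(adj$counts$adjusted) / sum(tr$pop[, , i]) - 1), 0.01)
})

test_that("joint score: smooth equal-sex population scores below 1, distortion raises it", {
  v <- 1000 * exp(-0.02 * (0:95))
  counts <- popfert:::.aggregate_ages(cbind(v, v), "five")
  toy <- structure(list(location = "toy", year = 2000, counts = counts,
                        age_grouping = "five", defacto = TRUE, outlier = FALSE,
                        drop_under5 = FALSE), class = "census_observation")
  js <- age_sex_joint_score(toy)
  expect_lt(js$joint, 1)
  # doubling one group strictly increases the score
  toy2 <- toy
  toy2$counts$value[toy2$counts$age_start == 30 &
                      toy2$counts$sex == "male"] <- 2 *
    toy2$counts$value[toy2$counts$age_start == 30 & toy2$counts$sex == "male"]
  expect_gt(age_sex_joint_score(toy2)$joint, js$joint)
})

test_that("joint score equals a hand-computed index on a 6-group toy table", {
  f <- c(100, 110, 105, 95, 90, 80)
  m <- c(102, 100, 110, 96, 85, 82)
  counts <- data.frame(age_start = rep(seq(0, 25, 5), 2),
                       age_end = rep(seq(5, 30, 5), 2),
                       sex = rep(c("female", "male"), each = 6),
                       value = c(f, m))
  toy <- structure(list(counts = counts, age_grouping = "five",
                        outlier = FALSE), class = "census_observation")
  ar <- function(p) 100 * 2 * p[2:5] / (p[1:4] + p[3:6])
  sr <- 100 * m / f
  expected <- 3 * mean(abs(diff(sr))) + mean(abs(ar(m) - 100)) +
    mean(abs(ar(f) - 100))
  expect_equal(age_sex_joint_score(toy)$joint, expected, tolerance = 1e-12)
})

test_that("feeney is a fixed point on smooth counts and conserves totals", {
  v <- 5000 * exp(-0.025 * (0:95))
  counts <- popfert:::.aggregate_ages(cbind(v, v), "single")
  out <- correct_heaping(counts, "feeney")
  expect_lt(max(abs(out$value - counts$value) / counts$value), 1e-6)
  expect_equal(sum(out$value), sum(counts$value), tolerance = 1e-9)
})

test_that("feeney moves the Whipple index at least 80% of the way to 100", {
  tr <- small_truth()
  oc <- obs_config(census_years = 1970, heaping_strength = 0.3,
                   age_grouping = "single")
  cen <- observe_census(tr, 1970, oc)
  w0 <- whipple_index(cen$counts)
  out <- correct_heaping(cen$counts, "feeney")
  w1 <- whipple_index(out)
  expect_gte((w0 - w1) / (w0 - 100), 0.8)
  expect_equal(sum(out$value), sum(cen$counts$value),
               tolerance = 1e-9 * sum(cen$counts$value))
  expect_true(all(out$value >= 0))
})

test_that("arriaga preserves 10-year totals and is exact on linear counts", {
  # density linear in age: two-point endpoint split is exact, interior too
  dens <- function(a) 200 - a
  g5 <- vapply(seq(0, 75, 5), function(s) sum(dens(s:(s + 4))), numeric(1))
  counts <- data.frame(age_start = rep(seq(0, 75, 5), 2),
                       age_end = rep(seq(5, 80, 5), 2),
                       sex = rep(c("female", "male"), each = 16),
                       value = rep(g5, 2))
  out <- correct_heaping(counts, "arriaga")
  expect_equal(out$value, counts$value, tolerance = 1e-9)
  # 10-year totals preserved on distorted input
  counts2 <- counts
  counts2$value <- counts2$value * stats::runif(32, 0.8, 1.2)
  out2 <- correct_heaping(counts2, "arriaga")
  for (s in seq(0, 70, 10)) {
    for (sx in c("female", "male")) {
      t10 <- function(d) sum(d$value[d$age_start %in% c(s, s + 5) &
                                       d$sex == sx])
      expect_equal(t10(out2), t10(counts2), tolerance = 1e-9)
    }
  }
})

test_that("arriaga strong smooths 10-year totals but preserves the overall total", {
  set.seed(2)
  g5 <- 1000 * exp(-0.02 * seq(0, 75, 5)) * stats::runif(16, 0.7, 1.3)
  counts <- data.frame(age_start = seq(0, 75, 5), age_end = seq(5, 80, 5),
                       sex = "female", value = g5)
  out <- correct_heaping(counts, "arriaga_strong")
  expect_equal(sum(out$value), sum(counts$value), tolerance = 1e-9)
  expect_true(all(out$value >= 0))
})

test_that("ten-year input is split into 5-year groups", {
  counts <- data.frame(age_start = seq(0, 70, 10), age_end = seq(10, 80, 10),
                       sex = "female",
                       value = 1000 * exp(-0.02 * seq(0, 70, 10)))
  out <- correct_heaping(counts, "arriaga")
  expect_true(all(out$age_end - out$age_start == 5))
  for (s in seq(0, 70, 10)) {
    expect_equal(sum(out$value[out$age_start %in% c(s, s + 5)]),
                 counts$value[counts$age_start == s], tolerance = 1e-9)
  }
})

test_that("heaping corrections reject mismatched groupings", {
  single <- data.frame(age_start = 0:10, age_end = 1:11, sex = "female",
                       value = rep(10, 11))
  expect_error(correct_heaping(single, "arriaga"), "5- or 10-year")
  five <- data.frame(age_start = seq(0, 40, 5), age_end = seq(5, 45, 5),
                     sex = "female", value = rep(10, 9))
  expect_error(correct_heaping(five, "feeney"), "single-year")
  short <- data.frame(age_start = c(0, 5), age_end = c(5, 10), sex = "female",
                      value = c(10, 10))
  expect_error(correct_heaping(short, "arriaga"), "30 years")
})

test_that("the correction rule follows the score thresholds", {
  tr <- small_truth()
  ocs <- obs_config(census_years = 1970, heaping_strength = 0.3,
                    age_grouping = "single")
  expect_equal(choose_heaping_correction(observe_census(tr, 1970, ocs)),
               "feeney")
  oc0 <- obs_config(census_years = 1970, heaping_strength = 0,
                    age_grouping = "five",
                    completeness_curve = function(sdi, age)
                      rep(1, length(age)))
  expect_true(choose_heaping_correction(observe_census(tr, 1970, oc0)) %in%
                c("none", "arriaga"))
  oce <- obs_config(census_years = 1970, heaping_strength = 0.3,
                    old_age_exaggeration = 0.35, age_grouping = "five")
  expect_true(choose_heaping_correction(observe_census(tr, 1970, oce)) !=
                "none")
})
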