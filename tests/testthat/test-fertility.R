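# helper: build a fertility_obs data.frame from a 9 x n matrix of group rates
make_obs <- function(rates, years, source_id = "vr", source_type = "vr",
                     rel_sd = 1e-5, groups = 2:8) {
  rows <- lapply(seq_along(years), function(i) {
    g <- seq(10, 50, 5)[groups]
    v <- rates[groups, i]
    data.frame(location = "syn", year = years[i], source_type = source_type,
               source_id = source_id, age_start = g, age_end = g + 5,
               measure = "asfr", value = v, variance = (v * rel_sd)^2,
               reference = source_id == "vr")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fertility_obs", "data.frame")
  out
}

test_that("data equal to a constant prior with zero noise returns the prior", {
  years <- 1960:2000
  rates <- matrix(rep(c(0.001, 0.05, 0.2, 0.18, 0.12, 0.06, 0.02, 0.004,
                        0.0004), length(years)), 9)
  obs <- make_obs(rates, years)
  est <- fit_stage1(obs, config = list(n_draws = 10))
  expect_equal(est$mean[2:8, ], rates[2:8, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(dim(est$draws)[3], 10)
  # draw means are recentred onto the point estimate
  expect_equal(apply(est$draws, c(1, 2), mean)[2:8, ], est$mean[2:8, ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("dense exact VR is interpolated to under 0.5%", {
  years <- 1955:2005
  tfr <- seq(5.5, 2.0, length.out = length(years))
  rates <- vapply(seq_along(years), function(i) {
    s <- hadwiger_asfr(tfr[i], mode = 27 + i / 25)
    vapply(1:9, function(g) mean(s[(5 * g - 4):(5 * g)]), numeric(1))
  }, numeric(9))
  obs <- make_obs(rates, years, rel_sd = 1e-6)
  est <- fit_stage1(obs, config = list(n_draws = 5, var_floor = 1e-12))
  rel <- abs(est$mean[2:8, match(years, est$years)] / rates[2:8, ] - 1)
  expect_lt(max(rel), 0.005)
})

test_that("synthetic recovery: biased source detected, rates within 5% at data years", {
  tr <- get_fixture("fert_truth", function()
    make_true_country(list(years = 1950:2000), seed = 5))
  oc <- obs_config(census_years = 1960, vr_years = 1955:2000,
                   vr_bias = c(vr = 1.0, vr2 = 0.85),
                   noise_sd = c(vr = 0.02, cbh = 0.07, sbh = 0.1), seed = 9)
  fo <- observe_fertility_sources(tr, oc)
  est <- fit_stage1(fo, config = list(n_draws = 10))
  # the secondary source's downward bias is recovered with the right sign
  expect_lt(est$source_offsets[["vr2"]], -0.05)
  expect_equal(est$source_offsets[["vr2"]], log(0.85), tolerance = 0.1)
  tru <- vapply(1955:2000, function(y) true_group_asfr(tr, y), numeric(9))
  rel <- abs(est$mean[2:8, match(1955:2000, est$years)] / tru[2:8, ] - 1)
  expect_lt(stats::quantile(rel, 0.95), 0.05)
  expect_lt(max(rel), 0.10)
})

test_that("reference cascade errors informatively with no resolvable reference", {
  obs <- data.frame(location = "x", year = 2000, source_type = "sbh",
                    source_id = "s1", age_start = 20, age_end = 25,
                    measure = "asfr", value = 0.1, variance = 1e-6,
                    reference = FALSE)
  expect_error(fit_stage1(obs), "reference source")
})

test_that("aggregate splitting: identity ratio, linearity, exact bias recovery", {
  years <- 1950:2000
  truth9 <- matrix(rep(c(0.002, 0.06, 0.22, 0.20, 0.13, 0.07, 0.025, 0.005,
                         0.0005), length(years)), 9)
  k <- 1.7
  stage1 <- asfr_estimate(truth9 / k, years, stage = "stage1")
  # SBH observation computed from the group-constant truth along the diagonal
  ceb_true <- function(sy, A) {
    single <- expand_asfr_groups(truth9)
    mean(vapply(A:(A + 4), function(a) {
      if (a <= 10) return(0)
      xs <- 10:(a - 1)
      ys <- pmin(pmax(sy - (a - xs), min(years)), max(years))
      sum(single[cbind(xs - 9, match(ys, years))])
    }, numeric(1)))
  }
  obs <- data.frame(location = "syn", year = 1995, source_type = "sbh",
                    source_id = "s95", age_start = 30, age_end = 35,
                    measure = "ceb", value = ceb_true(1995, 30),
                    variance = 1e-4, reference = FALSE)
  ps <- split_aggregates(obs, stage1)
  expect_true(nrow(ps) >= 3)
  gi <- match(ps$age_start, seq(10, 50, 5))
  expect_equal(ps$value,
               truth9[cbind(gi, match(ps$year, years))], tolerance = 1e-9)
  # doubling observed CEB doubles every pseudo point
  obs2 <- obs; obs2$value <- 2 * obs2$value
  ps2 <- split_aggregates(obs2, stage1)
  expect_equal(ps2$value, 2 * ps$value, tolerance = 1e-12)
  # CEB exactly matching stage 1 gives ratio 1
  obs3 <- obs; obs3$value <- ceb_true(1995, 30) / k
  ps3 <- split_aggregates(obs3, stage1)
  expect_equal(ps3$value, stage1$mean[cbind(gi, match(ps3$year, years))],
               tolerance = 1e-9)
})

test_that("splitting rejects positive CEB with zero implied fertility", {
  years <- 1990:2000
  stage1 <- asfr_estimate(matrix(0, 9, length(years)), years)
  obs <- data.frame(location = "syn", year = 2000, source_type = "sbh",
                    source_id = "s", age_start = 30, age_end = 35,
                    measure = "ceb", value = 2, variance = 1e-4,
                    reference = FALSE)
  expect_error(split_aggregates(obs, stage1), "implied cumulative fertility")
})

test_that("total births are split proportionally to stage-1 shares", {
  years <- 1990:1995
  rates <- matrix(rep(c(0.001, 0.05, 0.2, 0.18, 0.12, 0.06, 0.02, 0.004,
                        4e-4), 6), 9)
  stage1 <- asfr_estimate(rates, years)
  women <- matrix(1000, 9, 6)
  obs <- data.frame(location = "syn", year = 1992, source_type = "total_births",
                    source_id = "tb", age_start = 10, age_end = 55,
                    measure = "births", value = 5000, variance = 100,
                    reference = FALSE)
  ps <- split_aggregates(obs, stage1, women = women)
  expect_equal(nrow(ps), 9)
  implied_births <- ps$value * 5 * 1000
  expect_equal(sum(implied_births), 5000, tolerance = 1e-9)
  expect_equal(implied_births / sum(implied_births),
               rates[, 3] / sum(rates[, 3]), tolerance = 1e-12)
})

test_that("final estimation is a fixed point without aggregate data", {
  years <- 1970:2000
  rates <- matrix(rep(c(0.001, 0.05, 0.2, 0.18, 0.12, 0.06, 0.02, 0.004,
                        4e-4), 31), 9)
  obs <- make_obs(rates, years)
  st1 <- fit_stage1(obs, config = list(n_draws = 5), seed = 2)
  fin <- fit_final(obs, pseudo = NULL, config = list(n_draws = 5), seed = 2)
  expect_equal(fin$mean, st1$mean, tolerance = 1e-12)
  expect_equal(fin$stage, "final")
})

test_that("SBH splitting restores pre-period signal that VR alone misses", {
  tr <- get_fixture("fert_truth", function()
    make_true_country(list(years = 1950:2000), seed = 5))
  oc <- obs_config(census_years = 1960, vr_years = 1980:2000,
                   sbh_surveys = c(1975, 1985, 1995),
                   sbh_cohorts = seq(15, 45, 5),
                   vr_bias = c(vr = 1),
                   noise_sd = c(vr = 0.02, cbh = 0.07, sbh = 0.03), seed = 4)
  fo <- observe_fertility_sources(tr, oc)
  cfg <- list(n_draws = 5, years = 1950:2000)
  st1 <- fit_stage1(fo, config = cfg)
  ps <- split_aggregates(fo, st1)
  fin <- fit_final(fo, pseudo = ps, config = cfg)
  tru <- vapply(1950:2000, function(y) true_group_asfr(tr, y), numeric(9))
  pre <- which(1950:2000 < 1975)
  rmse <- function(est) sqrt(mean((log(est$mean[2:8, pre]) -
                                     log(tru[2:8, pre]))^2))
  expect_lt(rmse(fin), rmse(st1))
})

test_that("extreme-age model: trivial identities and generate-and-refit within 3%", {
  # trivial: slope 0, intercept log(0.01)
  em0 <- structure(list(b0 = log(0.01), b1 = 0, r5054 = 0.02),
                   class = "extreme_age_model")
  years <- 1990:1995
  rates <- matrix(rep(c(NA, 0.05, 0.2, 0.18, 0.12, 0.06, 0.02, 0.004, NA), 6),
                  9)
  rates[1, ] <- 0; rates[9, ] <- 0
  est <- asfr_estimate(rates, years)
  out <- apply_extreme_ages(est, em0)
  expect_equal(out$mean[1, ], 0.01 * out$mean[2, ], ignore_attr = TRUE)
  expect_equal(out$mean[9, ], 0.02 * out$mean[8, ], ignore_attr = TRUE)
  # zero 45-49 gives zero 50-54
  est2 <- est; est2$mean[8, ] <- 0
  expect_equal(apply_extreme_ages(est2, em0)$mean[9, ], rep(0, 6),
               ignore_attr = TRUE)
  # generate-and-refit on VR built with a known ratio law
  set.seed(11)
  yrs <- 1960:2005
  a15 <- seq(0.08, 0.02, length.out = length(yrs))
  b0t <- log(0.012); b1t <- 3
  a10 <- a15 * exp(b0t + b1t * a15) * exp(stats::rnorm(length(yrs), 0, 0.01))
  a45 <- seq(0.01, 0.002, length.out = length(yrs))
  a50 <- 0.08 * a45 * exp(stats::rnorm(length(yrs), 0, 0.01))
  vr <- do.call(rbind, lapply(seq_along(yrs), function(i) {
    data.frame(location = "syn", year = yrs[i], source_type = "vr",
               source_id = "vr", age_start = c(10, 15, 45, 50),
               age_end = c(15, 20, 50, 55), measure = "asfr",
               value = c(a10[i], a15[i], a45[i], a50[i]), variance = 1e-8,
               reference = TRUE)
  }))
  em <- fit_extreme_age_model(vr)
  expect_equal(em$r5054, 0.08, tolerance = 0.03 * 0.08 + 0.002)
  pred <- a15 * exp(em$b0 + em$b1 * a15)
  expect_lt(max(abs(pred / (a15 * exp(b0t + b1t * a15)) - 1)), 0.03)
})

test_that("sex ratio at birth: prior default, constant data, and ramp recovery", {
  yrs <- 1950:2017
  s0 <- estimate_srb(NULL, yrs)
  expect_equal(unname(s0$srb), rep(1.05, length(yrs)))
  dat <- data.frame(year = seq(1955, 2015, 5), p_male = 0.512,
                    variance = 1e-7)
  s1 <- estimate_srb(dat, yrs)
  expect_equal(unname(s1$srb[match(1985, yrs)]), 0.512 / 0.488,
               tolerance = 0.002)
  # late ramp to p = 0.539 (SRB ~ 1.17)
  pm <- c(rep(0.512, 40), seq(0.512, 0.539, length.out = 28))
  dat2 <- data.frame(year = yrs, p_male = pm, variance = 1e-8)
  s2 <- estimate_srb(dat2, yrs)
  expect_lt(abs(s2$srb[length(yrs)] - 1.17), 0.01)
  expect_error(estimate_srb(data.frame(year = 2000, p_male = 1.2,
                                       variance = 1e-6), yrs),
               "proportions")
})
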