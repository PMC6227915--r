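test_that("zero rates give a pure one-year age shift; the open interval accumulates", {
  base <- matrix(100 + (0:95) + rep(c(0, 50), each = 96), 96, 2)
  out <- ccmpp_project(base, NULL, 1.05, unit_surv(), NULL, years = 2000:2005)
  for (t in 1:5) {
    expect_equal(out$pop[2:95, , t + 1], out$pop[1:94, , t],
                 ignore_attr = TRUE)
    expect_equal(out$pop[96, , t + 1], out$pop[95, , t] + out$pop[96, , t],
                 ignore_attr = TRUE)
    expect_equal(out$pop[1, , t + 1], c(0, 0), ignore_attr = TRUE)
  }
  expect_equal(out$clipped, 0L)
})

test_that("the balancing identity holds exactly for projections", {
  tr <- small_truth()
  res <- balance_residual(tr$pop, tr$flows)
  expect_lt(max(abs(res)) / sum(tr$pop[, , 1]), 1e-9)
})

test_that("residual responds linearly to a perturbed death count", {
  tr <- small_truth()
  fl <- tr$flows
  fl$deaths[31, 1, 4] <- fl$deaths[31, 1, 4] + 123
  res <- balance_residual(tr$pop, fl)
  expect_equal(res[4], 123, tolerance = 1e-6)
  expect_lt(max(abs(res[-4])) / sum(tr$pop[, , 1]), 1e-9)
})

test_that("residual on a hand-built 3-age toy equals pencil-and-paper arithmetic", {
  # two years; ages collapsed into rows 1..3 of the grid, everything else 0
  arr <- array(0, c(96, 2, 2))
  arr[1:3, 1, 1] <- c(10, 20, 30)
  arr[1:3, 1, 2] <- c(8, 9, 21)
  grid <- population_grid(arr, 2000:2001)
  flows <- list(births = matrix(c(8, 0), 2, 1),
                deaths = array(0, c(96, 2, 1)),
                migrants = array(0, c(96, 2, 1)))
  flows$deaths[1:3, 1, 1] <- c(1, 2, 3)
  flows$migrants[2, 1, 1] <- -24
  # N(2001) - (N(2000) + B - D + G) = 38 - (60 + 8 - 6 - 24) = 0
  expect_equal(balance_residual(grid, flows), 0)
  flows$migrants[2, 1, 1] <- -20
  expect_equal(balance_residual(grid, flows), -4)
})

test_that("births equal the per-age exposure ledger (independent bookkeeping)", {
  tr <- small_truth()
  yrs <- tr$years
  for (t in c(3, 17)) {
    nf_start <- tr$pop[11:55, 1, t]
    nf_end <- tr$pop[11:55, 1, t + 1]
    ledger <- sum(tr$asfr[, t] * (nf_start + nf_end) / 2)
    expect_equal(sum(tr$flows$births[, t]), ledger, tolerance = 1e-9)
  }
})

test_that("monotone response: more fertility means more births, more mortality less population", {
  tr <- small_truth()
  n <- length(tr$years)
  up <- ccmpp_project(tr$pop[, , 1], tr$asfr[, -n] * 1.2, tr$srb, tr$surv,
                      tr$mig, years = tr$years)
  expect_true(all(colSums(up$flows$births) >=
                    colSums(tr$flows$births) - 1e-9))
  # raise qx at ages 30-34 in every year
  surv2 <- lapply(tr$surv, function(sv) {
    sv$female$s[31:35] <- sv$female$s[31:35] * 0.95
    sv$male$s[31:35] <- sv$male$s[31:35] * 0.95
    sv
  })
  down <- ccmpp_project(tr$pop[, , 1], tr$asfr[, -n], tr$srb, surv2,
                        tr$mig, years = tr$years)
  expect_true(all(down$pop[32:36, , 2] <= tr$pop[32:36, , 2] + 1e-9))
})

test_that("negative populations are clipped, counted, and absorbed into deaths", {
  base <- matrix(10, 96, 2)
  G <- array(0, c(96, 2, 1)); G[40, , 1] <- -50
  out <- ccmpp_project(base, NULL, 1.05, unit_surv(),
                       migration_surface(G, 2000), years = 2000:2001)
  expect_gt(out$clipped, 0)
  expect_true(all(out$pop >= 0))
  expect_lt(abs(balance_residual(out$pop, out$flows)), 1e-9)
})

test_that("back-projection is the exact inverse of projection under zero migration", {
  tr <- small_truth()
  n <- length(tr$years)
  anchor <- tr$pop[, , n]
  bp <- back_project(anchor, tr$surv[[n - 1]], years_back = 12,
                     anchor_year = tr$years[n])
  fw <- ccmpp_project(bp$pop[, , 1], NULL, tr$srb, tr$surv[[n - 1]], NULL,
                      years = (tr$years[n] - 12):tr$years[n],
                      births = bp$implied_births)
  expect_equal(unclass(fw$pop[, , 13]), unclass(anchor), tolerance = 1e-12)
  expect_true(bp$low_confidence)
})

test_that("zero-mortality anchor back-projects as a pure reverse shift at closed ages", {
  anchor <- matrix(1000 + 0:95, 96, 2)
  bp <- back_project(anchor, unit_surv(), years_back = 3, anchor_year = 1980)
  # one year back, every closed age holds next year's cohort one age older
  expect_equal(bp$pop[1:94, , 3], anchor[2:95, ], ignore_attr = TRUE)
  # forward projection with the implied births reproduces the anchor exactly
  fw <- ccmpp_project(bp$pop[, , 1], NULL, 1.05, unit_surv(), NULL,
                      years = 1977:1980, births = bp$implied_births)
  expect_equal(unclass(fw$pop[, , 4]), anchor, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("1950 baseline recovered within 2% at ages 5-80 under zero migration", {
  # oldest census 14 years after the baseline year, as when back-projecting
  # from the earliest available enumeration
  tr <- make_true_country(list(years = 1950:1964,
                               mig = list(amp = 0, peak_age = 25, age_sd = 10,
                                          shock_years = integer(0),
                                          shock_amp = 0,
                                          bump_years = integer(0),
                                          bump_amp = 0)), seed = 13)
  n <- length(tr$years)
  bp <- back_project(tr$pop[, , n], tr$surv, years_back = n - 1,
                     anchor_year = tr$years[n])
  rel <- abs(bp$pop[6:81, , 1] / tr$pop[6:81, , 1] - 1)
  expect_lt(max(rel), 0.02)
})

test_that("back-projection rejects zero survivorship", {
  sv <- unit_surv()
  sv$female$s[10] <- 0
  expect_error(back_project(matrix(1, 96, 2), sv, 2, 2000), "zero")
})
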