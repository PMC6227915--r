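# Bayesian demographic balancing: infer a baseline population and an
# age-time-correlated net-migration surface consistent with fertility,
# mortality and adjusted census counts.
#
# Migration is parameterized as net rates at a coarsened age x time knot grid
# with a mean-zero AR1(age) x AR1(time) Gaussian prior; knot rates are
# converted to counts against a fixed zero-migration reference projection, so
# the cohort-component model counts are exactly linear in the parameters. The
# design matrix is built from unit-perturbation runs of ccmpp_project itself,
# and the posterior is maximised by quasi-Newton iteration with analytic
# gradients. Posterior spread is supplied by the out-of-sample uncertainty
# module, not by this fit.

#' Balancing-model configuration
#'
#' @param sigma_base Prior sd of relative baseline deviations.
#' @param sigma_mig Prior marginal sd of migration rates (per capita-year).
#' @param rho_age,rho_time AR1 correlations of the migration prior across age
#'   and time knots (in (0,1)).
#' @param knot_age_step,knot_time_step Knot spacing (years of age / calendar
#'   years) of the migration surface.
#' @param sigma_census Census log-count sd at prime ages.
#' @param young_mult Variance-schedule multiplier at ages 0-4.
#' @param old_rate Exponential growth rate of the census sd after age 45.
#' @param max_census_age Oldest census age group start included in the
#'   likelihood (one fit per candidate; see [select_version()]).
#' @param reltol Optimizer relative tolerance.
#' @param seed Seed (kept for provenance; the MAP fit is deterministic).
#' @return List of class `balance_config`.
#' @export
balance_config <- function(sigma_base = 0.1, sigma_mig = 0.05,
                           rho_age = 0.9, rho_time = 0.95,
                           knot_age_step = 2, knot_time_step = 2,
                           sigma_census = 0.05, young_mult = 2,
                           old_rate = 0.03, max_census_age = 95L,
                           reltol = 1e-10, seed = 1L) {
  stopifnot(rho_age > 0, rho_age < 1, rho_time > 0, rho_time < 1,
            sigma_base > 0, sigma_mig > 0, sigma_census > 0)
  structure(as.list(environment()), class = "balance_config")
}

#' Census input-variance schedule by age
#'
#' Log-count standard deviations: inflated at ages 0-4, flat over 5-44, and
#' increasing log-linearly from age 45 to the open interval (age misreporting
#' grows with age).
#'
#' @param config A [balance_config()].
#' @param ages Ages at which to evaluate (default 0..95).
#' @return Positive sds per age.
#' @export
variance_schedule <- function(config, ages = 0:95) {
  s <- rep(config$sigma_census, length(ages))
  s[ages < 5] <- s[ages < 5] * config$young_mult
  old <- ages >= 45
  s[old] <- s[old] * exp(config$old_rate * (ages[old] - 45))
  s
}

# AR1 precision with unit marginal variance (tridiagonal), dense
.ar1_precision <- function(n, rho) {
  if (n == 1) return(matrix(1, 1, 1))
  Q <- diag(c(1, rep(1 + rho^2, n - 2), 1))
  for (i in 1:(n - 1)) Q[i, i + 1] <- Q[i + 1, i] <- -rho
  Q / (1 - rho^2)
}

# bilinear interpolation weights from a knot grid to full (ages x intervals)
.interp_1d <- function(full, knots) {
  W <- matrix(0, length(full), length(knots))
  for (i in seq_along(full)) {
    x <- full[i]
    j <- findInterval(x, knots, all.inside = TRUE)
    x0 <- knots[j]; x1 <- knots[min(j + 1, length(knots))]
    w <- if (x1 > x0) (x - x0) / (x1 - x0) else 0
    w <- min(max(w, 0), 1)
    W[i, j] <- 1 - w
    if (w > 0) W[i, min(j + 1, length(knots))] <- w
  }
  W
}

# model cells for one parameter setting: project and aggregate to the
# included census age groups
.cells_from_grid <- function(grid, censuses, keep) {
  yrs <- grid_years(grid)
  unlist(lapply(seq_along(censuses), function(ci) {
    cc <- censuses[[ci]]$counts[keep[[ci]], ]
    ti <- match(censuses[[ci]]$year, yrs)
    vapply(seq_len(nrow(cc)), function(r) {
      a1 <- cc$age_start[r]
      a2 <- if (cc$age_end[r] == -1L) 95L else cc$age_end[r] - 1L
      si <- match(cc$sex[r], SEXES)
      sum(grid[(a1:min(a2, 95)) + 1, si, ti])
    }, numeric(1))
  }))
}

# rows of each census to keep in the likelihood
.kept_rows <- function(censuses, max_age) {
  lapply(censuses, function(cn) {
    cc <- cn$counts
    keep <- cc$age_start <= max_age
    if (isTRUE(cn$drop_under5)) keep <- keep & cc$age_start >= 5
    if (isTRUE(cn$outlier)) keep <- keep & FALSE
    which(keep)
  })
}

#' Fit the demographic balancing model (MAP)
#'
#' Maximises the log posterior: Gaussian likelihood of log adjusted census
#' counts around log model counts (variance from [variance_schedule()]),
#' a Gaussian prior on relative baseline deviations around the initial
#' baseline, and the mean-zero AR1 x AR1 prior on migration-rate knots. Model
#' counts are generated by [ccmpp_project()]; under-5 and maximum-age
#' exclusions are honoured. Deterministic given the configuration.
#'
#' @param censuses List of adjusted `census_observation`s (see
#'   [adjust_census()]); counts must have an `adjusted` column.
#' @param asfr Single-age fertility (45 x n_intervals) per woman-year.
#' @param srb Sex ratio at birth (scalar or per interval).
#' @param surv Survivorship as in [ccmpp_project()].
#' @param init_baseline 96 x 2 matrix (or [population_grid()]): initial
#'   baseline population, assumed measured with substantial error.
#' @param years Year grid (baseline year first).
#' @param config A [balance_config()].
#' @return Object of class `balance_fit`: `baseline`, `migration`
#'   ([migration_surface()] of counts, with rates in `attr(, "rates")`),
#'   `pop` (fitted trajectory, exactly the projection of the fitted baseline
#'   and migration), `r2` (in-sample log-space R-squared), `nlp` (negative
#'   log posterior), `max_census_age`, `clipped`.
#' @export
fit_map <- function(censuses, asfr, srb, surv, init_baseline, years,
                    config = balance_config()) {
  if (inherits(init_baseline, "population_grid"))
    init_baseline <- init_baseline[, , 1]
  init_baseline <- matrix(init_baseline, 96, 2)
  n <- length(years); ni <- n - 1
  keep <- .kept_rows(censuses, config$max_census_age)
  if (length(censuses) > 0 && sum(lengths(keep)) == 0)
    stop("no census cells remain after exclusions")

  run <- function(base, G) {
    mig <- if (is.null(G)) NULL else migration_surface(G, years[-n])
    ccmpp_project(base, asfr, srb, surv, mig, years = years)
  }

  # knot structure
  ka <- unique(c(seq(0, 95, config$knot_age_step), 95))
  kt <- unique(c(seq(years[1], years[ni], config$knot_time_step), years[ni]))
  Wa <- .interp_1d(0:95, ka)
  Wt <- .interp_1d(years[1:ni], kt)
  nka <- length(ka); nkt <- length(kt)
  npm <- nka * nkt                   # migration knots per sex
  nb <- nka                          # baseline knots per sex

  # zero-migration reference projection (converts knot rates to counts)
  proj0 <- run(init_baseline, NULL)
  Nref <- unclass(proj0$pop)[, , 1:ni, drop = FALSE]

  rate_surface <- function(theta_mig) { # nka*nkt vector -> 96 x ni
    Wa %*% matrix(theta_mig, nka, nkt) %*% t(Wt)
  }
  build_G <- function(tm_f, tm_m) {
    G <- array(0, c(96, 2, ni))
    G[, 1, ] <- as.matrix(rate_surface(tm_f)) * Nref[, 1, ]
    G[, 2, ] <- as.matrix(rate_surface(tm_m)) * Nref[, 2, ]
    G
  }
  baseline_of <- function(tb_f, tb_m) {
    dev <- cbind(Wa %*% tb_f, Wa %*% tb_m)
    init_baseline * (1 + dev)
  }

  npar <- 2 * nb + 2 * npm
  idx_bf <- 1:nb; idx_bm <- nb + 1:nb
  idx_gf <- 2 * nb + 1:npm; idx_gm <- 2 * nb + npm + 1:npm

  unpack <- function(th) list(bf = th[idx_bf], bm = th[idx_bm],
                              gf = th[idx_gf], gm = th[idx_gm])
  grid_of <- function(th) {
    p <- unpack(th)
    run(baseline_of(p$bf, p$bm), build_G(p$gf, p$gm))
  }

  # priors
  Qmig <- kronecker(.ar1_precision(nkt, config$rho_time),
                    .ar1_precision(nka, config$rho_age)) / config$sigma_mig^2
  Qbase <- diag(nb) / config$sigma_base^2

  have_data <- length(censuses) > 0 && sum(lengths(keep)) > 0
  if (!have_data) {
    theta <- rep(0, npar)
    proj <- grid_of(theta)
    fit <- structure(list(baseline = init_baseline, migration =
                            migration_surface(array(0, c(96, 2, ni)),
                                              years[-n]),
                          pop = proj$pop, r2 = NA_real_, nlp = 0,
                          max_census_age = config$max_census_age,
                          clipped = proj$clipped, cells = NULL),
                     class = "balance_fit")
    return(fit)
  }

  # observed cells and weights
  obs <- unlist(lapply(seq_along(censuses), function(ci) {
    cc <- censuses[[ci]]$counts[keep[[ci]], ]
    if (is.null(cc$adjusted)) cc$value else cc$adjusted
  }))
  cell_sd <- unlist(lapply(seq_along(censuses), function(ci) {
    cc <- censuses[[ci]]$counts[keep[[ci]], ]
    mid <- ifelse(cc$age_end == -1L, 95, (cc$age_start + cc$age_end) / 2)
    variance_schedule(config, ages = mid)
  }))
  if (any(obs <= 0)) stop("nonpositive adjusted census counts")
  w <- 1 / cell_sd^2
  logc <- log(obs)

  # linear design: cells(theta) = cells0 + X theta (projection is linear)
  cells0 <- .cells_from_grid(proj0$pop, censuses, keep)
  X <- matrix(0, length(cells0), npar)
  unit <- function(j) { e <- rep(0, npar); e[j] <- 1; e }
  for (j in seq_len(npar)) {
    p <- unpack(unit(j))
    if (j <= 2 * nb) {
      pj <- run(baseline_of(p$bf, p$bm), NULL)
    } else {
      pj <- run(init_baseline, build_G(p$gf, p$gm))
    }
    X[, j] <- .cells_from_grid(pj$pop, censuses, keep) - cells0
  }

  nlp <- function(th) {
    y <- cells0 + as.numeric(X %*% th)
    if (any(y <= 0)) return(1e12)
    p <- unpack(th)
    0.5 * sum(w * (log(y) - logc)^2) +
      0.5 * (sum(p$bf * (Qbase %*% p$bf)) + sum(p$bm * (Qbase %*% p$bm)) +
               sum(p$gf * (Qmig %*% p$gf)) + sum(p$gm * (Qmig %*% p$gm)))
  }
  gr <- function(th) {
    y <- cells0 + as.numeric(X %*% th)
    y <- pmax(y, 1e-8)
    g_lik <- as.numeric(crossprod(X, w * (log(y) - logc) / y))
    p <- unpack(th)
    g_pri <- c(as.numeric(Qbase %*% p$bf), as.numeric(Qbase %*% p$bm),
               as.numeric(Qmig %*% p$gf), as.numeric(Qmig %*% p$gm))
    g_lik + g_pri
  }

  th0 <- rep(0, npar)
  opt <- stats::optim(th0, nlp, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = config$reltol))
  if (opt$value > nlp(th0) + 1e-8)
    stop("optimizer failed to improve on the initialization; nlp = ",
         signif(opt$value, 6))
  th <- opt$par
  p <- unpack(th)
  G <- build_G(p$gf, p$gm)
  base_fit <- baseline_of(p$bf, p$bm)
  if (any(base_fit < 0)) base_fit <- pmax(base_fit, 0)
  mig <- migration_surface(G, years[-n],
                           hyper = list(sigma_mig = config$sigma_mig,
                                        rho_age = config$rho_age,
                                        rho_time = config$rho_time))
  rates <- array(0, c(96, 2, ni))
  rates[, 1, ] <- as.matrix(rate_surface(p$gf))
  rates[, 2, ] <- as.matrix(rate_surface(p$gm))
  attr(mig, "rates") <- rates
  proj <- ccmpp_project(base_fit, asfr, srb, surv, mig, years = years)
  fitted_cells <- .cells_from_grid(proj$pop, censuses, keep)
  r2 <- {
    lf <- log(pmax(fitted_cells, 1e-12))
    1 - sum((lf - logc)^2) / sum((logc - mean(logc))^2)
  }
  structure(list(baseline = base_fit, migration = mig, pop = proj$pop,
                 r2 = r2, nlp = opt$value,
                 max_census_age = config$max_census_age,
                 clipped = proj$clipped,
                 cells = data.frame(obs = obs, fitted = fitted_cells,
                                    weight = w),
                 convergence = opt$convergence),
            class = "balance_fit")
}

#' @export
print.balance_fit <- function(x, ...) {
  cat("Balancing-model fit: max census age", x$max_census_age,
      "; in-sample log-space R^2 =",
      if (is.na(x$r2)) "NA (no data)" else signif(x$r2, 4),
      "; clipped cells:", x$clipped, "\n")
  invisible(x)
}

#' In-sample fit (log-space R-squared) of a balancing-model fit
#'
#' @param fit A [fit_map()] result.
#' @param censuses The censuses the fit was produced from.
#' @return R-squared of log fitted counts against log adjusted census counts
#'   over all included age-sex-census cells.
#' @export
insample_fit <- function(fit, censuses) {
  keep <- .kept_rows(censuses, fit$max_census_age)
  obs <- unlist(lapply(seq_along(censuses), function(ci) {
    cc <- censuses[[ci]]$counts[keep[[ci]], ]
    if (is.null(cc$adjusted)) cc$value else cc$adjusted
  }))
  if (length(obs) < 2) stop("fewer than 2 census cells")
  fitted <- .cells_from_grid(fit$pop, censuses, keep)
  lo <- log(obs); lf <- log(pmax(fitted, 1e-12))
  1 - sum((lf - lo)^2) / sum((lo - mean(lo))^2)
}

#' Select a model version across maximum-census-age candidates
#'
#' Among versions whose in-sample R-squared is within `r2_margin` of the best
#' and whose mean absolute migration rate over ages 55+ is below
#' `old_mig_cap`, pick the highest maximum census age; if no version
#' qualifies, fall back to the best R-squared.
#'
#' @param fits List of [fit_map()] results.
#' @param r2_margin Allowed R-squared shortfall from the best version.
#' @param old_mig_cap Cap on mean |migration rate| at ages 55+ (per year).
#' @return The selected `balance_fit`.
#' @export
select_version <- function(fits, r2_margin = 0.005, old_mig_cap = 0.01) {
  stopifnot(length(fits) >= 1)
  r2 <- vapply(fits, function(f) ifelse(is.na(f$r2), -Inf, f$r2), numeric(1))
  old_mig <- vapply(fits, function(f) {
    r <- attr(f$migration, "rates")
    if (is.null(r)) 0 else mean(abs(r[56:96, , ]))
  }, numeric(1))
  ok <- r2 >= max(r2) - r2_margin & old_mig < old_mig_cap
  if (any(ok)) {
    cand <- which(ok)
    ages <- vapply(fits[cand], `[[`, numeric(1), "max_census_age")
    fits[[cand[which.max(ages)]]]
  } else {
    fits[[which.max(r2)]]
  }
}
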