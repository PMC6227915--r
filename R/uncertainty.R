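# Population uncertainty from out-of-sample predictive validity: hold out
# censuses, refit the balancing model, and model the error sd as a monotone
# (isotonic) function of the number of years to the nearest used census;
# combine with the completeness-model coefficient uncertainty and generate
# draws of percentage error, fully correlated across ages within a
# location-year.

#' Hold-out errors of the balancing model
#'
#' Drops one census at a time, refits [fit_map()] on the remainder, and
#' records the relative error of the predicted total against the held-out
#' adjusted census total, together with the gap (years to the nearest census
#' that remained in the fit).
#'
#' @param censuses List of adjusted `census_observation`s (>= 2).
#' @param asfr,srb,surv,init_baseline,years,config As in [fit_map()].
#' @return data.frame with columns `year`, `gap`, `rel_error`.
#' @export
oos_holdout_errors <- function(censuses, asfr, srb, surv, init_baseline,
                               years, config = balance_config()) {
  if (length(censuses) < 2)
    stop("need at least 2 censuses to hold one out")
  rows <- lapply(seq_along(censuses), function(i) {
    held <- censuses[[i]]
    rest <- censuses[-i]
    fit <- fit_map(rest, asfr, srb, surv, init_baseline, years, config)
    keep <- .kept_rows(list(held), config$max_census_age)
    obs <- held$counts[keep[[1]], ]
    obs_tot <- sum(if (is.null(obs$adjusted)) obs$value else obs$adjusted)
    pred_tot <- sum(.cells_from_grid(fit$pop, list(held), keep))
    gap <- min(abs(held$year - vapply(rest, `[[`, numeric(1), "year")))
    data.frame(year = held$year, gap = gap,
               rel_error = (pred_tot - obs_tot) / obs_tot)
  })
  do.call(rbind, rows)
}

#' Relative sd of the completeness adjustment from the PES model
#'
#' Delta-method propagation of the completeness-model coefficient
#' variance-covariance to the relative scale of adjusted counts.
#'
#' @param model A [fit_completeness_model()] result.
#' @param sdi SDI at which to evaluate.
#' @return Relative standard deviation(s).
#' @export
completeness_rel_sd <- function(model, sdi) {
  x <- cbind(1, sdi)
  sd_eta <- sqrt(pmax(rowSums((x %*% model$vcov) * x), 0))
  eta <- model$coef[1] + model$coef[2] * sdi
  cval <- model$ceiling * stats::plogis(eta)
  # d log c / d eta = 1 - c/ceiling
  sd_eta * (1 - cval / model$ceiling)
}

#' Fit the out-of-sample error model
#'
#' Pools hold-out relative errors (possibly across synthetic replicates) and
#' fits the error sd as an isotonic (monotone nondecreasing) function of the
#' gap to the nearest census, scaling absolute errors to a normal sd.
#'
#' @param errors data.frame with columns `gap` and `rel_error`, e.g. rbind-ed
#'   [oos_holdout_errors()] results.
#' @param sigma_pes Relative sd from the completeness model (scalar; see
#'   [completeness_rel_sd()]).
#' @param n_draws Number of draws the model will generate (default 1000).
#' @return Object of class `error_model`: `sigma_gap` (function of gap),
#'   `gap_knots`, `gap_sd`, `sigma_pes`, `n_draws`.
#' @export
fit_oos_error_model <- function(errors, sigma_pes = 0, n_draws = 1000) {
  stopifnot(nrow(errors) >= 2, all(errors$gap >= 0))
  ord <- order(errors$gap)
  g <- errors$gap[ord]
  a <- abs(errors$rel_error[ord]) * sqrt(pi / 2)  # E|N(0,s)| = s*sqrt(2/pi)
  iso <- stats::isoreg(g, a)
  knots <- unique(g)
  sdk <- vapply(knots, function(k) max(iso$yf[g <= k]), numeric(1))
  f <- if (length(knots) >= 2) {
    stats::approxfun(knots, sdk, method = "linear", rule = 2)
  } else {
    function(gap) rep(sdk, length(gap))
  }
  structure(list(sigma_gap = function(gap) pmax(f(gap), 0),
                 gap_knots = knots, gap_sd = sdk,
                 sigma_pes = sigma_pes, n_draws = n_draws),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Out-of-sample error model:", length(x$gap_knots), "gap knots, sd",
      signif(min(x$gap_sd), 3), "-", signif(max(x$gap_sd), 3),
      "; sigma_pes =", signif(x$sigma_pes, 3), "\n")
  invisible(x)
}

#' Population draws and 95 percent uncertainty intervals
#'
#' Per location-year, draws a relative error `e ~ N(0, sigma_gap(gap)^2 +
#' sigma_pes^2)` (the gap term is zeroed in registry years, where only
#' completeness uncertainty remains), truncated at -0.9 to keep counts
#' positive and fully correlated across ages within the year; draws are
#' `mean * (1 + e)` and the interval is the 2.5th and 97.5th percentiles.
#'
#' @param mean_pop A [population_grid()] of point estimates.
#' @param gaps Years to the nearest census, one per year of `mean_pop`.
#' @param model A [fit_oos_error_model()] result.
#' @param registry_years Years with population-registry counts (no
#'   between-census uncertainty).
#' @param n_draws Number of draws (default from the model, 1000).
#' @param seed Integer seed; draws are deterministic given it.
#' @return List: `factors` (years x draws matrix of `1 + e`), `totals`
#'   (years x draws), `summary` (data.frame year/mean/lower/upper of totals),
#'   `n_draws`.
#' @export
population_draws <- function(mean_pop, gaps, model, registry_years = integer(0),
                             n_draws = model$n_draws, seed = 1L) {
  yrs <- grid_years(mean_pop)
  stopifnot(length(gaps) == length(yrs))
  if (n_draws < 2) stop("need at least 2 draws")
  if (n_draws < 100) warning("fewer than 100 draws; intervals will be noisy")
  sg <- model$sigma_gap(gaps)
  sg[yrs %in% registry_years] <- 0
  sd_y <- sqrt(sg^2 + model$sigma_pes^2)
  set.seed(seed)
  eps <- matrix(stats::rnorm(length(yrs) * n_draws), length(yrs), n_draws)
  eps <- pmax(eps * sd_y, -0.9)
  factors <- 1 + eps
  tot <- pop_total(mean_pop)
  totals <- tot * factors
  qs <- t(apply(totals, 1, stats::quantile, probs = c(0.025, 0.975)))
  list(factors = factors, totals = totals,
       summary = data.frame(year = yrs, mean = tot,
                            lower = qs[, 1], upper = qs[, 2]),
       n_draws = n_draws)
}
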