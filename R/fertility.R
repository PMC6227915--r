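# Two-stage estimation of age-specific fertility rates (ASFR) from
# heterogeneous sources, plus extreme-age models and the sex ratio at birth.
#
# Stage 1 smooths vital-registration and complete-birth-history ASFR with a
# covariate prior, source-bias adjustment to a reference source, local time
# smoothing of residuals, and Gaussian-process regression (Matern-5/2 over
# time). Stage 2 splits aggregate data (summary-birth-history children ever
# born, total births) into pseudo-ASFR points using the stage-1 estimates, and
# the model is re-fit with the augmented data.
#
# All rates are per woman-year internally; multiply by 1000 only at I/O.

FERT_GROUPS <- seq(10L, 50L, 5L)

#' ASFR estimate container
#'
#' @param mean 9 x n matrix of group rates per woman-year (groups 10-14 ...
#'   50-54 by row, years by column).
#' @param years Calendar years (columns).
#' @param draws Optional 9 x n x n_draws array; the draw mean is recentred to
#'   the point estimate.
#' @param stage Label: `"prior"`, `"stage1"` or `"final"`.
#' @return Object of class `asfr_estimate`.
#' @export
asfr_estimate <- function(mean, years, draws = NULL, stage = "stage1") {
  stopifnot(nrow(mean) == 9, ncol(mean) == length(years), all(mean >= 0))
  dimnames(mean) <- list(age_start = FERT_GROUPS, year = years)
  if (!is.null(draws)) {
    stopifnot(dim(draws)[1] == 9, dim(draws)[2] == length(years))
    m <- apply(draws, c(1, 2), base::mean)
    adj <- ifelse(m > 0, mean / m, 1)
    draws <- sweep(draws, c(1, 2), adj, `*`)
  }
  structure(list(mean = mean, years = years, draws = draws, stage = stage),
            class = "asfr_estimate")
}

#' @export
print.asfr_estimate <- function(x, ...) {
  tfr <- 5 * colSums(x$mean)
  cat("ASFR estimate (", x$stage, "): ", length(x$years), " years, TFR ",
      signif(tfr[1], 3), " -> ", signif(tfr[length(tfr)], 3),
      if (!is.null(x$draws)) paste0(", ", dim(x$draws)[3], " draws"), "\n",
      sep = "")
  invisible(x)
}

# Matern 5/2 covariance over time distances
.matern52 <- function(d, ls) {
  r <- sqrt(5) * abs(d) / ls
  (1 + r + r^2 / 3) * exp(-r)
}

# GP regression of y (at years td, variance v, prior mean m_d) onto a grid
# (prior mean m_g); returns posterior mean and covariance on the grid
.gp_posterior <- function(grid, td, y, v, m_g, m_d, amp, ls) {
  if (length(td) == 0 || amp <= 1e-10)
    return(list(mean = m_g, cov = matrix(0, length(grid), length(grid))))
  Kdd <- amp^2 * .matern52(outer(td, td, `-`), ls) + diag(pmax(v, 1e-10),
                                                          length(td))
  Kgd <- amp^2 * .matern52(outer(grid, td, `-`), ls)
  Kgg <- amp^2 * .matern52(outer(grid, grid, `-`), ls)
  U <- chol(Kdd)
  a <- backsolve(U, forwardsolve(t(U), y - m_d))
  W <- backsolve(U, forwardsolve(t(U), t(Kgd)))
  cov <- Kgg - Kgd %*% W
  list(mean = as.numeric(m_g + Kgd %*% a), cov = (cov + t(cov)) / 2)
}

# tricube-kernel local weighted mean of residuals on the year grid
.smooth_residuals <- function(grid, td, r, w, window) {
  vapply(grid, function(t0) {
    u <- abs(td - t0) / window
    k <- ifelse(u < 1, (1 - u^3)^3, 0) * w
    if (sum(k) <= 0) 0 else sum(k * r) / sum(k)
  }, numeric(1))
}

# data-density tier: smoothing window and GP length-scale by number of
# distinct data years for a group
.density_hyper <- function(n_years) {
  if (n_years >= 30) list(window = 3, ls = 4)
  else if (n_years >= 10) list(window = 10, ls = 12)
  else list(window = 20, ls = 20)
}

.fert_defaults <- function() {
  list(years = NULL, n_draws = 100, spline_knot = 0.1, var_floor = 1e-8)
}

# resolve the reference source; error with candidates if unresolvable
.reference_source <- function(data) {
  if (any(data$reference)) return(unique(data$source_id[data$reference])[1])
  for (ty in c("vr", "cbh")) {
    s <- unique(data$source_id[data$source_type == ty])
    if (length(s)) return(s[1])
  }
  stop("no reference source resolvable; candidates: ",
       paste(unique(data$source_id), collapse = ", "))
}

# per-source multiplicative bias (log offsets) vs the reference, from a fixed
# effect model on cells (group x year) observed by more than one source
.source_offsets <- function(df, ref) {
  offs <- stats::setNames(rep(0, length(unique(df$source_id))),
                          unique(df$source_id))
  if (length(offs) == 1) return(offs)
  df$cell <- interaction(df$age_start, df$year, drop = TRUE)
  dup <- names(which(table(df$cell) > 1))
  sub <- df[df$cell %in% dup & df$value > 0, ]
  if (nrow(sub) == 0 || length(unique(sub$source_id)) < 2) return(offs)
  sub$source_id <- stats::relevel(factor(sub$source_id), ref = ref)
  fit <- stats::lm(log(value) ~ cell + source_id, data = sub)
  cf <- stats::coef(fit)
  sc <- grep("^source_id", names(cf))
  est <- cf[sc]
  names(est) <- sub("^source_id", "", names(est))
  est[!is.finite(est)] <- 0
  offs[names(est)] <- est
  offs
}

# estimate one group's time series: prior (log scale) + smoothed residual +
# GP regression; returns list(mean log curve, cov)
.fit_group <- function(grid, gdat, log_prior_grid, log_prior_data,
                       config) {
  if (nrow(gdat) == 0)
    return(list(mean = log_prior_grid,
                cov = matrix(0, length(grid), length(grid))))
  lv <- log(pmax(gdat$value, 1e-10))
  r <- lv - log_prior_data
  relv <- pmax(gdat$variance / pmax(gdat$value, 1e-10)^2, config$var_floor)
  hyp <- .density_hyper(length(unique(gdat$year)))
  rt_grid <- .smooth_residuals(grid, gdat$year, r, 1 / relv, hyp$window)
  rt_data <- .smooth_residuals(gdat$year, gdat$year, r, 1 / relv, hyp$window)
  amp <- max(stats::mad(rt_grid, center = 0), stats::mad(r, center = 0))
  # non-sampling variance: second-difference noise estimator on the year-mean
  # residual series (insensitive to the smooth signal component)
  ubar <- tapply(r, gdat$year, mean)
  nsv <- if (length(ubar) >= 4) {
    (stats::mad(diff(ubar, differences = 2), center = 0) / sqrt(6))^2
  } else {
    stats::mad(r - rt_data, center = 0)^2
  }
  gp <- .gp_posterior(grid, gdat$year, r, relv + nsv, rt_grid, rt_data,
                      amp, hyp$ls)
  list(mean = log_prior_grid + gp$mean, cov = gp$cov)
}

#' First-stage ASFR estimation (spatiotemporal GP regression, time dimension)
#'
#' Estimates group ASFR from vital-registration and complete-birth-history
#' points: (i) the 20-24 prior is a linear model of log rate on schooling (or
#' an intercept when no covariate is supplied); (ii) other groups' priors are
#' a natural cubic spline of the estimated 20-24 rate plus the schooling term
#' (schooling omitted in the high-income super-region); (iii) source random
#' effects shift every source to the reference source's level; (iv) residuals
#' are locally smoothed in time and refined by Gaussian-process regression
#' (Matern-5/2), with data variance equal to sampling plus estimated
#' non-sampling variance. With a single location the spatial dimension is
#' degenerate and smoothing is over time only.
#'
#' @param data A `fertility_obs` data.frame; rows with `measure == "asfr"`
#'   are used.
#' @param education Optional data.frame (`year`, `age_start`, `value`) of mean
#'   years of schooling for women of each age group.
#' @param super_region Label; `"high-income"` drops the schooling covariate.
#' @param config Named list overriding defaults (`years`, `n_draws`,
#'   `spline_knot`, `var_floor`).
#' @param stage Stage label stored on the result.
#' @param seed Seed for posterior draws.
#' @return An [asfr_estimate()] with draws. Groups without any data keep
#'   their prior (zero when no prior is identifiable); ages 10-14 and 50-54
#'   are normally filled afterwards by [apply_extreme_ages()].
#' @export
fit_stage1 <- function(data, education = NULL, super_region = "other",
                       config = list(), stage = "stage1", seed = 1L) {
  config <- utils::modifyList(.fert_defaults(), config)
  stopifnot(inherits(data, "data.frame"))
  adat <- data[data$measure == "asfr" & data$value >= 0, ]
  if (nrow(adat) == 0) stop("no ASFR observations (VR/CBH) in data")
  grid <- if (is.null(config$years))
    seq(min(adat$year), max(adat$year)) else config$years
  adat <- adat[adat$year %in% grid, ]

  ref <- .reference_source(adat)
  offs <- .source_offsets(adat, ref)
  adat$value <- adat$value / exp(offs[adat$source_id])

  use_edu <- !is.null(education) && super_region != "high-income"
  edu_at <- function(g, yrs) {
    if (!use_edu) return(rep(0, length(yrs)))
    e <- education[education$age_start == g, ]
    stats::approx(e$year, e$value, xout = yrs, rule = 2)$y
  }

  mean_log <- matrix(NA_real_, 9, length(grid))
  covs <- vector("list", 9)

  # group 20-24 first: prior linear in schooling (intercept-only without it)
  g24 <- adat[adat$age_start == 20, ]
  if (nrow(g24) > 0) {
    pri_df <- data.frame(lv = log(pmax(g24$value, 1e-10)),
                         edu = edu_at(20, g24$year))
    pfit <- if (use_edu && stats::var(pri_df$edu) > 0)
      stats::lm(lv ~ edu, data = pri_df) else stats::lm(lv ~ 1, data = pri_df)
    lp_grid <- as.numeric(stats::predict(pfit, newdata = data.frame(
      edu = edu_at(20, grid))))
    lp_data <- as.numeric(stats::predict(pfit, newdata = data.frame(
      edu = edu_at(20, g24$year))))
    r24 <- .fit_group(grid, g24, lp_grid, lp_data, config)
    mean_log[3, ] <- r24$mean
    covs[[3]] <- r24$cov
  } else {
    mean_log[3, ] <- log(1e-10)
    covs[[3]] <- matrix(0, length(grid), length(grid))
  }
  est2024 <- exp(mean_log[3, ])

  for (gi in seq_along(FERT_GROUPS)) {
    if (gi == 3) next
    g <- FERT_GROUPS[gi]
    gdat <- adat[adat$age_start == g, ]
    if (nrow(gdat) == 0) {
      mean_log[gi, ] <- log(1e-10)
      covs[[gi]] <- matrix(0, length(grid), length(grid))
      next
    }
    x_data <- est2024[match(gdat$year, grid)]
    xd <- data.frame(lv = log(pmax(gdat$value, 1e-10)), x = x_data,
                     edu = edu_at(g, gdat$year))
    kn <- config$spline_knot
    # the fertility-upturn knot only enters when it lies inside the observed
    # range of the 20-24 rate; otherwise fall back to its median
    if (kn <= min(xd$x) || kn >= max(xd$x)) kn <- stats::median(xd$x)
    use_spline <- length(unique(xd$x)) >= 4 &&
      kn > min(xd$x) && kn < max(xd$x)
    form <- if (use_spline) {
      if (use_edu && stats::var(xd$edu) > 0)
        lv ~ splines::ns(x, knots = kn) + edu
      else lv ~ splines::ns(x, knots = kn)
    } else if (use_edu && stats::var(xd$edu) > 0) lv ~ x + edu else lv ~ x
    pfit <- tryCatch(stats::lm(form, data = xd),
                     error = function(e) stats::lm(lv ~ 1, data = xd))
    nd_g <- data.frame(x = est2024, edu = edu_at(g, grid))
    nd_d <- data.frame(x = x_data, edu = edu_at(g, gdat$year))
    lp_grid <- as.numeric(stats::predict(pfit, newdata = nd_g))
    lp_data <- as.numeric(stats::predict(pfit, newdata = nd_d))
    rg <- .fit_group(grid, gdat, lp_grid, lp_data, config)
    mean_log[gi, ] <- rg$mean
    covs[[gi]] <- rg$cov
  }

  est <- exp(mean_log)
  nd <- config$n_draws
  draws <- array(0, c(9, length(grid), nd))
  set.seed(seed)
  for (gi in 1:9) {
    cv <- covs[[gi]]
    ev <- eigen(cv, symmetric = TRUE)
    pos <- pmax(ev$values, 0)
    L <- ev$vectors %*% diag(sqrt(pos), length(pos))
    z <- matrix(stats::rnorm(length(grid) * nd), length(grid), nd)
    draws[gi, , ] <- exp(mean_log[gi, ] + L %*% z)
  }
  out <- asfr_estimate(est, grid, draws = draws, stage = stage)
  out$source_offsets <- offs
  out$reference <- ref
  out
}

#' Split aggregate fertility observations into pseudo-ASFR points
#'
#' For each summary-birth-history cohort, the ratio of observed children ever
#' born to the stage-1-implied cohort cumulative fertility scales the stage-1
#' cohort rates into period pseudo-ASFR points at each 5-year lag where the
#' cohort occupies a single 5-year age group. Total-births records are split
#' into group birth counts proportional to the stage-1 age shares (converted
#' to pseudo-ASFR when female population counts are supplied). Variances are
#' propagated from the observations on the relative scale.
#'
#' @param data A `fertility_obs` data.frame (rows with `measure` `"ceb"` or
#'   `"births"` are processed).
#' @param stage1 An [asfr_estimate()].
#' @param women Optional 9 x n matrix of female population by group/year for
#'   converting split births to rates.
#' @return A data.frame of pseudo-observations in the `fertility_obs` schema
#'   (`source_type` suffixed with `"_split"`).
#' @export
split_aggregates <- function(data, stage1, women = NULL) {
  stopifnot(inherits(stage1, "asfr_estimate"))
  grid <- stage1$years
  single <- expand_asfr_groups(stage1$mean)  # 45 x n, ages 10..54
  imp_ceb <- function(sy, a) {
    if (a <= 10) return(0)
    xs <- 10:(min(a, 55) - 1)
    yrs <- pmin(pmax(sy - (a - xs), min(grid)), max(grid))
    sum(single[cbind(xs - 9, match(yrs, grid))])
  }
  rows <- list()
  sbh <- data[data$measure == "ceb", ]
  for (i in seq_len(nrow(sbh))) {
    ob <- sbh[i, ]
    implied <- mean(vapply(ob$age_start:(ob$age_end - 1),
                           function(a) imp_ceb(ob$year, a), numeric(1)))
    if (implied <= 0) {
      if (ob$value > 0)
        stop("implied cumulative fertility is zero for cohort ",
             ob$age_start, "-", ob$age_end - 1, " with observed CEB > 0")
      next
    }
    ratio <- ob$value / implied
    relvar <- ob$variance / max(ob$value, 1e-8)^2
    k <- 0
    repeat {
      g <- ob$age_start - 5 * k
      y <- ob$year - 5 * k
      if (g < 10 || y < min(grid)) break
      if (g <= 50 && g %% 5 == 0) {
        gi <- match(g, FERT_GROUPS)
        val <- ratio * stage1$mean[gi, match(y, grid)]
        rows[[length(rows) + 1]] <- data.frame(
          location = ob$location, year = y,
          source_type = paste0(ob$source_type, "_split"),
          source_id = paste0(ob$source_id, "_split"),
          age_start = g, age_end = g + 5, measure = "asfr", value = val,
          variance = val^2 * relvar, reference = FALSE)
      }
      k <- k + 1
    }
  }
  tb <- data[data$measure == "births", ]
  for (i in seq_len(nrow(tb))) {
    ob <- tb[i, ]
    yi <- match(ob$year, grid)
    if (is.na(yi)) next
    if (is.null(women)) next  # cannot convert births to rates without women
    share <- stage1$mean[, yi] * women[, yi]
    if (sum(share) <= 0) next
    share <- share / sum(share)
    bi <- ob$value * share
    val <- ifelse(women[, yi] > 0, bi / (5 * women[, yi]), 0)
    relvar <- ob$variance / max(ob$value, 1e-8)^2
    rows[[length(rows) + 1]] <- data.frame(
      location = ob$location, year = ob$year, source_type = "births_split",
      source_id = paste0(ob$source_id, "_split"), age_start = FERT_GROUPS,
      age_end = FERT_GROUPS + 5, measure = "asfr", value = val,
      variance = pmax(val, 1e-8)^2 * relvar, reference = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(location = character(), year = numeric(),
               source_type = character(), source_id = character(),
               age_start = integer(), age_end = integer(),
               measure = character(), value = numeric(), variance = numeric(),
               reference = logical())
  rownames(out) <- NULL
  out
}

#' Final ASFR estimation with split aggregate data
#'
#' Re-runs the stage-1 machinery on the union of the original ASFR points and
#' the pseudo-points produced by [split_aggregates()]. With no aggregate data
#' the result equals stage 1.
#'
#' @inheritParams fit_stage1
#' @param pseudo Pseudo-observations from [split_aggregates()].
#' @return An [asfr_estimate()] with stage `"final"`.
#' @export
fit_final <- function(data, pseudo = NULL, education = NULL,
                      super_region = "other", config = list(), seed = 1L) {
  adat <- data[data$measure == "asfr", ]
  all_data <- if (!is.null(pseudo) && nrow(pseudo) > 0)
    rbind(adat, pseudo) else adat
  class(all_data) <- c("fertility_obs", "data.frame")
  fit_stage1(all_data, education = education, super_region = super_region,
             config = config, stage = "final", seed = seed)
}

#' Fit the extreme-maternal-age fertility model
#'
#' On vital-registration data: regression of `log(ASFR[10-14]/ASFR[15-19])`
#' on `ASFR[15-19]`, and the (constant) mean ratio `ASFR[50-54]/ASFR[45-49]`.
#'
#' @param data A `fertility_obs` data.frame with VR rows for the four groups.
#' @return Object of class `extreme_age_model`: list `b0`, `b1`, `r5054`.
#' @export
fit_extreme_age_model <- function(data) {
  vr <- data[data$source_type == "vr" & data$measure == "asfr", ]
  key <- function(g) {
    d <- vr[vr$age_start == g, c("year", "value")]
    stats::setNames(d$value, d$year)
  }
  a10 <- key(10); a15 <- key(15); a45 <- key(45); a50 <- key(50)
  yrs1 <- intersect(names(a10), names(a15))
  yrs1 <- yrs1[a10[yrs1] > 0 & a15[yrs1] > 0]
  if (length(yrs1) < 3) stop("too few VR years with 10-14 and 15-19 rates")
  fit <- stats::lm(y ~ x, data = data.frame(
    y = log(a10[yrs1] / a15[yrs1]), x = a15[yrs1]))
  yrs2 <- intersect(names(a45), names(a50))
  yrs2 <- yrs2[a45[yrs2] > 0]
  if (length(yrs2) < 1) stop("no VR years with 45-49 and 50-54 rates")
  structure(list(b0 = unname(stats::coef(fit)[1]),
                 b1 = unname(stats::coef(fit)[2]),
                 r5054 = mean(a50[yrs2] / a45[yrs2])),
            class = "extreme_age_model")
}

#' Fill extreme maternal ages from the adjacent groups
#'
#' `ASFR[10-14] = ASFR[15-19] * exp(b0 + b1 * ASFR[15-19])` and
#' `ASFR[50-54] = r5054 * ASFR[45-49]`, applied to the point estimate and all
#' draws.
#'
#' @param est An [asfr_estimate()].
#' @param model An `extreme_age_model` (from [fit_extreme_age_model()] or
#'   built manually).
#' @return The modified [asfr_estimate()].
#' @export
apply_extreme_ages <- function(est, model) {
  stopifnot(inherits(est, "asfr_estimate"))
  fill <- function(m) {
    m[1, ] <- m[2, ] * exp(model$b0 + model$b1 * m[2, ])
    m[9, ] <- model$r5054 * m[8, ]
    m
  }
  est$mean <- fill(est$mean)
  if (!is.null(est$draws))
    for (d in seq_len(dim(est$draws)[3]))
      est$draws[, , d] <- fill(est$draws[, , d])
  est
}

#' Estimate the sex ratio at birth over time
#'
#' Gaussian-process regression of the proportion of live-born males around a
#' time-invariant prior mean corresponding to 1.05 males per female; the SRB
#' is `p / (1 - p)`. Without data the prior is returned.
#'
#' @param data Optional data.frame with columns `year`, `p_male`, `variance`.
#' @param years Output year grid.
#' @param prior_srb Prior sex ratio at birth (males per female).
#' @param ls GP length-scale in years.
#' @param n_draws Number of posterior draws.
#' @param seed Seed for draws.
#' @return Object of class `srb_series`: list with `srb` (named vector by
#'   year), `p_male`, `draws` (years x n_draws of SRB).
#' @export
estimate_srb <- function(data = NULL, years, prior_srb = 1.05, ls = 10,
                         n_draws = 100, seed = 1L) {
  p0 <- prior_srb / (1 + prior_srb)
  m_g <- rep(p0, length(years))
  if (is.null(data) || nrow(data) == 0) {
    gp <- list(mean = m_g, cov = matrix(0, length(years), length(years)))
  } else {
    if (any(data$p_male <= 0 | data$p_male >= 1))
      stop("proportions male must be in (0, 1)")
    v <- if ("variance" %in% names(data)) data$variance else
      rep(1e-5, nrow(data))
    amp <- max(stats::mad(data$p_male, center = p0), 0.005)
    gp <- .gp_posterior(years, data$year, data$p_male, pmax(v, 1e-9),
                        m_g, rep(p0, nrow(data)), amp, ls)
  }
  p <- pmin(pmax(gp$mean, 0.05), 0.95)
  srb <- p / (1 - p)
  set.seed(seed)
  ev <- eigen(gp$cov, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
  pd <- pmin(pmax(gp$mean + L %*% matrix(stats::rnorm(length(years) * n_draws),
                                         length(years)), 0.05), 0.95)
  draws <- pd / (1 - pd)
  if (any(srb < 0.8 | srb > 1.4))
    warning("estimated SRB outside the plausible band (0.8, 1.4)")
  structure(list(srb = stats::setNames(srb, years), p_male = p, draws = draws,
                 years = years), class = "srb_series")
}

#' @export
print.srb_series <- function(x, ...) {
  cat("SRB series:", length(x$years), "years, range",
      signif(min(x$srb), 4), "-", signif(max(x$srb), 4), "\n")
  invisible(x)
}
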