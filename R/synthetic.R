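# Synthetic countries with known truth, emulating the statistical structure of
# real demographic data ecosystems: undercounted and age-heaped censuses,
# biased vital-registration fertility, retrospective birth histories, and
# smooth age-time migration surfaces with optional shock years. Every
# downstream stage has a parameter-recovery test against this truth.

#' Hadwiger-type age-specific fertility schedule
#'
#' Smooth, positive, unimodal schedule over single ages 10..54, normalised so
#' the single-age rates sum to the target total fertility.
#'
#' @param tfr Total fertility (births per woman over ages 10..54).
#' @param mode Modal age of childbearing (years).
#' @param width Shape parameter; larger values concentrate fertility around
#'   the mode.
#' @return Named vector of length 45 (ages 10..54), per woman-year.
#' @export
hadwiger_asfr <- function(tfr, mode = 27, width = 1.7) {
  stopifnot(tfr >= 0, mode > 10, mode < 55, width > 0)
  x <- (10:54) - 10 + 0.5
  cc <- mode - 10
  raw <- (cc / x)^1.5 * exp(-width^2 * (cc / x + x / cc - 2))
  f <- if (sum(raw) > 0) raw / sum(raw) * tfr else raw
  names(f) <- 10:54
  f
}

#' Siler (Gompertz-Makeham plus childhood) mortality law
#'
#' `mx(a) = a1 exp(-b1 a) + c0 + a2 exp(b2 a)`.
#'
#' @param a1,b1 Childhood-component level and decay.
#' @param c0 Background (Makeham) rate.
#' @param a2,b2 Senescent (Gompertz) level and slope.
#' @param ages Ages at which to evaluate.
#' @return Death rates per person-year.
#' @export
siler_mx <- function(a1 = 0.08, b1 = 1.1, c0 = 5e-4, a2 = 3e-5, b2 = 0.095,
                     ages = 0:110) {
  a1 * exp(-b1 * ages) + c0 + a2 * exp(b2 * ages)
}

.default_scenario <- function() {
  list(
    years = 1950:2017,
    baseline_total = 5e6,
    baseline_growth = 0.02,          # stable-population shape parameter
    tfr_start = 6.0, tfr_end = 2.2,  # linear decline over the period
    asfr_mode = 27, asfr_width = 1.7,
    mort = list(a1 = 0.08, b1 = 1.1, c0 = 5e-4, a2 = 3e-5, b2 = 0.095),
    male_excess = 1.3,               # multiplier on c0 and a2 for males
    mort_improvement = 0.01,         # annual proportional decline in mx
    mig = list(amp = 0.002, peak_age = 25, age_sd = 10,
               shock_years = integer(0), shock_amp = 0,
               bump_years = integer(0), bump_amp = 0),
    srb = 1.05,
    sdi_start = 0.25, sdi_end = 0.75
  )
}

.sex_mx <- function(sc, year, y0, sex) {
  m <- sc$mort
  f <- exp(-sc$mort_improvement * (year - y0))
  male <- if (sex == "male") sc$male_excess else 1
  siler_mx(m$a1, m$b1, m$c0 * male, m$a2 * male, m$b2) * f
}

.lt_from_mx <- function(mx) {
  qx <- pmin(mx_to_qx(mx, a = 0.5), 1)
  qx[111] <- 1
  complete_lifetable(qx, a0 = 0.2, a110 = max(1 / mx[111], 1e-6))
}

#' Generate a synthetic country with known demographic truth
#'
#' Builds single-age fertility (Hadwiger schedule with a linear total-fertility
#' trend), Siler mortality with annual improvement, an age-peaked net-migration
#' surface (rates applied to the evolving population, with optional shock
#' years), a constant sex ratio at birth, and a development-index path; the
#' true population is the cohort-component projection of the stable-shape
#' baseline under those rates, so it satisfies the balancing identity exactly.
#'
#' @param config Named list overriding the default scenario; see
#'   `popfert:::.default_scenario()` for fields.
#' @param seed Integer seed; the truth is deterministic given `config`+`seed`.
#' @return An object of class `synthetic_truth`: list with `pop`
#'   ([population_grid()]), `flows`, `asfr` (45 x n matrix, single ages 10..54
#'   per woman-year), `mx` (111 x 2 x n array), `lifetables` (per year, per
#'   sex [complete_lifetable()]), `surv` (per interval survivorship pairs),
#'   `mig` ([migration_surface()]), `srb`, `sdi`, `years`, `scenario`.
#' @export
make_true_country <- function(config = list(), seed = 1L) {
  sc <- utils::modifyList(.default_scenario(), config)
  years <- sc$years
  if (length(years) < 3) stop("year range must cover at least 3 years")
  if (sc$baseline_total < 0) stop("negative baseline counts")
  set.seed(seed)
  n <- length(years)
  ni <- n - 1
  y0 <- years[1]

  # fertility truth: single ages 10..54 by year
  tfr_t <- seq(sc$tfr_start, sc$tfr_end, length.out = n)
  asfr <- vapply(seq_len(n),
                 function(i) hadwiger_asfr(tfr_t[i], sc$asfr_mode,
                                           sc$asfr_width),
                 numeric(45))
  dimnames(asfr) <- list(age = 10:54, year = years)

  # mortality truth and survivorship
  mx <- array(0, c(111, 2, n), dimnames = list(age = 0:110, sex = SEXES,
                                               year = years))
  lifetables <- vector("list", n)
  surv <- vector("list", max(ni, 1))
  for (i in seq_len(n)) {
    mx[, 1, i] <- .sex_mx(sc, years[i], y0, "female")
    mx[, 2, i] <- .sex_mx(sc, years[i], y0, "male")
    lifetables[[i]] <- list(female = .lt_from_mx(mx[, 1, i]),
                            male = .lt_from_mx(mx[, 2, i]))
    if (i <= ni)
      surv[[i]] <- list(female = survivorship_ratios(lifetables[[i]]$female),
                        male = survivorship_ratios(lifetables[[i]]$male))
  }

  # stable-shape baseline from year-1 mortality
  lxf <- lifetables[[1]]$female$lx
  lx96 <- c(lxf[1:95], sum(lifetables[[1]]$female$Lx[96:111]) /
              max(lifetables[[1]]$female$Lx[96], 1e-12) * lxf[96])
  lx96[!is.finite(lx96)] <- lxf[96]
  shape <- exp(-sc$baseline_growth * (0:95)) * pmax(lx96, 1e-12)
  base <- matrix(rep(shape / sum(shape) / 2 * sc$baseline_total, 2), 96, 2)

  # migration rate surface: Gaussian in age, flat in time plus shocks
  age_prof <- exp(-0.5 * ((0:95 - sc$mig$peak_age) / sc$mig$age_sd)^2)
  amp_t <- rep(sc$mig$amp, ni)
  if (length(sc$mig$bump_years)) { # smooth (raised-cosine) migration episode
    by <- range(sc$mig$bump_years)
    u <- (years[-n] - by[1]) / max(by[2] - by[1], 1)
    w <- ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
    amp_t <- amp_t + sc$mig$bump_amp * w
  }
  amp_t[years[-n] %in% sc$mig$shock_years] <- sc$mig$shock_amp
  srb_t <- rep_len(sc$srb, ni)
  stopifnot(all(srb_t >= 0.9), all(srb_t <= 1.3))

  # first pass: migration counts = rate x current population
  G <- array(0, c(96, 2, ni))
  N <- base
  for (t in seq_len(ni)) {
    G[, , t] <- (amp_t[t] * age_prof) * N
    step <- ccmpp_project(N, asfr[, t], srb_t[t], surv[[t]],
                          migration_surface(G[, , t, drop = FALSE],
                                            years[t]),
                          years = years[t:(t + 1)])
    N <- step$pop[, , 2]
  }
  mig <- migration_surface(G, years[-n],
                           hyper = list(sigma_mig = NA, rho_age = NA,
                                        rho_time = NA))
  proj <- ccmpp_project(base, asfr[, -n, drop = FALSE], srb_t, surv, mig,
                        years = years)

  sdi <- seq(sc$sdi_start, sc$sdi_end, length.out = n)
  names(sdi) <- years
  structure(list(pop = proj$pop, flows = proj$flows, asfr = asfr, mx = mx,
                 lifetables = lifetables, surv = surv, mig = mig,
                 srb = srb_t, sdi = sdi, years = years, scenario = sc),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", length(x$years), "years", min(x$years), "-",
      max(x$years), "; final population",
      format(round(sum(x$pop[, , length(x$years)])), big.mark = ","), "\n")
  invisible(x)
}

#' Default census completeness curve for the generator
#'
#' Logistic in the development index, floored at 0.85, times a U-shaped age
#' multiplier (enumeration deficit under age 5 and over 65).
#'
#' @param sdi Development index in `[0, 1]`.
#' @param age Single ages.
#' @return Completeness proportions in `(0, 1.05]`.
#' @export
default_completeness <- function(sdi, age) {
  overall <- 0.85 + 0.15 * stats::plogis(8 * (sdi - 0.4))
  agemult <- 1 - 0.06 * pmax(1 - age / 5, 0) - 0.04 * pmax(age - 65, 0) / 30
  pmin(overall * agemult, 1.05)
}

#' Observation configuration for the synthetic generator
#'
#' @param census_years Years with a census.
#' @param completeness_curve `function(sdi, age)` giving enumeration
#'   completeness; default [default_completeness()].
#' @param heaping_strength Fraction of counts transferred from ages adjacent
#'   to each terminal-digit 0/5 age (in `[0, 1)`); immediate neighbours send
#'   this fraction, second neighbours half of it.
#' @param age_grouping One of `"single"`, `"five"`, `"ten"`.
#' @param old_age_exaggeration Fraction of counts at each age 60+ reported
#'   five years older (age overstatement common in low-registration settings).
#' @param vr_years Years with vital-registration fertility data.
#' @param cbh_surveys Years of complete-birth-history surveys (15-year recall).
#' @param sbh_surveys Years of summary-birth-history surveys.
#' @param sbh_cohorts Age-group starts of 5-year maternal cohorts surveyed.
#' @param vr_bias Named multiplicative bias per source id (applied to VR).
#' @param noise_sd Lognormal sd of observation noise per source type.
#' @param seed Integer seed for observation noise.
#' @return A list of class `obs_config`.
#' @export
obs_config <- function(census_years,
                       completeness_curve = default_completeness,
                       heaping_strength = 0.2,
                       old_age_exaggeration = 0,
                       age_grouping = c("five", "single", "ten"),
                       vr_years = integer(0),
                       cbh_surveys = integer(0),
                       sbh_surveys = integer(0),
                       sbh_cohorts = seq(15, 45, 5),
                       vr_bias = c(vr = 1.0),
                       noise_sd = c(vr = 0.03, cbh = 0.07, sbh = 0.1),
                       seed = 1L) {
  stopifnot(heaping_strength >= 0, heaping_strength < 1,
            old_age_exaggeration >= 0, old_age_exaggeration < 1)
  structure(list(census_years = census_years,
                 completeness_curve = completeness_curve,
                 heaping_strength = heaping_strength,
                 old_age_exaggeration = old_age_exaggeration,
                 age_grouping = match.arg(age_grouping),
                 vr_years = vr_years, cbh_surveys = cbh_surveys,
                 sbh_surveys = sbh_surveys, sbh_cohorts = sbh_cohorts,
                 vr_bias = vr_bias, noise_sd = noise_sd, seed = seed),
            class = "obs_config")
}

# total-preserving heaping operator on single-year counts: each age at
# distance 1 from a multiple of 5 (5..90) sends fraction h, distance 2 sends
# h/2, onto that multiple
.apply_heaping <- function(counts, h) {
  if (h <= 0) return(counts)
  out <- counts
  for (d in seq(5, 90, 5)) {
    for (off in c(-2, -1, 1, 2)) {
      a <- d + off
      if (a < 0 || a > 94) next
      frac <- if (abs(off) == 1) h else h / 2
      moved <- counts[a + 1, ] * frac
      out[a + 1, ] <- out[a + 1, ] - moved
      out[d + 1, ] <- out[d + 1, ] + moved
    }
  }
  out
}

.aggregate_ages <- function(counts, grouping) {
  if (grouping == "single") {
    starts <- 0:95; ends <- c(1:95, -1L)
  } else if (grouping == "five") {
    starts <- seq(0, 95, 5); ends <- c(seq(5, 95, 5), -1L)
  } else {
    starts <- seq(0, 90, 10); ends <- c(seq(10, 90, 10), -1L)
  }
  grp <- findInterval(0:95, starts)
  agg <- rowsum(counts, grp)
  data.frame(age_start = rep(starts, 2), age_end = rep(ends, 2),
             sex = rep(SEXES, each = length(starts)),
             value = c(agg[, 1], agg[, 2]))
}

#' Observe a census from synthetic truth
#'
#' Applies age- and development-dependent enumeration completeness, then a
#' total-preserving terminal-digit (0/5) heaping transfer, then aggregation to
#' the configured age grouping.
#'
#' @param truth A [make_true_country()] result.
#' @param year Census year (must be in the truth's range).
#' @param obs An [obs_config()].
#' @return A `census_observation`: list with `location`, `year`, `counts`
#'   (data.frame sex/age_start/age_end/value, age_end `-1` = open interval),
#'   `age_grouping`, `defacto`, `outlier`, and the true completeness applied.
#' @export
observe_census <- function(truth, year, obs) {
  stopifnot(inherits(truth, "synthetic_truth"), year %in% truth$years)
  i <- match(year, truth$years)
  N <- truth$pop[, , i]
  comp <- obs$completeness_curve(truth$sdi[i], 0:95)
  enum <- N * comp
  if (obs$old_age_exaggeration > 0) { # shift a share of 60+ five years older
    e <- obs$old_age_exaggeration
    shifted <- enum
    for (a in 60:95) {
      moved <- enum[a + 1, ] * e
      shifted[a + 1, ] <- shifted[a + 1, ] - moved
      dest <- min(a + 5, 95)
      shifted[dest + 1, ] <- shifted[dest + 1, ] + moved
    }
    enum <- shifted
  }
  heaped <- .apply_heaping(enum, obs$heaping_strength)
  counts <- .aggregate_ages(heaped, obs$age_grouping)
  structure(list(location = "synthetic", year = year, counts = counts,
                 age_grouping = obs$age_grouping, defacto = TRUE,
                 outlier = FALSE, completeness_true = comp,
                 correction = "none", drop_under5 = FALSE,
                 completeness_applied = NULL, age_multipliers = NULL),
            class = "census_observation")
}

#' @export
print.census_observation <- function(x, ...) {
  cat("Census", x$year, "(", x$age_grouping, "ages ) total",
      format(round(sum(x$counts$value)), big.mark = ","),
      if (x$outlier) "[outlier]" else "", "\n")
  invisible(x)
}

#' True exposure-weighted 5-year-group ASFR from a synthetic truth
#'
#' @param truth A [make_true_country()] result.
#' @param year Year of interest.
#' @return Named vector of 9 group rates (10-14 ... 50-54) per woman-year.
#' @export
true_group_asfr <- function(truth, year) {
  i <- match(year, truth$years)
  stopifnot(!is.na(i))
  w <- truth$pop[11:55, 1, i]
  g <- rep(1:9, each = 5)
  out <- as.numeric(rowsum(truth$asfr[, i] * w, g) /
                      pmax(rowsum(matrix(w), g), 1e-12))
  names(out) <- paste(seq(10, 50, 5), seq(14, 54, 5), sep = "-")
  out
}

# children ever born by exact survey date for a woman aged `a` (completed
# years) at the survey: sum of true single-age rates along the cohort
# diagonal from age 10 through age a-1; years clamped to the truth range
.ceb_single <- function(truth, survey_year, a) {
  if (a <= 10) return(0)
  xs <- 10:(min(a, 55) - 1)
  yrs <- pmin(pmax(survey_year - (a - xs), min(truth$years)),
              max(truth$years))
  sum(truth$asfr[cbind(xs - 9, match(yrs, truth$years))])
}

#' Observe fertility data sources from synthetic truth
#'
#' Emits vital-registration ASFR (with multiplicative source bias and
#' lognormal noise), complete-birth-history retrospective period ASFR (recall
#' noise), and summary-birth-history children-ever-born per 5-year maternal
#' cohort (integral of true fertility along cohort diagonals up to the survey
#' date, plus noise). Each point carries a sampling variance.
#'
#' @param truth A [make_true_country()] result.
#' @param obs An [obs_config()].
#' @return A data.frame of class `fertility_obs` with columns `location`,
#'   `year`, `source_type` (vr/cbh/sbh), `source_id`, `age_start`, `age_end`,
#'   `measure` (asfr/ceb), `value`, `variance`, `reference`.
#' @export
observe_fertility_sources <- function(truth, obs) {
  set.seed(obs$seed)
  rows <- list()
  grp_start <- seq(10, 50, 5)
  noise <- function(v, sd) v * exp(stats::rnorm(length(v), 0, sd))

  for (src in names(obs$vr_bias)) {
    for (y in obs$vr_years) {
      tru <- true_group_asfr(truth, y)
      val <- noise(tru * obs$vr_bias[[src]], obs$noise_sd[["vr"]])
      rows[[length(rows) + 1]] <- data.frame(
        location = "synthetic", year = y, source_type = "vr",
        source_id = src, age_start = grp_start, age_end = grp_start + 5,
        measure = "asfr", value = val,
        variance = (pmax(val, 1e-6) * obs$noise_sd[["vr"]])^2,
        reference = FALSE)
    }
  }
  for (sy in obs$cbh_surveys) {
    yrs <- intersect((sy - 15):(sy - 1), truth$years)
    for (y in yrs) {
      tru <- true_group_asfr(truth, y)[2:8]  # 15-19 .. 45-49
      val <- noise(tru, obs$noise_sd[["cbh"]])
      rows[[length(rows) + 1]] <- data.frame(
        location = "synthetic", year = y, source_type = "cbh",
        source_id = paste0("cbh_", sy), age_start = seq(15, 45, 5),
        age_end = seq(20, 50, 5), measure = "asfr", value = val,
        variance = (pmax(val, 1e-6) * obs$noise_sd[["cbh"]])^2,
        reference = FALSE)
    }
  }
  for (sy in obs$sbh_surveys) {
    for (A in obs$sbh_cohorts) {
      ceb <- mean(vapply(A:(A + 4), function(a) .ceb_single(truth, sy, a),
                         numeric(1)))
      val <- if (ceb > 0) noise(ceb, obs$noise_sd[["sbh"]]) else 0
      rows[[length(rows) + 1]] <- data.frame(
        location = "synthetic", year = sy, source_type = "sbh",
        source_id = paste0("sbh_", sy), age_start = A, age_end = A + 5,
        measure = "ceb", value = val,
        variance = (pmax(val, 1e-4) * obs$noise_sd[["sbh"]])^2,
        reference = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no fertility sources configured")
  # reference cascade: VR if present, else first CBH, else SBH mean
  ref_src <- if (any(out$source_type == "vr")) {
    out$source_id[out$source_type == "vr"][1]
  } else if (any(out$source_type == "cbh")) {
    out$source_id[out$source_type == "cbh"][1]
  } else out$source_id[1]
  out$reference <- out$source_id == ref_src
  rownames(out) <- NULL
  class(out) <- c("fertility_obs", "data.frame")
  out
}

#' Generate a synthetic library of paired complete and abridged life tables
#'
#' Complete tables come from varied Siler mortality parameters; abridged
#' tables are derived from them exactly (grouped survivorship), so each pair
#' is internally consistent.
#'
#' @param n Number of pairs (>= 2).
#' @param seed Integer seed.
#' @return List of `list(complete =, abridged =)` pairs.
#' @export
make_lifetable_library <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mx <- siler_mx(a1 = 0.08 * exp(stats::rnorm(1, 0, 0.4)),
                   b1 = 1.1 * exp(stats::rnorm(1, 0, 0.15)),
                   c0 = 5e-4 * exp(stats::rnorm(1, 0, 0.5)),
                   a2 = 3e-5 * exp(stats::rnorm(1, 0, 0.3)),
                   b2 = 0.095 * exp(stats::rnorm(1, 0, 0.03)))
    cmp <- .lt_from_mx(mx)
    list(complete = cmp, abridged = abridge_lifetable(cmp))
  })
}
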