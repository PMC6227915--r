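# Census preparation: completeness modelling from post-enumeration surveys,
# count adjustment, age-sex accuracy scoring, and age-heaping corrections.

#' Fit a census completeness model from post-enumeration surveys
#'
#' Regresses completeness on the Socio-demographic Index on a scaled-logit
#' scale (ceiling 1.05, so mild overcounts are representable) and stores the
#' coefficient variance-covariance matrix for uncertainty propagation. An
#' optional age pattern of enumeration is estimated by a penalized
#' cubic-spline meta-regression of age-specific completeness ratios with
#' inverse-variance weights, normalised to mean 1.
#'
#' @param pes data.frame of PES records with columns `completeness` (net
#'   coverage proportion, in (0.5, 1.05)) and `sdi`.
#' @param age_pattern Optional data.frame with columns `age`, `ratio`
#'   (age-specific completeness / overall completeness) and `variance`.
#' @return Object of class `completeness_model`: list with `coef`, `vcov`,
#'   `sigma` (residual sd on the link scale), `age_mult` (length-96 positive
#'   multipliers, mean 1), `ceiling`.
#' @export
fit_completeness_model <- function(pes, age_pattern = NULL) {
  stopifnot(is.data.frame(pes), all(c("completeness", "sdi") %in% names(pes)))
  if (nrow(pes) < 3) stop("need at least 3 PES records")
  if (length(unique(pes$sdi)) < 2) stop("all PES records have identical SDI")
  stopifnot(all(pes$completeness > 0.5), all(pes$completeness < 1.05))
  ceiling_c <- 1.05
  eta <- stats::qlogis(pes$completeness / ceiling_c)
  fit <- stats::lm(eta ~ sdi, data = data.frame(eta = eta, sdi = pes$sdi))
  age_mult <- rep(1, 96)
  if (!is.null(age_pattern) && nrow(age_pattern) >= 4 &&
      stats::var(age_pattern$ratio) > 0) {
    w <- if ("variance" %in% names(age_pattern))
      1 / pmax(age_pattern$variance, 1e-10) else rep(1, nrow(age_pattern))
    k <- min(8, max(4, floor(nrow(age_pattern) / 3)))
    gfit <- mgcv::gam(ratio ~ s(age, k = k), weights = w, data = age_pattern)
    age_mult <- as.numeric(stats::predict(gfit,
                                          newdata = data.frame(age = 0:95)))
    age_mult <- pmax(age_mult, 0.5)
    age_mult <- age_mult / mean(age_mult)
  }
  structure(list(coef = stats::coef(fit), vcov = stats::vcov(fit),
                 sigma = stats::sigma(fit), age_mult = age_mult,
                 ceiling = ceiling_c),
            class = "completeness_model")
}

#' @export
print.completeness_model <- function(x, ...) {
  cat("Census completeness model: logit(c/", x$ceiling, ") = ",
      signif(x$coef[1], 3), " + ", signif(x$coef[2], 3), " * SDI\n", sep = "")
  invisible(x)
}

#' Predict overall census completeness at a given SDI
#'
#' @param model A [fit_completeness_model()] result.
#' @param sdi Development index values.
#' @return Completeness proportions, capped at 1.02.
#' @export
predict_completeness <- function(model, sdi) {
  eta <- model$coef[1] + model$coef[2] * sdi
  pmin(model$ceiling * stats::plogis(eta), 1.02)
}

# mean age multiplier of a completeness model over an age interval
.group_multiplier <- function(model, age_start, age_end) {
  a1 <- ifelse(age_end == -1L, 95L, pmin(age_end - 1L, 95L))
  vapply(seq_along(age_start), function(i) {
    mean(model$age_mult[(age_start[i]:a1[i]) + 1])
  }, numeric(1))
}

#' Adjust census counts for enumeration completeness
#'
#' Divides raw counts by overall completeness times the age-specific
#' enumeration multiplier. High-SDI censuses with their own PES use the
#' nationally reported completeness; all others use the model prediction at
#' the census-year SDI. For low and middle SDI groups the under-5 counts are
#' flagged to be ignored by the balancing likelihood.
#'
#' @param census A `census_observation` (see [observe_census()] for the
#'   structure).
#' @param model A [fit_completeness_model()] result.
#' @param sdi SDI at the census year.
#' @param sdi_group One of `"low"`, `"middle"`, `"high-middle"`, `"high"`.
#' @param own_pes Optional list/row with element `completeness` from the
#'   census's own post-enumeration survey.
#' @return The census object with `counts$adjusted` added, `completeness_applied`,
#'   `age_multipliers`, and `drop_under5` set.
#' @export
adjust_census <- function(census, model, sdi,
                          sdi_group = c("low", "middle", "high-middle",
                                        "high"),
                          own_pes = NULL) {
  stopifnot(inherits(census, "census_observation"))
  sdi_group <- match.arg(sdi_group)
  if (isTRUE(census$outlier))
    stop("census ", census$year, " is flagged as an outlier; not adjusted")
  comp <- if (sdi_group == "high" && !is.null(own_pes))
    own_pes$completeness else predict_completeness(model, sdi)
  mult <- .group_multiplier(model, census$counts$age_start,
                            census$counts$age_end)
  census$counts$adjusted <- census$counts$value / (comp * mult)
  census$completeness_applied <- comp
  census$age_multipliers <- mult
  census$drop_under5 <- sdi_group %in% c("low", "middle")
  census
}

#' Age-sex accuracy joint score of a census
#'
#' Age ratios `AR(g) = 100 * 2 P(g) / (P(g-1) + P(g+1))` per sex, sex ratios
#' `SR(g) = 100 * M(g)/F(g)`; the age-ratio score is the mean absolute
#' deviation of AR from 100, the sex-ratio score the mean absolute change in
#' SR between adjacent groups, and the joint score (the UN age-sex accuracy
#' index) is `3 * sex-ratio score + male + female age-ratio scores`.
#'
#' @param census A `census_observation` with 5-year groups and both sexes.
#' @return List with `age_ratio_score` (per sex), `sex_ratio_score`, `joint`.
#' @export
age_sex_joint_score <- function(census) {
  cc <- census$counts
  closed <- cc[cc$age_end != -1L & (cc$age_end - cc$age_start) == 5, ]
  f <- closed$value[closed$sex == "female"][order(closed$age_start[closed$sex == "female"])]
  m <- closed$value[closed$sex == "male"][order(closed$age_start[closed$sex == "male"])]
  ng <- length(f)
  if (ng < 5 || length(m) != ng)
    stop("joint score requires >= 5 five-year groups for both sexes")
  ar <- function(p) {
    i <- 2:(ng - 1)
    den <- p[i - 1] + p[i + 1]
    if (any(den <= 0)) stop("zero denominator in age ratio")
    100 * 2 * p[i] / den
  }
  if (any(f <= 0)) stop("zero denominator in sex ratio")
  sr <- 100 * m / f
  ars_f <- mean(abs(ar(f) - 100))
  ars_m <- mean(abs(ar(m) - 100))
  srs <- mean(abs(diff(sr)))
  list(age_ratio_score = c(female = ars_f, male = ars_m),
       sex_ratio_score = srs, joint = 3 * srs + ars_m + ars_f)
}

#' Whipple index of terminal-digit age preference
#'
#' `100 * 5 * sum(counts at ages 25, 30, ..., 60) / sum(counts at 23..62)`;
#' 100 indicates no preference for ages ending in 0 or 5.
#'
#' @param counts Single-year counts; a numeric vector named by age, or a
#'   census counts data.frame (summed over sexes).
#' @return The index (typically in `[100, 500]`).
#' @export
whipple_index <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(counts$age_end - counts$age_start == 1 |
                    counts$age_end == -1L))
    v <- tapply(counts$value, counts$age_start, sum)
    counts <- stats::setNames(as.numeric(v), names(v))
  }
  ages <- as.integer(names(counts))
  num <- sum(counts[ages %in% seq(25, 60, 5)])
  den <- sum(counts[ages >= 23 & ages <= 62])
  if (den <= 0) stop("no counts at ages 23-62")
  100 * 5 * num / den
}

# cubic (4-point Lagrange) estimate at a multiple of 5 from its non-heaped
# neighbours at distances -2, -1, +1, +2
.lagrange_w <- c(-1, 4, 4, -1) / 6

.feeney_single <- function(v) {
  heaps <- seq(5, 90, 5)
  total <- sum(v)
  for (iter in 1:500) {
    maxrel <- 0
    for (d in heaps) {
      nb <- d + c(-2, -1, 1, 2)
      expected <- sum(.lagrange_w * v[nb + 1])
      excess <- v[d + 1] - expected
      move <- 0.5 * excess
      move <- max(min(move, v[d + 1]), -3 * min(v[nb + 1]))  # keep nonneg
      v[d + 1] <- v[d + 1] - move
      v[nb + 1] <- v[nb + 1] + move * c(1, 2, 2, 1) / 6
      maxrel <- max(maxrel, abs(excess) / max(total, 1e-12))
    }
    if (maxrel < 1e-8) break
  }
  v
}

.arriaga_split <- function(T10, strong = FALSE) {
  J <- length(T10)
  if (strong && J >= 3) {
    sm <- T10
    sm[2:(J - 1)] <- (T10[1:(J - 2)] + 2 * T10[2:(J - 1)] + T10[3:J]) / 4
    T10 <- sm * sum(T10) / sum(sm)
  }
  first <- numeric(J)
  for (j in seq_len(J)) {
    if (j == 1) {
      first[j] <- (15 * T10[1] - 3 * T10[2]) / 24
    } else if (j == J) {
      second <- (15 * T10[J] - 3 * T10[J - 1]) / 24
      first[j] <- T10[j] - second
    } else {
      first[j] <- (2 * T10[j - 1] + 11 * T10[j] - T10[j + 1]) / 24
    }
  }
  out <- as.numeric(rbind(first, T10 - first))
  if (any(out < 0)) { # floor and redistribute within the block
    for (j in seq_len(J)) {
      pair <- out[c(2 * j - 1, 2 * j)]
      if (any(pair < 0)) {
        pair <- pmax(pair, 0)
        out[c(2 * j - 1, 2 * j)] <- if (sum(pair) > 0)
          pair * T10[j] / sum(pair) else rep(T10[j] / 2, 2)
      }
    }
  }
  out
}

#' Correct age heaping in census counts
#'
#' `feeney`: iterative redistribution on single-year counts removing the
#' excess at terminal-digit 0/5 ages measured against a 4-point interpolation
#' of non-heaped neighbours; totals are preserved exactly and smooth inputs
#' are (near-)fixed points. `arriaga`: 5-year groups re-derived from 10-year
#' totals by the standard interpolation weights; 10-year totals preserved.
#' `arriaga_strong`: the 10-year totals themselves are first smoothed by a
#' centred moving average (overall total preserved), then split.
#'
#' @param counts A census counts data.frame (`sex`, `age_start`, `age_end`,
#'   `value`) in single-year (feeney) or 5-/10-year (arriaga) groups.
#' @param method One of `"feeney"`, `"arriaga"`, `"arriaga_strong"`.
#' @return The counts data.frame with `value` replaced by corrected counts.
#' @export
correct_heaping <- function(counts, method = c("feeney", "arriaga",
                                               "arriaga_strong")) {
  method <- match.arg(method)
  if (inherits(counts, "census_observation")) counts <- counts$counts
  pieces <- lapply(unique(counts$sex), function(sx) {
    cs <- counts[counts$sex == sx, ]
    cs <- cs[order(cs$age_start), ]
    w <- ifelse(cs$age_end == -1L, NA, cs$age_end - cs$age_start)
    closed <- which(!is.na(w))
    if (method == "feeney") {
      if (!all(w[closed] == 1)) stop("feeney requires single-year age groups")
      cs$value[closed] <- .feeney_single(cs$value[closed])
      return(cs)
    }
    if (!all(w[closed] %in% c(5, 10)))
      stop("arriaga requires 5- or 10-year age groups")
    span <- max(cs$age_end[closed]) - min(cs$age_start[closed])
    if (span < 30) stop("arriaga requires >= 30 years of age span")
    strong <- method == "arriaga_strong"
    if (all(w[closed] == 10)) {
      # split each 10-year group into 5-year halves
      T10 <- cs$value[closed]
      split5 <- .arriaga_split(T10, strong = strong)
      st <- cs$age_start[closed]
      halves <- data.frame(age_start = as.integer(rbind(st, st + 5L)),
                           age_end = as.integer(rbind(st + 5L, st + 10L)),
                           sex = sx, value = split5)
      open <- cs[is.na(w), c("age_start", "age_end", "sex", "value")]
      return(rbind(halves, open))
    }
    # 5-year groups: re-derive aligned pairs from their 10-year totals
    starts <- cs$age_start[closed]
    pairs <- starts[starts %% 10 == 0 & (starts + 5) %in% starts]
    T10 <- vapply(pairs, function(s)
      sum(cs$value[closed][starts %in% c(s, s + 5)]), numeric(1))
    split5 <- .arriaga_split(T10, strong = strong)
    for (k in seq_along(pairs)) {
      cs$value[closed][starts == pairs[k]] <- split5[2 * k - 1]
      cs$value[closed][starts == pairs[k] + 5] <- split5[2 * k]
    }
    cs
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Choose the heaping correction for a census
#'
#' Single-year censuses with Whipple index above 105 get the Feeney
#' correction. Grouped censuses are scored with the age-sex accuracy index:
#' joint score below 20 needs no correction, 20-40 the Arriaga split, 40 and
#' above the strong (pre-smoothed) Arriaga variant.
#'
#' @param census A `census_observation`.
#' @return One of `"none"`, `"feeney"`, `"arriaga"`, `"arriaga_strong"`.
#' @export
choose_heaping_correction <- function(census) {
  if (census$age_grouping == "single") {
    if (whipple_index(census$counts) > 105) "feeney" else "none"
  } else {
    js <- age_sex_joint_score(census)$joint
    if (js < 20) "none" else if (js < 40) "arriaga" else "arriaga_strong"
  }
}
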