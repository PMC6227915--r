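# Life-table containers and graduation from abridged to single-year ages.
#
# Abridged tables use the standard grouping <1, 1-4, then 5-year groups to the
# open interval 110+. Complete tables run over single ages 0..110 with the
# convention 1ax = 0.5 at ages 1..109; ages <1 and 110+ keep the abridged ax.

ABRIDGED_AGE_START <- c(0L, 1L, seq(5L, 110L, 5L))

#' Abridged period life table
#'
#' Builds an abridged life table on the standard age grouping (<1, 1-4, then
#' 5-year groups up to the open interval 110+) from group death probabilities.
#'
#' @param qx Numeric vector of length 24: probability of dying within each age
#'   group for someone alive at its start. The terminal (110+) value is forced
#'   to 1.
#' @param ax Optional person-years lived in the interval by those dying in it;
#'   defaults to 0.2 for age <1, half the interval width elsewhere, and 2 for
#'   the open interval.
#' @param shock_mx Optional nonnegative fatal-discontinuity death rate per
#'   group, carried for [add_shock_rates()].
#' @return A data.frame of class `abridged_lifetable` with columns `age_start`,
#'   `age_end` (exclusive; `-1` codes the open interval), `qx`, `lx`, `ax`,
#'   `mx` and optionally `shock_mx`. `lx` starts at 1.
#' @export
abridged_lifetable <- function(qx, ax = NULL, shock_mx = NULL) {
  n <- length(ABRIDGED_AGE_START)
  stopifnot(length(qx) == n, all(is.finite(qx)), all(qx >= 0), all(qx <= 1))
  qx[n] <- 1
  width <- c(diff(ABRIDGED_AGE_START), Inf)
  if (is.null(ax)) {
    ax <- width / 2
    ax[1] <- 0.2
    ax[n] <- 2
  }
  stopifnot(length(ax) == n, all(ax > 0))
  lx <- cumprod(c(1, 1 - qx[-n]))
  if (any(diff(lx) > 0)) stop("lx must be nonincreasing")
  # group death rate nmx from qx and ax: q = n*m / (1 + (n - ax) m)
  mx <- ifelse(qx >= 1, 1 / ax,
               qx / (width - (width - ax) * qx))
  out <- data.frame(age_start = ABRIDGED_AGE_START,
                    age_end = c(ABRIDGED_AGE_START[-1], -1L),
                    qx = qx, lx = lx, ax = ax, mx = mx)
  if (!is.null(shock_mx)) {
    stopifnot(length(shock_mx) == n, all(shock_mx >= 0))
    out$shock_mx <- shock_mx
  }
  class(out) <- c("abridged_lifetable", "data.frame")
  out
}

#' Complete (single-year) period life table
#'
#' @param qx Death probabilities at single ages 0..110 (length 111).
#' @param a0 Person-years lived by infant decedents (default 0.2).
#' @param a110 Expected years lived in the open 110+ interval (default 2).
#' @return A data.frame of class `complete_lifetable` with columns `age`
#'   (0..110), `qx`, `lx`, `ax`, `Lx`. `ax` is 0.5 at ages 1..109. The terminal
#'   `Lx` is `l110 * a110` (infinite when terminal mortality is zero).
#' @export
complete_lifetable <- function(qx, a0 = 0.2, a110 = 2) {
  stopifnot(length(qx) == 111, all(is.finite(qx)), all(qx >= 0), all(qx <= 1))
  ax <- rep(0.5, 111)
  ax[1] <- a0
  ax[111] <- a110
  lx <- cumprod(c(1, 1 - qx[-111]))
  Lx <- lx * (1 - qx * (1 - ax))
  # terminal open interval: L = l/m with m = 1/a110 when q = 1; infinite
  # person-years in the degenerate zero-mortality case
  Lx[111] <- if (lx[111] <= 0) 0 else if (qx[111] <= 0) Inf else lx[111] * a110
  out <- data.frame(age = 0:110, qx = qx, lx = lx, ax = ax, Lx = Lx)
  class(out) <- c("complete_lifetable", "data.frame")
  out
}

#' @export
print.abridged_lifetable <- function(x, ...) {
  cat("Abridged life table:", nrow(x), "age groups, l(110+) =",
      signif(x$lx[nrow(x)], 3), "\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
print.complete_lifetable <- function(x, ...) {
  e0 <- sum(x$Lx[is.finite(x$Lx)])
  cat("Complete life table: ages 0-110, e0 ~", signif(e0, 4), "\n")
  invisible(x)
}

#' Collapse a complete life table to the abridged grouping
#'
#' Group probabilities satisfy `1 - 5qx = prod(1 - 1qx)` over member ages
#' exactly, so a pair produced this way is internally consistent.
#'
#' @param complete A [complete_lifetable()].
#' @return An [abridged_lifetable()].
#' @export
abridge_lifetable <- function(complete) {
  stopifnot(inherits(complete, "complete_lifetable"))
  grp <- findInterval(complete$age, ABRIDGED_AGE_START)
  qx <- vapply(seq_along(ABRIDGED_AGE_START), function(g) {
    1 - prod(1 - complete$qx[grp == g])
  }, numeric(1))
  n <- length(ABRIDGED_AGE_START)
  ax <- c(diff(ABRIDGED_AGE_START), Inf) / 2
  ax[1] <- complete$ax[1]
  ax[n] <- complete$ax[111]
  abridged_lifetable(qx, ax = ax)
}

# conversions between death rates and probabilities at ax = a within a
# unit interval: q = m / (1 + (1 - a) m)
mx_to_qx <- function(m, a = 0.5) m / (1 + (1 - a) * m)
qx_to_mx <- function(q, a = 0.5) q / (1 - (1 - a) * q)

# parent abridged group index for each single age
.parent_group <- function(age) findInterval(age, ABRIDGED_AGE_START)

#' Fit the single-year vs abridged qx regression
#'
#' For each single age x in 0..14 and 100..109, fits by ordinary least squares
#' `log(1qx) = b0 + b1 * log(5qx)` across a library of paired complete and
#' abridged life tables, where `5qx` is the death probability of the abridged
#' group containing x. Age 110 is excluded: its probability is 1 by convention.
#'
#' @param library A list of pairs, each `list(complete =, abridged =)`.
#' @return An object of class `qx_regression`: data.frame with columns `age`,
#'   `b0`, `b1`, `sd` (residual standard deviation).
#' @export
fit_qx_regression <- function(library) {
  stopifnot(length(library) >= 2)
  ages <- c(0:14, 100:109)
  rows <- lapply(ages, function(x) {
    g <- .parent_group(x)
    yy <- vapply(library, function(p) p$complete$qx[p$complete$age == x],
                 numeric(1))
    xx <- vapply(library, function(p) p$abridged$qx[g], numeric(1))
    keep <- yy > 0 & xx > 0
    if (sum(keep) < 2)
      stop("fewer than 2 library pairs with positive qx at age ", x)
    lx <- log(xx[keep]); ly <- log(yy[keep])
    if (stats::var(lx) < 1e-20)
      stop("degenerate regressor (zero variance in abridged qx) at age ", x)
    fit <- stats::lm.fit(cbind(1, lx), ly)
    rss <- sum(fit$residuals^2)
    n <- sum(keep)
    data.frame(age = x, b0 = fit$coefficients[1], b1 = fit$coefficients[2],
               sd = if (n > 2) sqrt(rss / (n - 2)) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qx_regression", "data.frame")
  out
}

# solve for k such that prod(1 - k * qhat) = 1 - Q, exactly (Newton-refined)
.scale_group_qx <- function(qhat, Q) {
  if (Q >= 1) return(rep(1, length(qhat)))
  if (Q <= 0) return(rep(0, length(qhat)))
  if (all(qhat <= 0)) stop("cannot scale zero predicted qx to positive 5qx")
  target <- log1p(-Q)
  f <- function(k) sum(log1p(-k * qhat)) - target
  upper <- (1 - 1e-12) / max(qhat)
  if (f(upper) > 0) return(pmin(qhat * upper, 1))
  k <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  for (i in 1:8) { # polish to machine precision
    fk <- f(k)
    if (abs(fk) < 1e-15) break
    k <- k - fk / (-sum(qhat / (1 - k * qhat)))
    k <- min(max(k, 0), upper)
  }
  qs <- k * qhat
  if (any(qs < 0 | qs > 1)) stop("scaled qx outside [0, 1]")
  qs
}

# graduate single-year qx for ages 15..99 from abridged lx by interpolating
# log 5-year cumulative-hazard increments with a shape-preserving monotone
# cubic Hermite interpolant (pchip), then rescaling within each group so the
# group survival ratio is exact; knots from age 5 anchor the childhood decline
.graduate_hazard <- function(abridged) {
  ks <- seq(5L, 110L, 5L)
  lx <- abridged$lx[match(ks, abridged$age_start)]
  valid <- lx >= 1e-10
  H <- -log(pmax(lx, 1e-300))
  D <- diff(H)
  mids <- ks[-length(ks)] + 2.5
  segok <- valid[-length(valid)] & valid[-1] & D > 0
  ages <- 15:99
  seg <- findInterval(ages, ks)
  if (sum(segok) == 0) return(rep(0, length(ages)))
  xs <- mids[segok]; zs <- log(D[segok] / 5)
  zfun <- function(xo) {
    out <- numeric(length(xo))
    lo <- min(xs); hi <- max(xs)
    inr <- xo >= lo & xo <= hi
    out[inr] <- if (length(xs) >= 2)
      pracma::pchip(xs, zs, xo[inr]) else zs[1]
    if (length(xs) >= 2) {
      nn <- length(xs)
      out[xo > hi] <- zs[nn] +
        (zs[nn] - zs[nn - 1]) / (xs[nn] - xs[nn - 1]) * (xo[xo > hi] - hi)
      out[xo < lo] <- zs[1] +
        (zs[2] - zs[1]) / (xs[2] - xs[1]) * (xo[xo < lo] - lo)
    } else {
      out[!inr] <- zs[1]
    }
    out
  }
  d <- exp(zfun(ages + 0.5))
  q <- pmin(1 - exp(-d), 1)
  for (j in unique(seg)) {
    sel <- seg == j
    if (valid[j] && valid[j + 1])

      q[sel] <- if (D[j] <= 0) 0 else
        .scale_group_qx(pmax(q[sel], 1e-300), 1 - exp(-D[j]))
  }
  q
}

# the lx-spline graduation (Hyman-filtered monotone cubic on abridged lx)
.graduate_hyman_lx <- function(abridged) {
  knot_age <- ABRIDGED_AGE_START
  lx_knots <- abridged$lx
  pos <- lx_knots > 0
  if (sum(pos) < 3) return(rep(1, 85))
  sp <- stats::splinefun(knot_age[pos], lx_knots[pos], method = "hyman")
  top <- max(knot_age[pos])
  l_single <- ifelse(15:100 <= top, pmax(sp(pmin(15:100, top)), 0), 0)
  q <- ifelse(l_single[-86] > 0, 1 - l_single[-1] / l_single[-86], 1)
  pmin(pmax(q, 0), 1)
}

#' Expand an abridged life table to single-year ages
#'
#' Ages 15-99 are graduated from the abridged survivorship: the default
#' method interpolates the log of the 5-year cumulative-hazard increments
#' with a shape-preserving monotone cubic Hermite interpolant and rescales
#' within each group, so the group-consistency identity
#' `prod(1 - 1qx) = 1 - 5qx` is exact; `"hyman-lx"` instead interpolates
#' abridged `lx` at group boundaries with a Hyman-filtered monotone cubic
#' spline (consistent at the boundaries by construction but less accurate
#' where decrements are small). Ages 0-14 and 100-110 take predicted
#' single-year probabilities from the library regression, rescaled within
#' each abridged group so the same identity holds exactly.
#'
#' @param abridged An [abridged_lifetable()].
#' @param coeffs A [fit_qx_regression()] result.
#' @param method Graduation for ages 15-99: `"hazard"` (default) or
#'   `"hyman-lx"`.
#' @return A [complete_lifetable()].
#' @export
expand_lifetable <- function(abridged, coeffs,
                             method = c("hazard", "hyman-lx")) {
  stopifnot(inherits(abridged, "abridged_lifetable"),
            inherits(coeffs, "qx_regression"))
  method <- match.arg(method)
  if (any(diff(abridged$lx) > 1e-15)) stop("abridged lx must be nonincreasing")
  qx_out <- numeric(111)

  # regression ages, rescaled per group
  for (g in which(ABRIDGED_AGE_START %in% c(0, 1, 5, 10, 100, 105, 110))) {
    a0 <- abridged$age_start[g]
    a1 <- if (abridged$age_end[g] == -1L) 110L else abridged$age_end[g] - 1L
    ages <- a0:a1
    Q <- abridged$qx[g]
    if (a0 == 110L) { qx_out[111] <- 1; next }
    qhat <- vapply(ages, function(x) {
      cf <- coeffs[coeffs$age == x, ]
      if (nrow(cf) != 1) stop("no regression coefficients for age ", x)
      if (Q <= 0) 0 else exp(cf$b0 + cf$b1 * log(Q))
    }, numeric(1))
    qx_out[ages + 1] <- .scale_group_qx(qhat, Q)
  }

  qx_out[16:100] <- if (method == "hazard") .graduate_hazard(abridged)
                    else .graduate_hyman_lx(abridged)

  n <- nrow(abridged)
  complete_lifetable(qx_out, a0 = abridged$ax[1], a110 = abridged$ax[n])
}

#' Add fatal-discontinuity death rates to a complete life table
#'
#' Converts single-year probabilities to rates (with ax = 0.5), adds the
#' group-constant shock rate to every member age, and converts back. A shock
#' of zero leaves the table unchanged. Probabilities that would exceed 1 are
#' capped with a warning.
#'
#' @param complete A [complete_lifetable()].
#' @param shock_mx Nonnegative rate per abridged group (length 24).
#' @return A [complete_lifetable()].
#' @export
add_shock_rates <- function(complete, shock_mx) {
  stopifnot(inherits(complete, "complete_lifetable"),
            length(shock_mx) == length(ABRIDGED_AGE_START),
            all(shock_mx >= 0))
  if (all(shock_mx == 0)) return(complete)
  g <- .parent_group(complete$age)
  m <- qx_to_mx(pmin(complete$qx, 1 - 1e-12), a = 0.5) + shock_mx[g]
  q_new <- mx_to_qx(m, a = 0.5)
  # restore exact terminal probability; it is 1 whenever it was 1
  q_new[111] <- if (complete$qx[111] >= 1) 1 else q_new[111]
  if (any(q_new > 1)) {
    warning(sum(q_new > 1), " shocked qx value(s) capped at 1")
    q_new <- pmin(q_new, 1)
  }
  complete_lifetable(q_new, a0 = complete$ax[1], a110 = complete$ax[111])
}

#' Projection survivorship ratios from a complete life table
#'
#' Returns the person-year ratios used by the cohort-component projection with
#' an open interval at 95+: `S(a) = L(a+1)/L(a)` for single ages (the ratio
#' into the open interval uses L95/L94), newborn survivorship `L0/l0`, and the
#' open-interval ratio `T(96)/T(95)` where `T(a)` sums `Lx` from age a up.
#'
#' @param complete A [complete_lifetable()].
#' @return A list with `newborn` (scalar), `s` (length 95, ages 0..94), and
#'   `open` (scalar); all in (0, 1].
#' @export
survivorship_ratios <- function(complete) {
  stopifnot(inherits(complete, "complete_lifetable"))
  L <- complete$Lx
  if (any(L[1:96] <= 0)) stop("zero Lx below the open interval")
  s <- L[2:96] / L[1:95]                    # ages 0..94 -> 1..95
  T95 <- sum(L[96:111])
  T96 <- sum(L[97:111])
  open <- if (!is.finite(T95)) 1 else if (T95 <= 0)
    stop("zero person-years in the open interval") else T96 / T95
  list(newborn = L[1] / complete$lx[1], s = pmin(s, 1), open = min(open, 1))
}
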