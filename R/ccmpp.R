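# Cohort-component projection on single-year ages 0..94 plus the open 95+
# interval, two sexes, mid-year time points. The projection records vital
# flows so the demographic balancing identity
#   N(t+1) = N(t) + B - D + G
# holds exactly (to floating point) every year.

PROJ_AGES <- 0:95   # 95 codes the open interval 95+
SEXES <- c("female", "male")

#' Population grid container
#'
#' @param counts Array of person counts with dim `c(96, 2, n_years)` (single
#'   ages 0..94 plus open 95+, sexes female/male, mid-year time points), or a
#'   96 x 2 matrix for a single year.
#' @param years Integer vector of mid-year labels.
#' @return An array of class `population_grid` with dimnames age/sex/year.
#' @export
population_grid <- function(counts, years) {
  if (is.matrix(counts)) counts <- array(counts, c(96, 2, 1))
  stopifnot(length(dim(counts)) == 3, dim(counts)[1] == 96, dim(counts)[2] == 2,
            dim(counts)[3] == length(years), all(counts >= 0))
  dimnames(counts) <- list(age = PROJ_AGES, sex = SEXES, year = years)
  class(counts) <- c("population_grid", "array")
  counts
}

#' @export
print.population_grid <- function(x, ...) {
  yrs <- as.integer(dimnames(x)$year)
  cat("Population grid: ages 0-95+, 2 sexes,", length(yrs), "years (",
      min(yrs), "-", max(yrs), "), total in last year:",
      format(round(sum(x[, , length(yrs)])), big.mark = ","), "\n")
  invisible(x)
}

grid_years <- function(grid) as.integer(dimnames(grid)$year)

#' Total population per year
#' @param grid A [population_grid()].
#' @return Named numeric vector of totals by year.
#' @export
pop_total <- function(grid) apply(unclass(grid), 3, sum)

#' Net-migration surface container
#'
#' @param counts Array `c(96, 2, n_intervals)` of net migrants per interval
#'   (counts, sign unrestricted).
#' @param years Interval start years.
#' @param hyper Optional list of prior hyperparameters (`sigma_mig`,
#'   `rho_age`, `rho_time`) recorded for provenance.
#' @return Array of class `migration_surface`.
#' @export
migration_surface <- function(counts, years, hyper = NULL) {
  if (is.matrix(counts)) counts <- array(counts, c(96, 2, 1))
  stopifnot(length(dim(counts)) == 3, dim(counts)[1] == 96, dim(counts)[2] == 2,
            dim(counts)[3] == length(years), all(is.finite(counts)))
  dimnames(counts) <- list(age = PROJ_AGES, sex = SEXES, year = years)
  attr(counts, "hyper") <- hyper
  class(counts) <- c("migration_surface", "array")
  counts
}

#' Expand 5-year-group ASFR to single ages (constant within group)
#'
#' @param asfr5 Vector of 9 group rates (10-14 ... 50-54, per woman-year) or a
#'   9 x n matrix over time.
#' @return Matrix 45 x n with rownames ages 10..54.
#' @export
expand_asfr_groups <- function(asfr5) {
  if (is.null(dim(asfr5))) asfr5 <- matrix(asfr5, ncol = 1)
  stopifnot(nrow(asfr5) == 9, all(asfr5 >= 0))
  out <- asfr5[rep(1:9, each = 5), , drop = FALSE]
  rownames(out) <- 10:54
  out
}

# normalize survivorship input to a list of n elements, each a
# list(female =, male =) of survivorship_ratios() results; a single ratios
# object (or a single female/male pair) is recycled over intervals and sexes
.per_interval_surv <- function(x, n) {
  as_pair <- function(e) {
    if (!is.null(e$s)) list(female = e, male = e)
    else { stopifnot(!is.null(e$female$s), !is.null(e$male$s)); e }
  }
  if (!is.null(x$s) || !is.null(x$female)) x <- list(x)
  x <- lapply(x, as_pair)
  if (length(x) == 1) x <- rep(x, n)
  stopifnot(length(x) == n)
  x
}

#' Cohort-component population projection
#'
#' Projects a baseline population forward one year at a time: half the net
#' migrants are added at the start of each interval, cohorts are survived one
#' age step (the open 95+ interval absorbs), the remaining half of migrants
#' are added at the end. Births are age-specific fertility applied to the
#' mean of start- and end-of-interval female population, split by the sex
#' ratio at birth and survived with newborn survivorship.
#'
#' @param baseline A [population_grid()] (first year is used) or 96 x 2 matrix.
#' @param asfr Single-age fertility per woman-year: a 45 x n_intervals matrix
#'   (ages 10..54), a length-45 vector recycled over time, or `NULL` for zero
#'   fertility (then `births` may supply counts directly).
#' @param srb Sex ratio at birth (males per female), scalar or per interval.
#' @param surv [survivorship_ratios()] output, one list recycled or a list of
#'   one per interval.
#' @param mig A [migration_surface()] of net migrant counts (or `NULL`).
#' @param years Vector of mid-year time points to produce (length >= 2).
#' @param births Optional 2 x n_intervals matrix (female, male rows) of
#'   pre-survival birth counts overriding the fertility-based computation;
#'   used e.g. to reverse a back-projection exactly.
#' @return A list: `pop` ([population_grid()]), `flows` (list with `births`
#'   2 x n, `deaths` and `migrants` 96 x 2 x n arrays), `clipped` (count of
#'   negative populations clipped to zero; the clipped mass is added to
#'   deaths so the balancing identity still holds).
#' @export
ccmpp_project <- function(baseline, asfr, srb, surv, mig = NULL, years,
                          births = NULL) {
  stopifnot(length(years) >= 2)
  n <- length(years) - 1
  if (inherits(baseline, "population_grid")) baseline <- baseline[, , 1]
  baseline <- matrix(baseline, 96, 2)
  if (any(baseline < 0)) stop("negative baseline counts")
  if (is.null(asfr)) asfr <- matrix(0, 45, n)
  if (is.null(dim(asfr))) asfr <- matrix(asfr, 45, n)
  if (ncol(asfr) == 1 && n > 1) asfr <- asfr[, rep(1, n), drop = FALSE]
  stopifnot(nrow(asfr) == 45, ncol(asfr) == n)
  srb <- rep_len(srb, n)
  surv <- .per_interval_surv(surv, n)
  G <- if (is.null(mig)) array(0, c(96, 2, n)) else unclass(mig)
  stopifnot(all(dim(G) == c(96, 2, n)))

  pop <- array(0, c(96, 2, n + 1))
  pop[, , 1] <- baseline
  Bmat <- matrix(0, 2, n, dimnames = list(SEXES, years[-(n + 1)]))
  Darr <- array(0, c(96, 2, n))
  clipped <- 0L
  fert_idx <- 11:55  # ages 10..54 within 1-based age vector

  for (t in seq_len(n)) {
    sv <- surv[[t]]
    smat <- cbind(sv$female$s, sv$male$s)          # 95 x 2
    sopen <- c(sv$female$open, sv$male$open)
    snew <- c(sv$female$newborn, sv$male$newborn)
    N <- pop[, , t]
    Nh <- N + G[, , t] / 2
    Ns <- matrix(0, 96, 2)
    Ns[2:95, ] <- Nh[1:94, ] * smat[1:94, ]
    Ns[96, ] <- Nh[95, ] * smat[95, ] + Nh[96, ] * sopen
    d_cohort <- Nh * (1 - rbind(smat, sopen))
    Nend <- Ns + G[, , t] / 2
    if (is.null(births)) {
      expo <- (N[fert_idx, 1] + Nend[fert_idx, 1]) / 2
      B <- sum(asfr[, t] * expo)
      Bf <- B / (1 + srb[t]); Bm <- B - Bf
    } else {
      Bf <- births[1, t]; Bm <- births[2, t]
    }
    Nend[1, ] <- Nend[1, ] + c(Bf, Bm) * snew
    D <- d_cohort
    D[1, ] <- D[1, ] + c(Bf, Bm) * (1 - snew)
    neg <- Nend < 0
    if (any(neg)) {
      clipped <- clipped + sum(neg)
      D[neg] <- D[neg] + Nend[neg]  # clipped mass absorbed by deaths
      Nend[neg] <- 0
    }
    pop[, , t + 1] <- Nend
    Bmat[, t] <- c(Bf, Bm)
    Darr[, , t] <- D
  }
  dimnames(Darr) <- dimnames(G) <- list(age = PROJ_AGES, sex = SEXES,
                                        year = years[-(n + 1)])
  list(pop = population_grid(pop, years),
       flows = list(births = Bmat, deaths = Darr, migrants = G),
       clipped = clipped)
}

#' Balancing-equation residual
#'
#' @param grid A [population_grid()] over years t0..T.
#' @param flows Vital flows as returned by [ccmpp_project()].
#' @return Numeric vector per interval: `N(t+1) - (N(t) + B - D + G)` totaled
#'   over age and sex.
#' @export
balance_residual <- function(grid, flows) {
  yrs <- grid_years(grid)
  n <- length(yrs) - 1
  vapply(seq_len(n), function(t) {
    sum(grid[, , t + 1]) -
      (sum(grid[, , t]) + sum(flows$births[, t]) - sum(flows$deaths[, , t]) +
         sum(flows$migrants[, , t]))
  }, numeric(1))
}

#' Backward cohort-component projection to a baseline year
#'
#' Reverse-survives an anchor population under zero net migration:
#' `N(a, t) = N(a+1, t+1) / S(a)`. The open 95+ interval is split between
#' age-94 entrants and open-interval stayers using the anchor census shape,
#' so a forward projection reproduces the anchor exactly. The implied
#' pre-survival birth counts for each back year (from the reconstructed age-0
#' populations) are returned so the forward projection can be reversed
#' exactly; the result is flagged low confidence for the balancing model.
#'
#' @param anchor A [population_grid()] at the anchor year (or 96 x 2 matrix).
#' @param surv Survivorship as in [ccmpp_project()], per back interval
#'   (recycled if a single list); element t corresponds to the interval
#'   starting at `anchor_year - years_back + t - 1`.
#' @param years_back Number of years to project backwards (>= 1).
#' @param anchor_year Year of the anchor population.
#' @param srb Sex ratio at birth used only to label implied births (unused in
#'   the reconstruction itself).
#' @return A list: `pop` ([population_grid()] from `anchor_year - years_back`
#'   to `anchor_year`), `implied_births` (2 x years_back matrix), and
#'   `low_confidence = TRUE`.
#' @export
back_project <- function(anchor, surv, years_back, anchor_year, srb = 1.05) {
  stopifnot(years_back >= 1)
  if (inherits(anchor, "population_grid")) anchor <- anchor[, , dim(anchor)[3]]
  anchor <- matrix(anchor, 96, 2)
  surv <- .per_interval_surv(surv, years_back)
  pop <- array(0, c(96, 2, years_back + 1))
  pop[, , years_back + 1] <- anchor
  # split of the open interval by the anchor shape (per sex)
  for (t in years_back:1) {
    sv <- surv[[t]]
    smat <- cbind(sv$female$s, sv$male$s)
    sopen <- c(sv$female$open, sv$male$open)
    snew <- c(sv$female$newborn, sv$male$newborn)
    if (any(c(smat, sopen, snew) <= 0)) stop("zero survivorship ratio")
    nxt <- pop[, , t + 1]
    cur <- matrix(0, 96, 2)
    cur[1:94, ] <- nxt[2:95, ] / smat[1:94, ]
    w94 <- anchor[95, ] * smat[95, ]
    wop <- anchor[96, ] * sopen
    rho <- ifelse(w94 + wop > 0, w94 / (w94 + wop), 0)
    cur[95, ] <- rho * nxt[96, ] / smat[95, ]
    cur[96, ] <- (1 - rho) * nxt[96, ] / sopen
    pop[, , t] <- cur
  }
  implied <- vapply(seq_len(years_back), function(t) {
    pop[1, , t + 1] / vapply(surv[[t]], `[[`, numeric(1), "newborn")
  }, numeric(2))
  implied <- matrix(implied, nrow = 2,
                    dimnames = list(SEXES, anchor_year - years_back:1))
  list(pop = population_grid(pop, (anchor_year - years_back):anchor_year),
       implied_births = implied, low_confidence = TRUE)
}
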