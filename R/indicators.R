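# Summary indicators computed from ASFR schedules, life tables and population
# grids: total fertility (TFR) and its under-25 / over-30 components, span
# aggregates, livebirths, net reproductive rate, growth and age-structure
# measures, and the Socio-demographic Index.

.as_asfr_matrix <- function(asfr) {
  if (inherits(asfr, "asfr_estimate")) asfr <- asfr$mean
  if (is.null(dim(asfr))) asfr <- matrix(asfr, ncol = 1)
  if (nrow(asfr) != 9)
    stop("need all nine 5-year maternal age groups 10-14 ... 50-54; got ",
         nrow(asfr))
  if (any(is.na(asfr))) {
    bad <- FERT_GROUPS[apply(is.na(asfr), 1, any)]
    stop("missing ASFR for group(s) starting at: ", paste(bad, collapse = ", "))
  }
  asfr
}

#' Fertility summary measures
#'
#' From 5-year-group ASFR (per woman-year): `TFR = 5 * sum(all groups)`,
#' `TFU25 = 5 * sum(10-14, 15-19, 20-24)`, `TFO30 = 5 * sum(30-34 ... 50-54)`,
#' so `TFU25 + 5*ASFR(25-29) + TFO30 = TFR` exactly. Span-aggregated ASFR is
#' total births over total woman-years in the span (equal group weights when
#' no population is supplied). Livebirths require female population counts.
#'
#' @param asfr An [asfr_estimate()], a length-9 vector, or a 9 x n matrix of
#'   rates per woman-year.
#' @param women Optional 9 x n matrix of female person-years by group.
#' @param span Optional `c(lo, hi)` age span (group-aligned) for the
#'   aggregated ASFR (e.g. `c(10, 20)` for ages 10-19).
#' @return List with `tfr`, `tfu25`, `tfo30` (vectors by year), and when
#'   requested/possible `span_asfr` and `livebirths`.
#' @export
fertility_summaries <- function(asfr, women = NULL, span = NULL) {
  m <- .as_asfr_matrix(asfr)
  out <- list(tfr = 5 * colSums(m),
              tfu25 = 5 * colSums(m[1:3, , drop = FALSE]),
              tfo30 = 5 * colSums(m[5:9, , drop = FALSE]))
  if (!is.null(span)) {
    sel <- which(FERT_GROUPS >= span[1] & FERT_GROUPS + 5 <= span[2])
    if (length(sel) == 0) stop("span does not cover any 5-year group")
    out$span_asfr <- if (is.null(women)) {
      colMeans(m[sel, , drop = FALSE])
    } else {
      colSums(m[sel, , drop = FALSE] * 5 * women[sel, , drop = FALSE]) /
        colSums(5 * women[sel, , drop = FALSE])
    }
  }
  if (!is.null(women)) out$livebirths <- colSums(m * 5 * women)
  out
}

#' Net reproductive rate
#'
#' Expected female livebirths per woman under period fertility, mortality and
#' sex ratio at birth:
#' `NRR = sum_g 5 * ASFR(g) * (1/(1+SRB)) * (5Lx_female(g) / (5 * l0))`.
#'
#' @param asfr Length-9 group rates per woman-year (or [asfr_estimate()] /
#'   matrix; each column gives one NRR).
#' @param srb Sex ratio at birth (males per female).
#' @param female_lt A [complete_lifetable()] for females.
#' @return NRR value(s).
#' @export
nrr <- function(asfr, srb, female_lt) {
  m <- .as_asfr_matrix(asfr)
  stopifnot(inherits(female_lt, "complete_lifetable"))
  L5 <- vapply(FERT_GROUPS, function(g)
    sum(female_lt$Lx[female_lt$age %in% g:(g + 4)]), numeric(1))
  surv <- L5 / (5 * female_lt$lx[1])
  as.numeric(colSums(m * 5 * surv / (1 + srb)))
}

#' Population summary measures
#'
#' Annualised logarithmic growth between two years, percent change, and
#' age-structure measures at the later year: working-age (15-64) proportion,
#' mean age (open interval placed at `95 + e(95)` when a life table is
#' supplied, else at age 100), and proportion female.
#'
#' @param pop A [population_grid()].
#' @param t1,t2 Years (`t1 < t2`).
#' @param life_table Optional [complete_lifetable()] for the open-interval
#'   mean-age contribution.
#' @return List with `growth_rate` (per year), `percent_change`,
#'   `working_age_share`, `mean_age`, `prop_female` (the last three at `t2`).
#' @export
population_summaries <- function(pop, t1, t2, life_table = NULL) {
  yrs <- grid_years(pop)
  stopifnot(t1 < t2, t1 %in% yrs, t2 %in% yrs)
  n1 <- sum(pop[, , match(t1, yrs)])
  n2 <- sum(pop[, , match(t2, yrs)])
  if (n1 <= 0 || n2 <= 0) stop("zero population")
  N2 <- pop[, , match(t2, yrs)]
  open_age <- if (!is.null(life_table)) {
    T95 <- sum(life_table$Lx[96:111])
    95 + if (is.finite(T95) && life_table$lx[96] > 0)
      T95 / life_table$lx[96] else 5
  } else 100
  agemid <- c(0:94 + 0.5, open_age)
  list(growth_rate = log(n2 / n1) / (t2 - t1),
       percent_change = 100 * (n2 / n1 - 1),
       working_age_share = sum(N2[16:65, ]) / sum(N2),
       mean_age = sum(agemid * rowSums(N2)) / sum(N2),
       prop_female = sum(N2[, 1]) / sum(N2))
}

#' Percent change between two printed population totals
#'
#' Convenience for worked examples: `100 * (n2/n1 - 1)`.
#' @param n1,n2 Totals at the earlier and later time.
#' @return Percent change.
#' @export
percent_change <- function(n1, n2) {
  if (n1 <= 0) stop("zero population")
  100 * (n2 / n1 - 1)
}

#' Socio-demographic Index
#'
#' Geometric mean of three components rescaled to `[0, 1]`: total fertility
#' under age 25 (inverted, so high fertility gives a low component),
#' lag-distributed income per capita (log scale), and mean years of education
#' in the population aged 15 and over.
#'
#' @param tfu25 Total fertility under 25 (livebirths per woman).
#' @param ldi Lag-distributed income per capita.
#' @param education Mean years of education (15+).
#' @param anchors List of `c(min, max)` anchors per component; defaults:
#'   `tfu25 = c(0, 3)`, `ldi = c(250, 60000)` (log scale), `edu = c(0, 17)`.
#' @return List with `sdi` and the three rescaled `components`.
#' @export
sdi <- function(tfu25, ldi, education,
                anchors = list(tfu25 = c(0, 3), ldi = c(250, 60000),
                               edu = c(0, 17))) {
  for (a in anchors) if (a[1] >= a[2]) stop("anchor min must be below max")
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  c_f <- clamp01((anchors$tfu25[2] - tfu25) /
                   (anchors$tfu25[2] - anchors$tfu25[1]))
  c_i <- clamp01((log(ldi) - log(anchors$ldi[1])) /
                   (log(anchors$ldi[2]) - log(anchors$ldi[1])))
  c_e <- clamp01((education - anchors$edu[1]) /
                   (anchors$edu[2] - anchors$edu[1]))
  list(sdi = (c_f * c_i * c_e)^(1 / 3),
       components = cbind(fertility = c_f, income = c_i, education = c_e))
}
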