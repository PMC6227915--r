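# Tidy CSV schemas. Ages are integers; age intervals are half-open
# [age_start, age_end); the open interval is coded age_end = -1.

#' Convert a population grid to the tidy population schema
#'
#' @param grid A [population_grid()].
#' @param location Location label.
#' @return data.frame with columns `location`, `year`, `sex`, `age`, `value`
#'   (age 95 is the open 95+ interval).
#' @export
population_to_df <- function(grid, location = "synthetic") {
  yrs <- grid_years(grid)
  data.frame(location = location,
             year = rep(yrs, each = 96 * 2),
             sex = rep(rep(SEXES, each = 96), length(yrs)),
             age = rep(0:95, 2 * length(yrs)),
             value = as.numeric(unclass(grid)))
}

#' Rebuild a population grid from the tidy schema
#'
#' @param df data.frame in the [population_to_df()] schema (one location).
#' @return A [population_grid()].
#' @export
population_from_df <- function(df) {
  yrs <- sort(unique(df$year))
  arr <- array(0, c(96, 2, length(yrs)))
  for (si in 1:2) for (yi in seq_along(yrs)) {
    sub <- df[df$sex == SEXES[si] & df$year == yrs[yi], ]
    arr[sub$age + 1, si, yi] <- sub$value
  }
  population_grid(arr, yrs)
}

#' Write/read the package CSV schemas
#'
#' Thin wrappers around [utils::write.csv()] / [utils::read.csv()]; the
#' fertility and census schemas are plain data.frames already.
#'
#' @param x Object/data.frame to write.
#' @param path File path.
#' @return `read_schema_csv` returns a data.frame.
#' @export
write_schema_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schema_csv
#' @export
read_schema_csv <- function(path) utils::read.csv(path)

#' Convert an abridged life table to the tidy lifetable schema
#'
#' @param lt An [abridged_lifetable()].
#' @param location,year,sex Labels.
#' @return data.frame with `location`, `year`, `sex`, `age_start`, `age_end`,
#'   `qx`, `lx`, `ax`.
#' @export
lifetable_to_df <- function(lt, location = "synthetic", year = NA, sex = NA) {
  data.frame(location = location, year = year, sex = sex,
             age_start = lt$age_start, age_end = lt$age_end,
             qx = lt$qx, lx = lt$lx, ax = lt$ax)
}

#' Published 2017 fertility and population fixtures
#'
#' Reads the worked-example fixture shipped with the package: published 2017
#' age-specific fertility rates (per 1000 women) for selected locations, and
#' published global population totals (thousands) for 1950 and 2017.
#'
#' @return A list with `asfr` (data.frame location/age_start/age_end/
#'   asfr_per_1000) and `pop_totals` (data.frame year/total_thousands).
#' @export
published_fixtures <- function() {
  d <- system.file("extdata", package = "popfert")
  list(asfr = utils::read.csv(file.path(d, "published_asfr_2017_selected.csv")),
       pop_totals = utils::read.csv(file.path(
         d, "published_global_population_totals.csv")))
}
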