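#' Season and decade definitions
#'
#' Connectivity is modelled for two movement seasons: spring (April-June)
#' and early winter (November-December). Monthly sea-ice grids are first
#' averaged within each season and year, then the annual seasonal means
#' are averaged within decade groups (the historical reference period is
#' treated as one long "decade" group, e.g. 1991-2005).
#'
#' @param name Season name. `season_definition()` accepts any label but
#'   the two standard seasons have constructors of their own.
#' @param months Integer vector of month numbers within one calendar year.
#' @return A `season_definition`.
#' @export
season_definition <- function(name, months) {
  months <- as.integer(months)
  if (length(months) == 0 || anyNA(months) || any(months < 1 | months > 12)) {
    abort("`months` must be non-empty month numbers within one calendar year.")
  }
  structure(list(name = as.character(name), months = sort(unique(months))),
            class = "season_definition")
}

#' @rdname season_definition
#' @export
spring_season <- function() season_definition("spring", 4:6)

#' @rdname season_definition
#' @export
early_winter_season <- function() season_definition("early_winter", c(11L, 12L))

#' @param label Text label for the group, e.g. `"2021-2030"`.
#' @param years Inclusive, contiguous integer year range. Ordinary decade
#'   groups span at most 10 years; a longer explicit range (the 15-year
#'   historical block) is accepted.
#' @rdname season_definition
#' @export
decade_group <- function(label, years) {
  years <- as.integer(years)
  if (length(years) == 0 || anyNA(years)) abort("`years` must be integers.")
  years <- sort(years)
  if (!all(diff(years) == 1L) && length(years) > 1) {
    abort("`years` must be contiguous.")
  }
  structure(list(label = as.character(label), years = years),
            class = "decade_group")
}

#' Standard projection decades
#'
#' The nine projection decades 2021-2030 through 2091-2100.
#'
#' @return A named list of [decade_group()]s.
#' @export
projection_decades <- function() {
  starts <- seq(2021L, 2091L, by = 10L)
  out <- lapply(starts, function(s) {
    decade_group(sprintf("%d-%d", s, s + 9L), s:(s + 9L))
  })
  setNames(out, vapply(out, `[[`, character(1), "label"))
}

#' Seasonal mean of monthly SIC grids
#'
#' Cell-wise arithmetic mean of one year's monthly sea-ice grids over the
#' season's months. A cell is nodata in the output if any contributing
#' grid is nodata there.
#'
#' @param monthly Named list of [raster_grid()]s keyed `"<year>_<month>"`
#'   (as produced by [generate_sic_series()]).
#' @param season A [season_definition()].
#' @param year Integer year.
#' @return A [raster_grid()] of seasonal-mean SIC.
#' @export
seasonal_mean <- function(monthly, season, year) {
  stopifnot(inherits(season, "season_definition"))
  keys <- sic_key(year, season$months)
  missing <- keys[!keys %in% names(monthly)]
  if (length(missing)) {
    abort(sprintf("Missing monthly grids for season '%s': %s",
                  season$name, paste(missing, collapse = ", ")))
  }
  grids <- monthly[keys]
  do.call(check_alignment, grids)
  vals <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
  ref <- grids[[1]]
  raster_grid(vals, cell_size_km = ref$cell_size_km,
              nodata_value = ref$nodata_value, origin = ref$origin)
}

#' Decadal mean of annual seasonal SIC grids
#'
#' Cell-wise mean over the decade group's years of the annual seasonal
#' means. Every year of the group must be present; partial decades are an
#' error, never silently averaged over fewer years.
#'
#' @param annual_means Named list of [raster_grid()]s keyed by year
#'   (`as.character(year)`).
#' @param decade A [decade_group()].
#' @return A [raster_grid()] of decadal-mean SIC.
#' @export
decadal_mean <- function(annual_means, decade) {
  stopifnot(inherits(decade, "decade_group"))
  keys <- as.character(decade$years)
  missing <- keys[!keys %in% names(annual_means)]
  if (length(missing)) {
    abort(sprintf("Decade %s is incomplete; missing years: %s",
                  decade$label, paste(missing, collapse = ", ")))
  }
  grids <- annual_means[keys]
  do.call(check_alignment, grids)
  vals <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
  ref <- grids[[1]]
  raster_grid(vals, cell_size_km = ref$cell_size_km,
              nodata_value = ref$nodata_value, origin = ref$origin)
}

#' Decadal-mean seasonal SIC straight from a monthly series
#'
#' Convenience composition of [seasonal_mean()] over each year of the
#' decade followed by [decadal_mean()].
#'
#' @inheritParams seasonal_mean
#' @inheritParams decadal_mean
#' @return A [raster_grid()].
#' @export
decadal_seasonal_mean <- function(monthly, season, decade) {
  annual <- lapply(decade$years, function(y) seasonal_mean(monthly, season, y))
  decadal_mean(setNames(annual, as.character(decade$years)), decade)
}
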