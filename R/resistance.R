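#' Habitat reclassification tables
#'
#' Land resistance comes from reclassifying seasonal habitat
#' probability-of-use into ten bins. The best-habitat bin gets resistance
#' 1 and each successive bin one more, except the two lowest-probability
#' bins (roughly 0-15 percent use) which jump to 20 and 30 so that
#' animals route onto sea ice rather than across effectively unused land.
#'
#' Bins are half-open `[lower, upper)` with the top bin closed at its
#' upper bound, so every probability in `[0, top]` maps to exactly one
#' resistance.
#'
#' @param bounds Data frame or tibble with columns `lower`, `upper`,
#'   `resistance`; bins must tile `[0, top]` without gaps or overlaps and
#'   resistance must strictly decrease as probability increases.
#' @return A `bin_table`.
#' @export
bin_table <- function(bounds) {
  bounds <- as_tibble(bounds)
  stopifnot(all(c("lower", "upper", "resistance") %in% names(bounds)))
  bounds <- dplyr::arrange(bounds, .data$lower)
  if (any(bounds$resistance <= 0)) abort("Resistances must be positive.")
  if (bounds$lower[1] != 0) abort("Bins must start at probability 0.")
  if (nrow(bounds) > 1) {
    if (any(abs(bounds$lower[-1] - bounds$upper[-nrow(bounds)]) > 1e-12)) {
      abort("Bins must tile the probability range without gaps or overlaps.")
    }
    if (any(diff(bounds$resistance) >= 0)) {
      abort("Resistance must strictly decrease as probability increases.")
    }
  }
  structure(list(bounds = bounds, top = bounds$upper[nrow(bounds)]),
            class = "bin_table")
}

#' @rdname bin_table
#' @export
spring_bin_table <- function() {
  bin_table(tibble(
    lower = c(0.00, 0.09, 0.16, 0.24, 0.33, 0.41, 0.50, 0.58, 0.65, 0.73),
    upper = c(0.09, 0.16, 0.24, 0.33, 0.41, 0.50, 0.58, 0.65, 0.73, 0.83),
    resistance = c(30, 20, 8, 7, 6, 5, 4, 3, 2, 1)
  ))
}

#' @rdname bin_table
#' @export
winter_bin_table <- function() {
  bin_table(tibble(
    lower = c(0.00, 0.07, 0.15, 0.23, 0.30, 0.39, 0.48, 0.55, 0.64, 0.76),
    upper = c(0.07, 0.15, 0.23, 0.30, 0.39, 0.48, 0.55, 0.64, 0.76, 0.88),
    resistance = c(30, 20, 8, 7, 6, 5, 4, 3, 2, 1)
  ))
}

#' Reclassify habitat probability into land resistance
#'
#' Each land cell's probability of use is mapped to its bin's resistance.
#' Nodata propagates; probabilities above the top bin's upper bound are a
#' validation error (the binning domain is `[0, top]`).
#'
#' @param habitat A [raster_grid()] of probabilities in `[0, top]`.
#' @param bins A [bin_table()].
#' @return A [raster_grid()] of land resistances.
#' @examples
#' g <- raster_grid(matrix(c(0.80, 0.05), 1, 2))
#' bin_habitat_probability(g, spring_bin_table())$values
#' @export
bin_habitat_probability <- function(habitat, bins) {
  stopifnot(is_raster_grid(habitat), inherits(bins, "bin_table"))
  v <- habitat$values
  live <- !is.na(v)
  if (any(v[live] < 0 | v[live] > bins$top + 1e-12)) {
    bad <- which(live & (v < 0 | v > bins$top + 1e-12))
    abort(sprintf(
      "%d habitat values outside [0, %g]; first offending value %g.",
      length(bad), bins$top, v[bad[1]]
    ))
  }
  b <- bins$bounds
  res <- matrix(NA_real_, habitat$n_rows, habitat$n_cols)
  # half-open [lower, upper); top bin closed at its upper bound
  idx <- findInterval(pmin(v[live], bins$top), c(b$lower, b$upper[nrow(b)]),
                      rightmost.closed = TRUE)
  res[live] <- b$resistance[idx]
  raster_grid(res, cell_size_km = habitat$cell_size_km,
              nodata_value = habitat$nodata_value, origin = habitat$origin)
}

#' Sea-ice transform parameters
#'
#' Sea resistance is a linear transform of sea-ice concentration (SIC):
#' cells below the impassability cutoff (default 70 percent) are
#' impassable (infinite resistance); remaining cells get
#' `(100 - SIC) + offset` with a default offset of 10, so that passable
#' sea (resistance 10-40) is always costlier than all but the two worst
#' land bins.
#'
#' @param impassable_below SIC percent below which sea is impassable.
#' @param offset Constant added to the remaining resistances.
#' @return A `sic_transform_params`.
#' @export
sic_transform_params <- function(impassable_below = 70, offset = 10) {
  stopifnot(impassable_below >= 0, impassable_below <= 100, offset >= 0)
  structure(list(impassable_below = impassable_below, offset = offset),
            class = "sic_transform_params")
}

#' Transform sea-ice concentration to sea resistance
#'
#' @param sic A [raster_grid()] of SIC percent in `[0, 100]`.
#' @param params A [sic_transform_params()].
#' @return A [raster_grid()] whose values are finite resistances on
#'   passable sea and `Inf` (the impassable sentinel) below the cutoff;
#'   nodata propagates.
#' @examples
#' g <- raster_grid(matrix(c(99, 70, 69.9, 100), 2, 2))
#' sic_to_resistance(g)$values
#' @export
sic_to_resistance <- function(sic, params = sic_transform_params()) {
  stopifnot(is_raster_grid(sic), inherits(params, "sic_transform_params"))
  v <- sic$values
  live <- !is.na(v)
  if (any(v[live] < 0 | v[live] > 100)) {
    abort("SIC values must lie in [0, 100].")
  }
  res <- (100 - v) + params$offset
  res[live & v < params$impassable_below] <- Inf
  raster_grid(res, cell_size_km = sic$cell_size_km,
              nodata_value = sic$nodata_value, origin = sic$origin)
}

#' Combine land and sea resistance into one surface
#'
#' The island label grid is authoritative: land cells (label > 0) take the
#' land resistance, sea cells (label 0) the sea resistance. A land cell
#' with nodata land resistance is a validation error (habitat must cover
#' every island cell).
#'
#' @param land_res [raster_grid()] from [bin_habitat_probability()].
#' @param sea_res [raster_grid()] from [sic_to_resistance()].
#' @param islands An [island_grid()] aligned with both.
#' @return A `resistance_surface`: fields `resistance` (matrix; `Inf` =
#'   impassable), `provenance` (`"land"`/`"sea"` matrix) and the grid
#'   geometry.
#' @export
combine_surfaces <- function(land_res, sea_res, islands) {
  stopifnot(is_raster_grid(land_res), is_raster_grid(sea_res),
            is_island_grid(islands))
  check_alignment(land_res, sea_res, islands)
  land <- islands$labels > 0L
  if (any(land & is.na(land_res$values))) {
    bad <- which(land & is.na(land_res$values), arr.ind = TRUE)
    abort(sprintf(
      "%d land cells have nodata land resistance; first at (row %d, col %d).",
      nrow(bad), bad[1, 1], bad[1, 2]
    ))
  }
  res <- matrix(NA_real_, islands$n_rows, islands$n_cols)
  res[land] <- land_res$values[land]
  res[!land] <- sea_res$values[!land]
  if (any(res <= 0, na.rm = TRUE)) {
    abort("Resistance surface contains nonpositive resistances.")
  }
  prov <- matrix("sea", islands$n_rows, islands$n_cols)
  prov[land] <- "land"
  structure(
    list(
      resistance = res,
      provenance = prov,
      n_rows = islands$n_rows, n_cols = islands$n_cols,
      cell_size_km = islands$cell_size_km, origin = islands$origin
    ),
    class = "resistance_surface"
  )
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat(sprintf(
    "<resistance_surface> %d x %d cells: %d land, %d passable sea, %d impassable\n",
    x$n_rows, x$n_cols, sum(x$provenance == "land"),
    sum(x$provenance == "sea" & is.finite(x$resistance), na.rm = TRUE),
    sum(is.infinite(x$resistance), na.rm = TRUE)
  ))
  invisible(x)
}

is_resistance_surface <- function(x) inherits(x, "resistance_surface")

#' Build a resistance surface directly from matrices
#'
#' Low-level constructor used by tests and small examples: a plain
#' resistance matrix (`Inf` = impassable, `NA` not allowed) plus an
#' island label matrix.
#'
#' @param resistance Numeric matrix of positive resistances / `Inf`.
#' @param labels Integer label matrix (0 = sea) of the same shape.
#' @param cell_size_km Cell size.
#' @return A list with `surface` and `islands`.
#' @export
resistance_surface_from_matrix <- function(resistance, labels,
                                           cell_size_km = 25) {
  islands <- island_grid(labels, cell_size_km = cell_size_km)
  if (any(is.na(resistance))) abort("`resistance` must not contain NA.")
  if (any(resistance <= 0)) abort("Resistances must be positive.")
  prov <- matrix("sea", nrow(resistance), ncol(resistance))
  prov[labels > 0L] <- "land"
  surface <- structure(
    list(resistance = resistance, provenance = prov,
         n_rows = nrow(resistance), n_cols = ncol(resistance),
         cell_size_km = cell_size_km, origin = c(0, 0)),
    class = "resistance_surface"
  )
  list(surface = surface, islands = islands)
}
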