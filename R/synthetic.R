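#' Configuration for a synthetic archipelago
#'
#' Describes the random archipelago generator: grid shape, island count
#' and size range, and the autocorrelation length of the habitat field.
#' The generator stands in for real inputs (island masks and seasonal
#' habitat probability-of-use surfaces) so the whole pipeline can be run
#' and tested without external rasters.
#'
#' Habitat probability fields are smoothed white noise with a
#' north-to-south productivity trend, rescaled onto `[0, max_prob]` per
#' season. The defaults cap spring at 0.83 and winter at 0.88, the
#' ceilings of the default reclassification tables, so generated
#' surfaces always fall inside the binning domain.
#'
#' @param n_rows,n_cols Grid shape.
#' @param n_islands Number of disjoint islands to place.
#' @param island_radius_range_cells Length-2 integer range of island
#'   radii, in cells.
#' @param habitat_smoothness_cells Half-width of the moving-average
#'   smoothing window (autocorrelation length), in cells.
#' @param cell_size_km Cell edge length (km).
#' @param max_prob_spring,max_prob_winter Upper bound of the rescaled
#'   habitat fields per season.
#' @param seed Integer seed; identical configs give identical output.
#' @return An `archipelago_config` list.
#' @export
archipelago_config <- function(n_rows = 60, n_cols = 60, n_islands = 8,
                               island_radius_range_cells = c(1, 5),
                               habitat_smoothness_cells = 3,
                               cell_size_km = 25,
                               max_prob_spring = 0.83,
                               max_prob_winter = 0.88,
                               seed = 1) {
  stopifnot(n_rows >= 4, n_cols >= 4, n_islands >= 1,
            length(island_radius_range_cells) == 2,
            island_radius_range_cells[1] >= 1,
            island_radius_range_cells[2] >= island_radius_range_cells[1],
            habitat_smoothness_cells >= 1)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      n_islands = as.integer(n_islands),
      island_radius_range_cells = as.integer(island_radius_range_cells),
      habitat_smoothness_cells = habitat_smoothness_cells,
      cell_size_km = cell_size_km,
      max_prob_spring = max_prob_spring,
      max_prob_winter = max_prob_winter,
      seed = as.integer(seed)
    ),
    class = "archipelago_config"
  )
}

# sample() treats a length-1 numeric as 1:n; this never does.
sample_one <- function(x) x[sample.int(length(x), 1L)]

# Box-filter smoothing with edge renormalisation.
smooth_field <- function(m, half_width) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  w <- as.integer(half_width)
  for (dr in -w:w) {
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    for (dc in -w:w) {
      cs <- max(1, 1 - dc):min(nc, nc - dc)
      acc[rs, cs] <- acc[rs, cs] + m[rs + dr, cs + dc]
      cnt[rs, cs] <- cnt[rs, cs] + 1
    }
  }
  acc / cnt
}

#' Generate a synthetic archipelago
#'
#' Places disjoint, roughly circular islands at random positions (with at
#' least one sea cell between any two islands), then draws spring and
#' winter habitat probability-of-use fields as spatially smoothed
#' Gaussian noise plus a north-to-south increasing productivity trend,
#' rescaled to the season's probability range on land and nodata at sea.
#'
#' @param config An [archipelago_config()].
#' @return A list with elements `islands` (an [island_grid()]) and
#'   `habitat` (list of `spring` / `winter` [raster_grid()]s).
#' @examples
#' arc <- generate_archipelago(archipelago_config(n_rows = 20, n_cols = 20,
#'                                                n_islands = 3, seed = 7))
#' length(arc$islands$island_ids)
#' @export
generate_archipelago <- function(config) {
  stopifnot(inherits(config, "archipelago_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  labels <- matrix(0L, nr, nc)
  rmin <- config$island_radius_range_cells[1]
  rmax <- config$island_radius_range_cells[2]
  max_tries <- 400L
  for (id in seq_len(config$n_islands)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      rad <- sample_one(rmin:rmax)
      r0 <- sample_one(seq(rad + 1, nr - rad))
      c0 <- sample_one(seq(rad + 1, nc - rad))
      rows <- pmax(1, r0 - rad - 1):pmin(nr, r0 + rad + 1)
      cols <- pmax(1, c0 - rad - 1):pmin(nc, c0 + rad + 1)
      # disk mask within the bounding box
      rr <- outer(rows - r0, rep(1, length(cols)))
      cc <- outer(rep(1, length(rows)), cols - c0)
      disk <- (rr^2 + cc^2) <= rad^2
      # require a one-cell sea moat: nothing else within the padded box
      if (any(labels[rows, cols] != 0L)) next
      sub <- labels[rows, cols]
      sub[disk] <- id
      labels[rows, cols] <- sub
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf(
        "Could not place island %d without overlap after %d tries; reduce n_islands or radii.",
        id, max_tries
      ))
    }
  }
  islands <- island_grid(labels, cell_size_km = config$cell_size_km)

  habitat_field <- function(max_prob) {
    noise <- matrix(rnorm(nr * nc), nr, nc)
    sm <- smooth_field(noise, config$habitat_smoothness_cells)
    trend <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
    f <- sm + trend  # southern rows (larger row index) more productive
    f[labels == 0L] <- NA_real_
    rng <- range(f, na.rm = TRUE)
    if (diff(rng) > 0) f <- (f - rng[1]) / diff(rng)
    else f <- f * 0 + 0.5
    raster_grid(f * max_prob, cell_size_km = config$cell_size_km)
  }
  list(
    islands = islands,
    habitat = list(
      spring = habitat_field(config$max_prob_spring),
      winter = habitat_field(config$max_prob_winter)
    )
  )
}

#' Configuration for a synthetic sea-ice concentration scenario
#'
#' Parametrises the monthly sea-ice concentration (SIC) generator:
#' a monthly baseline climatology, a linear decline over years whose rate
#' depends on the emissions scenario, a latitudinal gradient so southern
#' cells lose ice first, a multiplier that makes early-winter
#' (November-December) ice decline faster than spring ice, and additive
#' Gaussian noise. Generated SIC is clamped to `[0, 100]` percent.
#'
#' Default decline rates are 0 (historical), 0.45 (moderate) and 0.9
#' (high) percent per year, so the high scenario loses ice twice as fast
#' as the moderate one, and the default year ranges are 1991-2005 for the
#' historical block and 2021-2100 for projections.
#'
#' @param scenario_name One of `"historical"`, `"moderate"`, `"high"`.
#' @param start_year,end_year Inclusive year range (defaults by scenario).
#' @param monthly_baseline Named numeric vector, names = month numbers
#'   (as integers 1-12), values = baseline SIC percent. The default
#'   covers the spring (4-6) and early-winter (11, 12) months.
#' @param annual_decline_rate Percent SIC lost per year (default by
#'   scenario).
#' @param latitude_gradient Percent SIC subtracted per row southwards.
#' @param winter_decline_multiplier Factor (>= 1) applied to the decline
#'   in November and December.
#' @param noise_sd Standard deviation of additive Gaussian noise (percent).
#' @param seed Integer seed.
#' @return A `sic_scenario_config` list.
#' @export
sic_scenario_config <- function(scenario_name = c("historical", "moderate", "high"),
                                start_year = NULL, end_year = NULL,
                                monthly_baseline = c(`4` = 97, `5` = 95, `6` = 88,
                                                     `11` = 86, `12` = 94),
                                annual_decline_rate = NULL,
                                latitude_gradient = 0.5,
                                winter_decline_multiplier = 1.5,
                                noise_sd = 2,
                                seed = 1) {
  scenario_name <- match.arg(scenario_name)
  if (is.null(start_year)) {
    start_year <- if (scenario_name == "historical") 1991L else 2021L
  }
  if (is.null(end_year)) {
    end_year <- if (scenario_name == "historical") 2005L else 2100L
  }
  if (is.null(annual_decline_rate)) {
    annual_decline_rate <- switch(scenario_name,
      historical = 0, moderate = 0.45, high = 0.9
    )
  }
  months <- suppressWarnings(as.integer(names(monthly_baseline)))
  if (anyNA(months) || any(months < 1 | months > 12)) {
    abort("`monthly_baseline` must be named by month numbers 1-12.")
  }
  stopifnot(end_year >= start_year, winter_decline_multiplier >= 1,
            noise_sd >= 0, annual_decline_rate >= 0)
  structure(
    list(
      scenario_name = scenario_name,
      start_year = as.integer(start_year), end_year = as.integer(end_year),
      monthly_baseline = monthly_baseline,
      annual_decline_rate = annual_decline_rate,
      latitude_gradient = latitude_gradient,
      winter_decline_multiplier = winter_decline_multiplier,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sic_scenario_config"
  )
}

sic_key <- function(year, month) sprintf("%d_%02d", year, month)

#' Generate a monthly sea-ice concentration series
#'
#' Evaluates, for every year of the scenario and every month of the
#' baseline climatology,
#' `SIC = clamp(baseline[month] - decline(year, month)
#'        - latitude_gradient * south_offset(row) + noise, 0, 100)`
#' where `decline(year, month) = annual_decline_rate * (year - start_year)`,
#' multiplied by `winter_decline_multiplier` in November and December,
#' and `south_offset(row)` counts rows from the northern grid edge.
#' Only sea cells carry SIC; land cells are nodata when an island grid is
#' supplied.
#'
#' @param config A [sic_scenario_config()].
#' @param n_rows,n_cols Grid shape.
#' @param islands Optional [island_grid()]; its land cells become nodata.
#' @param cell_size_km Cell size for the produced grids.
#' @return A named list of [raster_grid()]s keyed `"<year>_<month>"`,
#'   with attributes `years` and `months`.
#' @export
generate_sic_series <- function(config, n_rows, n_cols, islands = NULL,
                                cell_size_km = if (!is.null(islands)) islands$cell_size_km else 25) {
  stopifnot(inherits(config, "sic_scenario_config"))
  if (!is.null(islands)) {
    stopifnot(is_island_grid(islands))
    if (islands$n_rows != n_rows || islands$n_cols != n_cols) {
      abort("`islands` shape does not match the requested grid shape.")
    }
  }
  set.seed(config$seed)
  months <- as.integer(names(config$monthly_baseline))
  years <- config$start_year:config$end_year
  south_offset <- matrix(rep(seq_len(n_rows) - 1L, n_cols), n_rows, n_cols)
  lat_term <- config$latitude_gradient * south_offset
  out <- list()
  for (year in years) {
    for (k in seq_along(months)) {
      month <- months[k]
      mult <- if (month %in% c(11L, 12L)) config$winter_decline_multiplier else 1
      decline <- config$annual_decline_rate * (year - config$start_year) * mult
      noise <- if (config$noise_sd > 0) {
        matrix(rnorm(n_rows * n_cols, sd = config$noise_sd), n_rows, n_cols)
      } else 0
      sic <- config$monthly_baseline[[k]] - decline - lat_term + noise
      sic <- pmin(pmax(sic, 0), 100)
      if (!is.null(islands)) sic[islands$labels > 0L] <- NA_real_
      out[[sic_key(year, month)]] <- raster_grid(sic, cell_size_km = cell_size_km)
    }
  }
  attr(out, "years") <- years
  attr(out, "months") <- months
  attr(out, "scenario") <- config$scenario_name
  out
}

#' Tiny hand-assigned fixture archipelago
#'
#' An 8 x 8 grid with three islands (two multi-cell, one single-cell),
#' fixed habitat probabilities spanning the lowest and highest
#' reclassification bins, and a north-to-south SIC gradient with cells
#' both above and below the 70 percent impassability cutoff. Values are
#' hard-coded, not random; used as the worked example throughout the
#' documentation and as an oracle fixture in tests.
#'
#' @return A list with `islands` ([island_grid()]), `habitat`
#'   (`spring` / `winter` [raster_grid()]s) and `sic` (a [raster_grid()]).
#' @export
make_worked_fixture <- function() {
  labels <- matrix(0L, 8, 8)
  labels[2, 2] <- 1L; labels[2, 3] <- 1L; labels[3, 2] <- 1L
  labels[6, 6] <- 2L; labels[7, 6] <- 2L; labels[7, 7] <- 2L
  labels[2, 7] <- 3L
  islands <- island_grid(labels, cell_size_km = 25)

  hab <- matrix(NA_real_, 8, 8)
  hab[2, 2] <- 0.80; hab[2, 3] <- 0.60; hab[3, 2] <- 0.05
  hab[6, 6] <- 0.45; hab[7, 6] <- 0.20; hab[7, 7] <- 0.70
  hab[2, 7] <- 0.12
  habitat <- list(
    spring = raster_grid(hab, cell_size_km = 25),
    winter = raster_grid(hab, cell_size_km = 25)
  )

  # SIC falls southwards from 95 to 60; rows 7-8 are below the 70 cutoff.
  sic <- matrix(rep(100 - 5 * seq_len(8), 8), 8, 8)
  sic[labels > 0L] <- NA_real_
  list(islands = islands, habitat = habitat,
       sic = raster_grid(sic, cell_size_km = 25))
}
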