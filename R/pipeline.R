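#' Percent change relative to a baseline
#'
#' `100 * (current - baseline) / baseline`, the form used for reporting
#' changes in mean cumulative current density against the historical
#' scenario.
#'
#' @param current_mean,baseline_mean Real values; `baseline_mean` must be
#'   strictly positive.
#' @return Percent change (a bare number, e.g. `27` for +27%).
#' @examples
#' percent_change(1.27, 1.0)
#' @export
percent_change <- function(current_mean, baseline_mean) {
  if (!is.finite(baseline_mean) || baseline_mean <= 0) {
    abort("Percent change is undefined for a nonpositive baseline.")
  }
  100 * (current_mean - baseline_mean) / baseline_mean
}

#' Assemble a pipeline configuration
#'
#' Bundles everything one full scenario analysis needs: the island grid,
#' per-season habitat surfaces, per-scenario monthly SIC series, season
#' and decade definitions, the resistance parameters, and the graph
#' neighbourhood. `habitat` and `bins` are named by season; the name
#' `"early_winter"` falls back to an entry named `"winter"` so generator
#' output plugs in directly.
#'
#' @param islands An [island_grid()].
#' @param habitat Named list of habitat [raster_grid()]s by season.
#' @param sic Named list: scenario name -> monthly SIC series
#'   (as from [generate_sic_series()]).
#' @param decades Named list: scenario name -> list of [decade_group()]s.
#' @param seasons List of [season_definition()]s.
#' @param bins Named list of [bin_table()]s by season.
#' @param sic_params A [sic_transform_params()].
#' @param neighborhood 4 or 8.
#' @param baseline_scenario Scenario name used as the percent-change
#'   baseline (its first decade group), or `NA` to skip.
#' @param out_dir Optional directory for artifact files.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(islands, habitat, sic, decades,
                            seasons = list(spring_season(), early_winter_season()),
                            bins = list(spring = spring_bin_table(),
                                        early_winter = winter_bin_table()),
                            sic_params = sic_transform_params(),
                            neighborhood = 8,
                            baseline_scenario = "historical",
                            out_dir = NULL) {
  stopifnot(is_island_grid(islands), is.list(habitat), is.list(sic),
            is.list(decades))
  if (!setequal(names(sic), names(decades))) {
    abort("`sic` and `decades` must cover the same scenario names.")
  }
  structure(
    list(islands = islands, habitat = habitat, sic = sic, decades = decades,
         seasons = seasons, bins = bins, sic_params = sic_params,
         neighborhood = neighborhood, baseline_scenario = baseline_scenario,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

season_entry <- function(lst, season_name) {
  if (season_name %in% names(lst)) return(lst[[season_name]])
  if (season_name == "early_winter" && "winter" %in% names(lst)) {
    return(lst[["winter"]])
  }
  abort(sprintf("No entry named '%s' (or 'winter') supplied.", season_name))
}

#' Run the full scenario analysis
#'
#' For every (season, scenario, decade): average the monthly SIC series
#' into the decadal seasonal mean, transform it to sea resistance,
#' reclassify the season's habitat surface to land resistance, mosaic the
#' two, solve all-pairs cumulative current, build the least-cost island
#' network, and compute (area-corrected) current-flow centrality. The
#' mean cumulative current over all land cells is compared against the
#' baseline scenario's value for the same season as a percent change.
#'
#' The run is deterministic: identical configuration gives identical
#' outputs (all randomness lives in the synthetic generators, seeded via
#' their configs).
#'
#' @param config A [pipeline_config()].
#' @return A `scenario_report` with tibbles `summary` (season, scenario,
#'   decade, connection counts, land mean current, percent change),
#'   `island_means`, `centrality` and `links`. When `out_dir` is set, per
#'   (season, scenario, decade) artifacts are written under
#'   `<season>/<scenario>/<decade>/` plus a top-level `summary.csv`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- list(); means <- list(); cents <- list(); links <- list()
  for (season in config$seasons) {
    hab <- season_entry(config$habitat, season$name)
    bins <- season_entry(config$bins, season$name)
    land_res <- bin_habitat_probability(hab, bins)
    for (scenario in names(config$sic)) {
      for (decade in config$decades[[scenario]]) {
        sic_dec <- decadal_seasonal_mean(config$sic[[scenario]], season, decade)
        sea_res <- sic_to_resistance(sic_dec, config$sic_params)
        surface <- combine_surfaces(land_res, sea_res, config$islands)
        cmap <- cumulative_current(surface, config$islands,
                                   config$neighborhood)
        net <- build_network(surface, config$islands, config$neighborhood,
                             season = season$name, scenario = scenario,
                             decade = decade$label)
        cent <- area_correct(network_current_flow_centrality(net))
        land <- config$islands$labels > 0L
        land_mean <- mean(cmap$current[land])
        key <- tibble(season = season$name, scenario = scenario,
                      decade = decade$label)
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          key,
          n_connections = count_connections(net),
          n_pruned = sum(net$links$status == "pruned_intermediate"),
          n_severed = sum(net$links$status == "severed"),
          land_mean_current = land_mean
        )
        means[[length(means) + 1L]] <- dplyr::bind_cols(
          key[rep(1, nrow(cmap$island_means)), ], cmap$island_means
        )
        cents[[length(cents) + 1L]] <- dplyr::bind_cols(
          key[rep(1, nrow(cent$nodes)), ], cent$nodes
        )
        links[[length(links) + 1L]] <- dplyr::bind_cols(
          key[rep(1, nrow(net$links)), ],
          dplyr::select(net$links, "a", "b", "cwd", "status")
        )
        if (!is.null(config$out_dir)) {
          dir <- file.path(config$out_dir, season$name, scenario,
                           decade$label)
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
          write_ascii_grid(current_map_to_raster(cmap),
                           file.path(dir, "cumulative_current.asc"))
          write_table(cmap$island_means,
                      file.path(dir, "island_mean_current.csv"))
          write_table(dplyr::select(net$links, "a", "b", "cwd", "status"),
                      file.path(dir, "network.csv"))
          write_table(cent$nodes, file.path(dir, "centrality.csv"))
        }
      }
    }
  }
  summary <- dplyr::bind_rows(rows)

  # percent change of land mean current vs the baseline scenario, per season
  base <- config$baseline_scenario
  if (!is.na(base) && base %in% summary$scenario) {
    baseline <- dplyr::summarise(
      dplyr::group_by(summary[summary$scenario == base, ], .data$season),
      baseline_mean = .data$land_mean_current[1], .groups = "drop"
    )
    summary <- dplyr::left_join(summary, baseline, by = "season")
    summary$pct_change_vs_baseline <- ifelse(
      is.na(summary$baseline_mean), NA_real_,
      100 * (summary$land_mean_current - summary$baseline_mean) /
        summary$baseline_mean
    )
    summary$baseline_mean <- NULL
  } else {
    summary$pct_change_vs_baseline <- NA_real_
  }

  report <- structure(
    list(summary = summary,
         island_means = dplyr::bind_rows(means),
         centrality = dplyr::bind_rows(cents),
         links = dplyr::bind_rows(links)),
    class = "scenario_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(summary, file.path(config$out_dir, "summary.csv"))
    write_table(report$centrality, file.path(config$out_dir, "centrality.csv"))
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>\n")
  print(x$summary)
  invisible(x)
}
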