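#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the object's main per-unit
#' tibble (per island or per link), `glance()` a one-row summary.
#'
#' @param x A package result object.
#' @param ... Unused.
#' @return A tibble.
#' @name icescape-tidiers
NULL

#' @rdname icescape-tidiers
#' @method tidy current_map
#' @export
tidy.current_map <- function(x, ...) x$island_means

#' @rdname icescape-tidiers
#' @method glance current_map
#' @export
glance.current_map <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_solvable = sum(x$pairs$solvable),
    total_current = sum(x$current, na.rm = TRUE),
    max_cell_current = max(x$current, na.rm = TRUE)
  )
}

#' @rdname icescape-tidiers
#' @method tidy island_network
#' @export
tidy.island_network <- function(x, ...) {
  dplyr::select(x$links, "a", "b", "cwd", "status")
}

#' @rdname icescape-tidiers
#' @method glance island_network
#' @export
glance.island_network <- function(x, ...) {
  tibble(
    n_islands = nrow(x$nodes),
    n_active = sum(x$links$status == "active"),
    n_pruned = sum(x$links$status == "pruned_intermediate"),
    n_severed = sum(x$links$status == "severed"),
    season = x$season, scenario = x$scenario, decade = x$decade
  )
}

#' @rdname icescape-tidiers
#' @method tidy centrality_table
#' @export
tidy.centrality_table <- function(x, ...) x$nodes

#' @rdname icescape-tidiers
#' @method glance centrality_table
#' @export
glance.centrality_table <- function(x, ...) {
  tibble(
    n_islands = nrow(x$nodes),
    n_pairs_solved = x$n_pairs_solved,
    total_centrality = sum(x$nodes$centrality)
  )
}

#' @rdname icescape-tidiers
#' @method tidy pair_solve
#' @export
tidy.pair_solve <- function(x, ...) {
  dplyr::select(x$edge_currents, "from", "to", "conductance", "current")
}

#' @rdname icescape-tidiers
#' @method glance pair_solve
#' @export
glance.pair_solve <- function(x, ...) {
  tibble(source = x$source, ground = x$ground, solvable = x$solvable,
         effective_resistance = x$effective_resistance)
}

#' @rdname icescape-tidiers
#' @method tidy scenario_report
#' @export
tidy.scenario_report <- function(x, ...) x$summary

#' @rdname icescape-tidiers
#' @method glance scenario_report
#' @export
glance.scenario_report <- function(x, ...) {
  tibble(
    n_runs = nrow(x$summary),
    seasons = length(unique(x$summary$season)),
    scenarios = length(unique(x$summary$scenario))
  )
}

raster_tibble <- function(values, cell_size_km) {
  nr <- nrow(values)
  tibble(
    row = rep(seq_len(nr), ncol(values)),
    col = rep(seq_len(ncol(values)), each = nr),
    # y grows northwards; row 1 is the northern edge
    x = (rep(seq_len(ncol(values)), each = nr) - 0.5) * cell_size_km,
    y = (nr - rep(seq_len(nr), ncol(values)) + 0.5) * cell_size_km,
    value = as.vector(values)
  )
}

#' Plot methods
#'
#' `autoplot()` turns result objects into ggplot2 figures: a cumulative
#' current raster, an island network coloured by link status, a
#' centrality ranking, or the summary trajectories of a scenario report.
#'
#' @param object A package result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name icescape-plots
NULL

#' @rdname icescape-plots
#' @method autoplot current_map
#' @export
autoplot.current_map <- function(object, ...) {
  df <- raster_tibble(object$current, object$cell_size_km)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "current (A)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east", y = "km north",
                  title = "Cumulative current density")
}

#' @rdname icescape-plots
#' @method autoplot island_network
#' @export
autoplot.island_network <- function(object, ...) {
  links <- dplyr::filter(object$links, .data$status != "severed")
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(links)), function(k) {
    p <- links$path[[k]]
    if (is.null(p)) return(NULL)
    tibble(x = p[-nrow(p), 2], y = -p[-nrow(p), 1],
           xend = p[-1, 2], yend = -p[-1, 1],
           status = links$status[k])
  }))
  gg <- ggplot2::ggplot()
  if (nrow(segs)) {
    gg <- gg + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$status)
    )
  }
  gg + ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row (north up)",
                  title = "Island least-cost network")
}

#' @rdname icescape-plots
#' @method autoplot centrality_table
#' @export
autoplot.centrality_table <- function(object, ...) {
  df <- object$nodes
  df$island <- factor(df$island, levels = df$island[order(df$centrality)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centrality, y = .data$island)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "current-flow centrality (A)", y = "island")
}

#' @rdname icescape-plots
#' @method autoplot scenario_report
#' @export
autoplot.scenario_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$decade, y = .data$n_connections,
                               colour = .data$scenario,
                               group = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~season) +
    ggplot2::labs(x = "decade", y = "active connections") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
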