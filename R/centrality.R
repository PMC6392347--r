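#' Current-flow centrality on the island network
#'
#' Treats each island as a node of a small electrical network whose link
#' resistances are the cost-weighted distances of the active least-cost
#' links. For every unordered pair of islands in the same connected
#' component, one amp is injected at one island and drained at the other;
#' each terminal is credited the full 1 A, every other island the
#' through-current (half the sum of absolute incident link currents), and
#' each link the absolute current it carries. Raw centrality is the sum
#' over all pairs; pairs in different components contribute nothing.
#' Severed and pruned links do not conduct.
#'
#' @param network An `island_network` from [build_network()].
#' @param cwd_floor Links with cost-weighted distance below this floor
#'   (islands touching within one cell) conduct at `1/cwd_floor` so the
#'   island-level system stays finite.
#' @return A `centrality_table`: `nodes` tibble (`island`, `area_km2`,
#'   `centrality`, `rank_raw`), `links` tibble (`a`, `b`, `current`), and
#'   `n_pairs_solved`.
#' @export
network_current_flow_centrality <- function(network, cwd_floor = 1e-9) {
  stopifnot(inherits(network, "island_network"))
  ids <- network$nodes$island
  n <- length(ids)
  act <- network$links[network$links$status == "active", , drop = FALSE]
  cent <- setNames(numeric(n), ids)
  link_cur <- if (nrow(act)) numeric(nrow(act)) else numeric(0)
  n_pairs <- 0L

  if (n >= 2 && nrow(act) > 0) {
    ai <- match(act$a, ids); bi <- match(act$b, ids)
    g <- 1 / pmax(act$cwd, cwd_floor)
    ig <- igraph::make_empty_graph(n, directed = FALSE)
    ig <- igraph::add_edges(ig, as.vector(rbind(ai, bi)))
    memb <- igraph::components(ig)$membership
    L <- matrix(0, n, n)
    for (k in seq_along(g)) {
      L[ai[k], bi[k]] <- L[ai[k], bi[k]] - g[k]
      L[bi[k], ai[k]] <- L[bi[k], ai[k]] - g[k]
      L[ai[k], ai[k]] <- L[ai[k], ai[k]] + g[k]
      L[bi[k], bi[k]] <- L[bi[k], bi[k]] + g[k]
    }
    pairs <- utils::combn(n, 2)
    for (p in seq_len(ncol(pairs))) {
      s <- pairs[1, p]; t <- pairs[2, p]
      if (memb[s] != memb[t]) next
      n_pairs <- n_pairs + 1L
      comp <- which(memb == memb[s])
      sub <- setdiff(comp, t)
      v <- numeric(n)
      rhs <- numeric(length(sub))
      rhs[match(s, sub)] <- 1
      v[sub] <- solve(L[sub, sub, drop = FALSE], rhs)
      cur <- g * (v[ai] - v[bi])
      cur[memb[ai] != memb[s]] <- 0
      link_cur <- link_cur + abs(cur)
      through <- numeric(n)
      for (k in seq_along(cur)) {
        through[ai[k]] <- through[ai[k]] + abs(cur[k])
        through[bi[k]] <- through[bi[k]] + abs(cur[k])
      }
      node_cur <- through / 2
      node_cur[c(s, t)] <- 1
      cent <- cent + node_cur
    }
  }
  nodes <- dplyr::mutate(
    dplyr::select(network$nodes, "island", "area_km2"),
    centrality = unname(cent),
    rank_raw = rank(-.data$centrality, ties.method = "min")
  )
  structure(
    list(
      nodes = nodes,
      links = tibble(a = act$a, b = act$b, cwd = act$cwd,
                     current = link_cur),
      n_pairs_solved = n_pairs,
      season = network$season, scenario = network$scenario,
      decade = network$decade
    ),
    class = "centrality_table"
  )
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("<centrality_table> %d islands, %d pairs solved\n",
              nrow(x$nodes), x$n_pairs_solved))
  print(x$nodes)
  invisible(x)
}

#' Standardise centrality by island area
#'
#' Small islands can matter far more than their size suggests; dividing
#' raw current-flow centrality by island area (km^2) highlights them.
#' Both rank orders are (re)computed: rank 1 is the most central island.
#'
#' @param table A `centrality_table`.
#' @param areas Optional named vector (island id -> km^2) overriding the
#'   areas stored on the table; every island needs a positive area.
#' @return The table with `centrality_per_area`, `rank_raw` and
#'   `rank_area_corrected` columns on `$nodes`.
#' @export
area_correct <- function(table, areas = NULL) {
  stopifnot(inherits(table, "centrality_table"))
  nodes <- table$nodes
  if (!is.null(areas)) {
    idx <- match(as.character(nodes$island), names(areas))
    if (anyNA(idx)) {
      abort(sprintf("No area supplied for island(s): %s",
                    paste(nodes$island[is.na(idx)], collapse = ", ")))
    }
    nodes$area_km2 <- as.numeric(areas[idx])
  }
  if (any(!is.finite(nodes$area_km2) | nodes$area_km2 <= 0)) {
    abort("Every island needs a positive, finite area.")
  }
  nodes$centrality_per_area <- nodes$centrality / nodes$area_km2
  nodes$rank_raw <- rank(-nodes$centrality, ties.method = "min")
  nodes$rank_area_corrected <- rank(-nodes$centrality_per_area,
                                    ties.method = "min")
  table$nodes <- nodes
  table
}
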