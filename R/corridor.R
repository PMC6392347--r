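#' Cost-weighted distance from an island
#'
#' Multi-source shortest-path (Dijkstra) cost from every cell of the
#' source island to every passable cell, with step costs identical to the
#' circuit module's edge resistances (mean of the two cell resistances,
#' `sqrt(2)` scaling on diagonals). Source-island cells have cost 0;
#' unreachable and impassable cells are `+Inf`.
#'
#' @param surface A `resistance_surface`.
#' @param islands The aligned [island_grid()].
#' @param source Island id.
#' @param neighborhood 4 or 8.
#' @param graph Optionally a prebuilt [build_graph()] result.
#' @return A numeric matrix of accumulated costs (same shape as the grid).
#' @export
cost_distance <- function(surface, islands, source, neighborhood = 8,
                          graph = NULL) {
  stopifnot(is_resistance_surface(surface), is_island_grid(islands))
  if (!source %in% islands$island_ids) {
    abort(sprintf("Island %d absent from the label grid.", source))
  }
  graph <- graph %||% build_graph(surface, neighborhood)
  field <- cost_field(graph, islands, source)
  out <- matrix(Inf, surface$n_rows, surface$n_cols)
  out[graph$nodes$cell] <- field
  out
}

# igraph view of a conductance graph, weighted by edge resistance.
as_igraph <- function(graph) {
  ig <- igraph::make_empty_graph(nrow(graph$nodes), directed = FALSE)
  if (nrow(graph$edges)) {
    ig <- igraph::add_edges(
      ig, as.vector(rbind(graph$edges$from, graph$edges$to)),
      weight = graph$edges$resistance
    )
  }
  ig
}

# Per-node least cost from any cell of `source`; vector over graph nodes.
cost_field <- function(graph, islands, source, ig = NULL) {
  ig <- ig %||% as_igraph(graph)
  src_nodes <- graph$nodes$node[islands$labels[graph$nodes$cell] == source]
  d <- igraph::distances(ig, v = src_nodes, weights = NULL,
                         algorithm = "dijkstra")
  if (nrow(d) == 1) d[1, ] else do.call(pmin, asplit(d, 1))
}

# Lexicographically-first pair of touching cells between two islands, or
# NULL. Touching = within the neighbourhood stencil.
adjacent_cells <- function(islands, a, b, neighborhood) {
  lab <- islands$labels
  nr <- nrow(lab); nc <- ncol(lab)
  a_cells <- which(lab == a)
  a_rc <- cbind((a_cells - 1L) %% nr + 1L, (a_cells - 1L) %/% nr + 1L)
  ord <- order(a_rc[, 1], a_rc[, 2])
  offs <- neighbor_offsets(neighborhood)
  for (k in ord) {
    r <- a_rc[k, 1]; c <- a_rc[k, 2]
    hits <- NULL
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (lab[rr, cc] == b) hits <- rbind(hits, c(rr, cc))
    }
    if (!is.null(hits)) {
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      return(rbind(c(r, c), hits[1, ]))
    }
  }
  NULL
}

neighbor_offsets <- function(neighborhood) {
  offs <- list(c(-1L, 0L), c(0L, -1L), c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) {
    offs <- c(list(c(-1L, -1L), c(-1L, 1L)), offs, list(c(1L, -1L), c(1L, 1L)))
  }
  offs
}

# Greedy downhill walk on the cost-to-target field from the cheapest
# source cell; at ties picks the smallest (row, col). Returns a 2-column
# (row, col) matrix ending on the target island.
trace_path <- function(graph, islands, a, b, d_to_b, neighborhood) {
  lab <- islands$labels
  nr <- graph$n_rows; nc <- graph$n_cols
  res <- matrix(Inf, nr, nc)
  res[graph$nodes$cell] <- graph$nodes$resistance
  dmat <- matrix(Inf, nr, nc)
  dmat[graph$nodes$cell] <- d_to_b

  a_cells <- which(lab == a)
  a_rc <- cbind((a_cells - 1L) %% nr + 1L, (a_cells - 1L) %/% nr + 1L)
  best <- min(dmat[a_cells])
  cand <- which(dmat[a_cells] <= best + 1e-12 * max(1, best))
  cand <- cand[order(a_rc[cand, 1], a_rc[cand, 2])]
  cur <- a_rc[cand[1], ]
  path <- matrix(cur, 1, 2)
  offs <- neighbor_offsets(neighborhood)
  max_steps <- nr * nc + 1L
  for (step in seq_len(max_steps)) {
    if (lab[cur[1], cur[2]] == b) break
    d_cur <- dmat[cur[1], cur[2]]
    nxt <- NULL
    for (o in offs) {
      rr <- cur[1] + o[1]; cc <- cur[2] + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!is.finite(res[rr, cc])) next
      w <- (res[cur[1], cur[2]] + res[rr, cc]) / 2 *
        (if (all(o != 0L)) sqrt(2) else 1)
      if (abs(d_cur - (w + dmat[rr, cc])) <= 1e-8 * max(1, d_cur)) {
        if (is.null(nxt) || rr < nxt[1] || (rr == nxt[1] && cc < nxt[2])) {
          nxt <- c(rr, cc)
        }
      }
    }
    if (is.null(nxt)) {
      abort("Path trace failed to step downhill; inconsistent cost field.")
    }
    cur <- nxt
    path <- rbind(path, cur)
  }
  dimnames(path) <- list(NULL, c("row", "col"))
  path
}

link_status <- function(path, islands, a, b) {
  if (is.null(path)) return("severed")
  labs <- islands$labels[cbind(path[, 1], path[, 2])]
  interior <- labs[labs != a & labs != b]
  if (any(interior > 0L)) "pruned_intermediate" else "active"
}

#' Least-cost path between two islands
#'
#' The minimum cost-weighted-distance route between any cell of island
#' `a` and any cell of island `b`, with a deterministic tie-break (the
#' greedy walk picks the smallest `(row, col)` neighbour among optimal
#' steps). Islands touching within one cell get an active zero-cost link.
#' A link whose path interior crosses a third island is flagged
#' `pruned_intermediate` (the islands are not adjacent core areas); a
#' pair with no finite-cost route is `severed`.
#'
#' @inheritParams cost_distance
#' @param a,b Island ids.
#' @param d_to_b Optionally a precomputed [cost_field()] vector for `b`.
#' @return An `island_link`: list with `a`, `b`, `cwd`, `status`
#'   (`active`, `pruned_intermediate` or `severed`) and `path`
#'   (a (row, col) matrix, or `NULL` when severed).
#' @export
least_cost_path <- function(surface, islands, a, b, neighborhood = 8,
                            graph = NULL, d_to_b = NULL) {
  stopifnot(a != b)
  graph <- graph %||% build_graph(surface, neighborhood)
  adj <- adjacent_cells(islands, a, b, neighborhood)
  if (!is.null(adj)) {
    dimnames(adj) <- list(NULL, c("row", "col"))
    return(structure(list(a = a, b = b, cwd = 0, status = "active",
                          path = adj), class = "island_link"))
  }
  d_to_b <- d_to_b %||% cost_field(graph, islands, b)
  a_nodes <- graph$nodes$node[islands$labels[graph$nodes$cell] == a]
  cwd <- min(d_to_b[a_nodes])
  if (!is.finite(cwd)) {
    return(structure(list(a = a, b = b, cwd = Inf, status = "severed",
                          path = NULL), class = "island_link"))
  }
  path <- trace_path(graph, islands, a, b, d_to_b, neighborhood)
  structure(list(a = a, b = b, cwd = cwd,
                 status = link_status(path, islands, a, b), path = path),
            class = "island_link")
}

#' @export
print.island_link <- function(x, ...) {
  cat(sprintf("<island_link> %d - %d: %s, cwd = %s\n", x$a, x$b, x$status,
              format(x$cwd, digits = 6)))
  invisible(x)
}

#' Build the island network
#'
#' Least-cost links for every unordered island pair. Links intercepted by
#' an intermediate island are retained with status `pruned_intermediate`,
#' severed pairs with `severed`; only `active` links count as
#' connections.
#'
#' @inheritParams cost_distance
#' @param season,scenario,decade Optional labels carried on the network.
#' @return An `island_network`: `nodes` (tibble `island`, `n_cells`,
#'   `area_km2`), `links` (tibble `a`, `b`, `cwd`, `status`, `path`
#'   list-column), and the labels.
#' @export
build_network <- function(surface, islands, neighborhood = 8,
                          season = NA_character_, scenario = NA_character_,
                          decade = NA_character_) {
  stopifnot(is_resistance_surface(surface), is_island_grid(islands))
  ids <- islands$island_ids
  if (length(ids) < 2) abort("Need at least two islands.")
  graph <- build_graph(surface, neighborhood)
  ig <- as_igraph(graph)
  fields <- lapply(setNames(ids, ids), function(id) {
    cost_field(graph, islands, id, ig = ig)
  })
  pairs <- utils::combn(ids, 2)
  links <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    least_cost_path(surface, islands, a, b, neighborhood,
                    graph = graph, d_to_b = fields[[as.character(b)]])
  })
  structure(
    list(
      nodes = island_areas(islands),
      links = tibble(
        a = pairs[1, ], b = pairs[2, ],
        cwd = vapply(links, `[[`, numeric(1), "cwd"),
        status = vapply(links, `[[`, character(1), "status"),
        path = lapply(links, `[[`, "path")
      ),
      season = season, scenario = scenario, decade = decade,
      neighborhood = neighborhood
    ),
    class = "island_network"
  )
}

#' @export
print.island_network <- function(x, ...) {
  cat(sprintf(
    "<island_network> %d islands; %d active, %d pruned, %d severed links\n",
    nrow(x$nodes), sum(x$links$status == "active"),
    sum(x$links$status == "pruned_intermediate"),
    sum(x$links$status == "severed")
  ))
  invisible(x)
}

#' Count surviving island connections
#'
#' The number of active links in the network (the quantity tracked across
#' decades to measure connectivity loss).
#'
#' @param network An `island_network`.
#' @return Integer count.
#' @export
count_connections <- function(network) {
  stopifnot(inherits(network, "island_network"))
  sum(network$links$status == "active")
}
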