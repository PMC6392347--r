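#' Build the conductance graph of a resistance surface
#'
#' Every passable cell (finite resistance) becomes a node; orthogonal
#' (and, with the 8-cell neighbourhood, diagonal) pairs of passable cells
#' become undirected edges. The resistance of the edge between cells i
#' and j is the arithmetic mean of the two cell resistances, scaled by
#' `sqrt(2)` for diagonal neighbours; conductance is its reciprocal. This
#' is the standard raster-to-network convention of circuit-theoretic
#' connectivity tools, and the corridor module reuses exactly these edge
#' weights so least-cost and circuit results live on the same graph.
#'
#' @param surface A `resistance_surface` (see [combine_surfaces()]).
#' @param neighborhood 4 or 8 (default 8).
#' @return A `conductance_graph` with tibbles `nodes`
#'   (`node`, `row`, `col`, `island`, `resistance`) and `edges`
#'   (`from`, `to`, `resistance`, `conductance`), plus grid geometry.
#' @export
build_graph <- function(surface, neighborhood = 8) {
  stopifnot(is_resistance_surface(surface))
  if (!neighborhood %in% c(4, 8)) abort("`neighborhood` must be 4 or 8.")
  nr <- surface$n_rows; nc <- surface$n_cols
  res <- surface$resistance
  passable <- is.finite(res) & !is.na(res)
  if (!any(passable)) abort("Resistance surface has no passable cells.")
  node_of_cell <- rep(NA_integer_, nr * nc)
  cells <- which(passable)                    # column-major linear indices
  node_of_cell[cells] <- seq_along(cells)
  rows <- (cells - 1L) %% nr + 1L
  cols <- (cells - 1L) %/% nr + 1L

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    cell2 <- r2[ok] + (c2[ok] - 1L) * nr
    n1 <- node_of_cell[cells[ok]]
    n2 <- node_of_cell[cell2]
    live <- !is.na(n2)
    scale <- if (all(off != 0L)) sqrt(2) else 1
    er <- (res[cells[ok]][live] + res[cell2[live]]) / 2 * scale
    from <- c(from, n1[live]); to <- c(to, n2[live]); w <- c(w, er)
  }
  nodes <- tibble(
    node = seq_along(cells), row = rows, col = cols, cell = cells,
    island = 0L, resistance = res[cells]
  )
  lo <- pmin(from, to); hi <- pmax(from, to)
  structure(
    list(
      nodes = nodes,
      edges = tibble(from = lo, to = hi, resistance = w, conductance = 1 / w),
      node_of_cell = node_of_cell,
      n_rows = nr, n_cols = nc, neighborhood = neighborhood,
      cell_size_km = surface$cell_size_km
    ),
    class = "conductance_graph"
  )
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("<conductance_graph> %d nodes, %d edges (%d-neighbourhood)\n",
              nrow(x$nodes), nrow(x$edges), x$neighborhood))
  invisible(x)
}

#' Contract the focal islands into zero-resistance supernodes
#'
#' For a pairwise solve the two focal islands are treated as homogeneous
#' zero-resistance regions: all of an island's cells merge into one
#' supernode, edges internal to the island vanish, and parallel edges
#' from the supernode to a common neighbour merge by summing
#' conductances. Every other island keeps its per-cell land resistances.
#'
#' @param graph A `conductance_graph` from [build_graph()].
#' @param islands The [island_grid()] aligned with the surface.
#' @param focal Integer pair of island ids to contract.
#' @return A `contracted_graph`: edge tibble over group ids, the
#'   node-to-group map, the two focal group ids and the member cells of
#'   each focal supernode.
#' @export
contract_islands <- function(graph, islands, focal) {
  stopifnot(inherits(graph, "conductance_graph"), is_island_grid(islands),
            length(focal) == 2)
  if (!all(focal %in% islands$island_ids)) {
    abort(sprintf("Focal island id(s) %s absent from the label grid.",
                  paste(setdiff(focal, islands$island_ids), collapse = ", ")))
  }
  lab_of_node <- islands$labels[graph$nodes$cell]
  n <- nrow(graph$nodes)
  grp <- seq_len(n)
  grp[lab_of_node == focal[1]] <- n + 1L
  grp[lab_of_node == focal[2]] <- n + 2L
  grp <- as.integer(factor(grp, levels = unique(grp[order(grp)])))
  source_group <- grp[which(lab_of_node == focal[1])[1]]
  ground_group <- grp[which(lab_of_node == focal[2])[1]]

  gi <- grp[graph$edges$from]; gj <- grp[graph$edges$to]
  keep <- gi != gj
  a <- pmin(gi[keep], gj[keep]); b <- pmax(gi[keep], gj[keep])
  g <- graph$edges$conductance[keep]
  key <- paste(a, b)
  agg <- rowsum(g, key, reorder = FALSE)
  pair <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  edges <- tibble(
    from = as.integer(pair[, 1]), to = as.integer(pair[, 2]),
    conductance = as.numeric(agg[, 1])
  )
  structure(
    list(
      edges = edges,
      n_groups = max(grp),
      group_of_node = grp,
      source_group = source_group,
      ground_group = ground_group,
      focal = as.integer(focal),
      member_cells = list(
        source = graph$nodes$cell[lab_of_node == focal[1]],
        ground = graph$nodes$cell[lab_of_node == focal[2]]
      )
    ),
    class = "contracted_graph"
  )
}

# Sparse graph Laplacian from an edge tibble over 1..n nodes.
graph_laplacian <- function(edges, n) {
  L <- sparseMatrix(
    i = c(edges$from, edges$to),
    j = c(edges$to, edges$from),
    x = c(-edges$conductance, -edges$conductance),
    dims = c(n, n)
  )
  deg <- -Matrix::rowSums(L)
  L + Diagonal(n, deg)
}

#' Solve one island pair's current flow
#'
#' Injects one amp into the source island's supernode and grounds the
#' other island, with the focal pair contracted to zero resistance and
#' all other cells keeping their assigned resistances. Node potentials
#' solve the graph Laplacian system; edge current is conductance times
#' potential difference. Per-cell current magnitude is half the sum of
#' the absolute incident edge currents (so a unit of through-current is
#' counted once), and each focal island's full 1 A is spread uniformly
#' over its member cells for mapping. If source and ground are in
#' different components the pair is reported unsolvable (zero current
#' everywhere), not an error: severed connectivity is a result.
#'
#' @param graph A `conductance_graph`.
#' @param islands The aligned [island_grid()].
#' @param source,ground Island ids (source receives 1 A).
#' @return A `pair_solve`: `solvable`, `effective_resistance` (ohms; `Inf`
#'   when unsolvable), `current` (per-cell matrix, `NA` at impassable
#'   cells), `potential` (per-cell matrix, volts, ground island at 0),
#'   and `edge_currents` (tibble on the contracted graph).
#' @export
solve_pair <- function(graph, islands, source, ground) {
  stopifnot(inherits(graph, "conductance_graph"))
  if (source == ground) abort("`source` and `ground` must differ.")
  con <- contract_islands(graph, islands, c(source, ground))
  n <- con$n_groups
  current <- matrix(NA_real_, graph$n_rows, graph$n_cols)
  current[graph$nodes$cell] <- 0
  potential <- matrix(NA_real_, graph$n_rows, graph$n_cols)

  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(con$edges)) {
    ig <- igraph::add_edges(ig, as.vector(rbind(con$edges$from, con$edges$to)))
  }
  comp <- igraph::components(ig)
  same <- comp$membership[con$source_group] == comp$membership[con$ground_group]
  if (!same) {
    return(structure(
      list(source = source, ground = ground, solvable = FALSE,
           effective_resistance = Inf, current = current,
           potential = potential,
           edge_currents = dplyr::mutate(con$edges, current = 0),
           contracted = con),
      class = "pair_solve"
    ))
  }
  in_comp <- which(comp$membership == comp$membership[con$source_group])
  sub <- con$edges[con$edges$from %in% in_comp & con$edges$to %in% in_comp, ]
  # relabel component nodes 1..m
  pos <- match(seq_len(n), in_comp)
  m <- length(in_comp)
  L <- graph_laplacian(
    tibble(from = pos[sub$from], to = pos[sub$to],
           conductance = sub$conductance),
    m
  )
  src <- pos[con$source_group]; gnd <- pos[con$ground_group]
  keep <- setdiff(seq_len(m), gnd)
  rhs <- numeric(m - 1)
  rhs[match(src, keep)] <- 1
  v_red <- as.numeric(Matrix::solve(
    Matrix::forceSymmetric(L[keep, keep, drop = FALSE]), rhs
  ))
  v <- numeric(m)
  v[keep] <- v_red
  v[gnd] <- 0

  edge_cur <- numeric(nrow(con$edges))
  inside <- con$edges$from %in% in_comp & con$edges$to %in% in_comp
  edge_cur[inside] <- con$edges$conductance[inside] *
    (v[pos[con$edges$from[inside]]] - v[pos[con$edges$to[inside]]])

  # accumulate |current| at each group endpoint
  acc <- numeric(n)
  abs_cur <- abs(edge_cur)
  acc_from <- rowsum(abs_cur, con$edges$from, reorder = FALSE)
  acc[as.integer(rownames(acc_from))] <- acc[as.integer(rownames(acc_from))] + acc_from[, 1]
  acc_to <- rowsum(abs_cur, con$edges$to, reorder = FALSE)
  acc[as.integer(rownames(acc_to))] <- acc[as.integer(rownames(acc_to))] + acc_to[, 1]

  grp <- con$group_of_node
  ordinary <- !(grp %in% c(con$source_group, con$ground_group))
  cells <- graph$nodes$cell
  current[cells[ordinary]] <- acc[grp[ordinary]] / 2
  current[con$member_cells$source] <- 1 / length(con$member_cells$source)
  current[con$member_cells$ground] <- 1 / length(con$member_cells$ground)

  vfull <- rep(NA_real_, n)
  vfull[in_comp] <- v
  potential[cells] <- vfull[grp]

  structure(
    list(source = source, ground = ground, solvable = TRUE,
         effective_resistance = v[src],
         current = current, potential = potential,
         edge_currents = dplyr::mutate(con$edges, current = edge_cur),
         contracted = con),
    class = "pair_solve"
  )
}

#' @export
print.pair_solve <- function(x, ...) {
  cat(sprintf("<pair_solve> %d -> %d: %s, R_eff = %s ohm\n",
              x$source, x$ground,
              if (x$solvable) "solved" else "unsolvable",
              format(x$effective_resistance, digits = 6)))
  invisible(x)
}

#' Cumulative current over all island pairs
#'
#' Solves every unordered pair of islands once and sums the per-cell
#' current magnitudes into one cumulative current map, the circuit-theory
#' picture of where between-island movement concentrates. Unsolvable
#' (disconnected) pairs contribute zero. The per-island mean is the mean
#' cumulative current over the island's cells.
#'
#' @param surface A `resistance_surface`.
#' @param islands The aligned [island_grid()] (>= 2 islands).
#' @param neighborhood 4 or 8.
#' @return A `current_map`: `current` (matrix; `NA` at impassable cells),
#'   `island_means` (tibble `island`, `mean_current`), `pairs` (tibble
#'   `a`, `b`, `effective_resistance`, `solvable`), grid geometry.
#' @export
cumulative_current <- function(surface, islands, neighborhood = 8) {
  stopifnot(is_resistance_surface(surface), is_island_grid(islands))
  ids <- islands$island_ids
  if (length(ids) < 2) abort("Need at least two islands.")
  graph <- build_graph(surface, neighborhood)
  total <- matrix(NA_real_, surface$n_rows, surface$n_cols)
  total[graph$nodes$cell] <- 0
  pairs <- utils::combn(ids, 2)
  recs <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ps <- solve_pair(graph, islands, pairs[1, k], pairs[2, k])
    if (ps$solvable) {
      total[graph$nodes$cell] <- total[graph$nodes$cell] +
        ps$current[graph$nodes$cell]
    }
    recs[[k]] <- tibble(a = pairs[1, k], b = pairs[2, k],
                        effective_resistance = ps$effective_resistance,
                        solvable = ps$solvable)
  }
  means <- vapply(ids, function(id) {
    mean(total[islands$labels == id])
  }, numeric(1))
  structure(
    list(
      current = total,
      island_means = tibble(island = ids, mean_current = means),
      pairs = dplyr::bind_rows(recs),
      n_rows = surface$n_rows, n_cols = surface$n_cols,
      cell_size_km = surface$cell_size_km, origin = surface$origin
    ),
    class = "current_map"
  )
}

#' @export
print.current_map <- function(x, ...) {
  cat(sprintf("<current_map> %d x %d cells, %d/%d pairs solvable\n",
              x$n_rows, x$n_cols, sum(x$pairs$solvable), nrow(x$pairs)))
  invisible(x)
}

#' Convert a current map to a raster grid
#'
#' @param cmap A `current_map`.
#' @return A [raster_grid()] (impassable cells nodata).
#' @export
current_map_to_raster <- function(cmap) {
  stopifnot(inherits(cmap, "current_map"))
  raster_grid(cmap$current, cell_size_km = cmap$cell_size_km,
              origin = cmap$origin)
}
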