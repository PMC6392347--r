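# Independent oracles, deliberately written with plain loops and dense
# linear algebra so they share no code with the package implementation.

oracle_offsets <- function(neighborhood) {
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  offs
}

# Dense Laplacian-pseudoinverse solve of a pairwise current-flow problem.
# res: resistance matrix (Inf = impassable); labels: island labels.
# Returns effective resistance and a per-cell current matrix under the
# same mapping convention as the package (half-sum at interior cells,
# 1 A spread over focal-island cells).
oracle_solve <- function(res, labels, source, ground, neighborhood = 4) {
  nr <- nrow(res); nc <- ncol(res)
  pass <- which(is.finite(res))
  grps <- character(length(pass))
  for (k in seq_along(pass)) {
    lab <- labels[pass[k]]
    grps[k] <- if (lab == source) "S" else if (lab == ground) "G"
    else as.character(pass[k])
  }
  ug <- unique(grps)
  n <- length(ug)
  gidx <- match(grps, ug)
  L <- matrix(0, n, n)
  ef <- integer(0); et <- integer(0); eg <- numeric(0)
  for (k in seq_along(pass)) {
    cell <- pass[k]
    r <- (cell - 1L) %% nr + 1L; c <- (cell - 1L) %/% nr + 1L
    for (o in oracle_offsets(neighborhood)) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      cell2 <- rr + (cc - 1L) * nr
      if (!is.finite(res[cell2])) next
      k2 <- match(cell2, pass)
      w <- (res[cell] + res[cell2]) / 2 * (if (all(o != 0L)) sqrt(2) else 1)
      g1 <- gidx[k]; g2 <- gidx[k2]
      if (g1 == g2) next
      L[g1, g2] <- L[g1, g2] - 1 / w
      L[g2, g1] <- L[g2, g1] - 1 / w
      L[g1, g1] <- L[g1, g1] + 1 / w
      L[g2, g2] <- L[g2, g2] + 1 / w
      ef <- c(ef, g1); et <- c(et, g2); eg <- c(eg, 1 / w)
    }
  }
  s <- match("S", ug); t <- match("G", ug)
  # reachability by breadth-first search over groups
  adj <- abs(L) > 0; diag(adj) <- FALSE
  seen <- rep(FALSE, n); seen[s] <- TRUE; frontier <- s
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  current <- matrix(NA_real_, nr, nc)
  current[pass] <- 0
  if (!seen[t]) {
    return(list(solvable = FALSE, effective_resistance = Inf,
                current = current))
  }
  e <- numeric(n); e[s] <- 1; e[t] <- -1
  v <- as.numeric(MASS::ginv(L) %*% e)
  acc <- numeric(n)
  link_cur <- eg * (v[ef] - v[et])
  for (k in seq_along(link_cur)) {
    acc[ef[k]] <- acc[ef[k]] + abs(link_cur[k])
    acc[et[k]] <- acc[et[k]] + abs(link_cur[k])
  }
  for (k in seq_along(pass)) {
    g <- gidx[k]
    current[pass[k]] <- if (grps[k] == "S") 1 / sum(labels[pass] == source)
    else if (grps[k] == "G") 1 / sum(labels[pass] == ground)
    else acc[g] / 2
  }
  list(solvable = TRUE, effective_resistance = v[s] - v[t],
       current = current)
}

# Exhaustive least-cost search: depth-first enumeration of simple paths
# from any `a` cell to any `b` cell with branch-and-bound pruning (exact,
# since all step costs are positive).
oracle_lcp <- function(res, labels, a, b, neighborhood = 4) {
  nr <- nrow(res); nc <- ncol(res)
  best <- Inf
  offs <- oracle_offsets(neighborhood)
  offs <- c(offs, lapply(offs, function(o) -o))
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, cost) {
    if (cost >= best) return(invisible())
    if (labels[r, c] == b) {
      best <<- cost
      return(invisible())
    }
    visited[r, c] <<- TRUE
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (visited[rr, cc] || !is.finite(res[rr, cc])) next
      w <- (res[r, c] + res[rr, cc]) / 2 * (if (all(o != 0L)) sqrt(2) else 1)
      dfs(rr, cc, cost + w)
    }
    visited[r, c] <<- FALSE
    invisible()
  }
  starts <- which(labels == a)
  for (cell in starts) {
    dfs((cell - 1L) %% nr + 1L, (cell - 1L) %/% nr + 1L, 0)
  }
  best
}

# Independent all-pairs shortest path by Floyd-Warshall on the dense
# step-cost matrix over passable cells.
oracle_floyd_warshall <- function(res, neighborhood = 4) {
  nr <- nrow(res); nc <- ncol(res)
  pass <- which(is.finite(res))
  n <- length(pass)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_along(pass)) {
    cell <- pass[k]
    r <- (cell - 1L) %% nr + 1L; c <- (cell - 1L) %/% nr + 1L
    for (o in oracle_offsets(neighborhood)) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      cell2 <- rr + (cc - 1L) * nr
      if (!is.finite(res[cell2])) next
      k2 <- match(cell2, pass)
      w <- (res[cell] + res[cell2]) / 2 * (if (all(o != 0L)) sqrt(2) else 1)
      D[k, k2] <- min(D[k, k2], w); D[k2, k] <- D[k, k2]
    }
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  list(pass = pass, D = D)
}

# Path-counting centrality oracle for tree-shaped island networks:
# every pair's unit current follows the unique path, so a node's
# through-current is the number of pairs whose path strictly contains it
# and each terminal credit is 1 per incident pair.
oracle_tree_centrality <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$a[k], nodes); j <- match(edges$b[k], nodes)
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  tree_path <- function(s, t) {
    parent <- rep(NA_integer_, n)
    queue <- s; seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (!seen[nb]) {
          seen[nb] <- TRUE; parent[nb] <- cur; queue <- c(queue, nb)
        }
      }
    }
    if (!seen[t]) return(NULL)
    path <- t
    while (path[1] != s) path <- c(parent[path[1]], path)
    path
  }
  cent <- setNames(numeric(n), nodes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- tree_path(i, j)
    if (is.null(p)) next
    cent[c(i, j)] <- cent[c(i, j)] + 1
    interior <- setdiff(p, c(i, j))
    cent[interior] <- cent[interior] + 1
  }
  cent
}

# Random passable resistance grid with two single-cell islands in
# opposite corners; used by the randomized solver checks.
random_two_island_case <- function(seed, max_dim = 8, neighborhood = 4) {
  set.seed(seed)
  nr <- sample(2:max_dim, 1); nc <- sample(2:max_dim, 1)
  res <- matrix(round(runif(nr * nc, 1, 50), 2), nr, nc)
  # sprinkle impassable sea cells away from the corners
  n_block <- sample(0:floor(nr * nc / 5), 1)
  if (n_block > 0) {
    cand <- setdiff(seq_len(nr * nc), c(1L, nr * nc))
    res[sample(cand, n_block)] <- Inf
  }
  labels <- matrix(0L, nr, nc)
  labels[1, 1] <- 1L; labels[nr, nc] <- 2L
  res[1, 1] <- round(runif(1, 1, 8), 2); res[nr, nc] <- round(runif(1, 1, 8), 2)
  list(res = res, labels = labels, neighborhood = neighborhood)
}

# Fixture: two 1-cell islands joined by a 1x3 sea strip (1x5 grid).
strip_fixture <- function(sea_res = 20) {
  res <- matrix(c(2, sea_res, sea_res, sea_res, 3), 1, 5)
  labels <- matrix(c(1L, 0L, 0L, 0L, 2L), 1, 5)
  resistance_surface_from_matrix(res, labels)
}

# Fixture: three collinear 1-cell islands on a uniform 1x7 sea strip.
collinear_fixture <- function(sea_res = 20, land_res = 2) {
  res <- matrix(sea_res, 1, 7)
  labels <- matrix(0L, 1, 7)
  labels[1, c(1, 4, 7)] <- c(1L, 2L, 3L)
  res[1, c(1, 4, 7)] <- land_res
  resistance_surface_from_matrix(res, labels)
}
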