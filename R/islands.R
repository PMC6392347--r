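#' Island label grids
#'
#' An `island_grid` assigns each cell of the analysis lattice to sea
#' (label 0) or to one island (label k >= 1). Island areas follow from
#' the cell count and the cell size. Each island must form a single
#' 8-connected component; the constructor verifies this so that the
#' circuit and corridor stages can treat labels as core areas.
#'
#' @param labels Integer matrix, row 1 = north; 0 = sea, k >= 1 = island id.
#' @param cell_size_km Cell edge length in kilometres.
#' @param origin Projected (x, y) of the lower-left corner, km.
#' @param check Verify the one-component-per-island invariant
#'   (default TRUE).
#' @return An `island_grid` with fields `labels`, `island_ids`,
#'   `island_areas` (km^2, named by id), and the shared grid geometry.
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[4, 4] <- 2L
#' ig <- island_grid(m, cell_size_km = 25)
#' ig$island_areas
#' @export
island_grid <- function(labels, cell_size_km = 25, origin = c(0, 0),
                        check = TRUE) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    abort("`labels` must be an integer matrix.")
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    abort("Labels must be nonnegative integers (0 = sea).")
  }
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0]))
  if (check) {
    for (id in ids) {
      if (n_components_8(labels == id) != 1L) {
        abort(sprintf("Island %d is not a single 8-connected component.", id))
      }
    }
  }
  areas <- vapply(ids, function(id) sum(labels == id) * cell_size_km^2,
                  numeric(1))
  structure(
    list(
      labels = labels,
      n_rows = nrow(labels),
      n_cols = ncol(labels),
      cell_size_km = as.numeric(cell_size_km),
      origin = as.numeric(origin),
      island_ids = ids,
      island_areas = setNames(areas, ids)
    ),
    class = "island_grid"
  )
}

#' @export
print.island_grid <- function(x, ...) {
  cat(sprintf("<island_grid> %d x %d cells, %d islands (%.0f-%.0f km^2)\n",
              x$n_rows, x$n_cols, length(x$island_ids),
              if (length(x$island_ids)) min(x$island_areas) else NA,
              if (length(x$island_ids)) max(x$island_areas) else NA))
  invisible(x)
}

is_island_grid <- function(x) inherits(x, "island_grid")

# Number of 8-connected components of a logical mask (flood fill).
n_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        lin <- rr + (cc - 1L) * nr
        if (mask[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
  }
  comps
}

#' Island areas as a tibble
#'
#' @param islands An [island_grid()].
#' @return A tibble with columns `island`, `n_cells`, `area_km2`.
#' @export
island_areas <- function(islands) {
  stopifnot(is_island_grid(islands))
  tibble(
    island = islands$island_ids,
    n_cells = vapply(islands$island_ids,
                     function(id) sum(islands$labels == id), integer(1)),
    area_km2 = unname(islands$island_areas)
  )
}
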