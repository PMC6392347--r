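#' Raster grids on the analysis lattice
#'
#' A `raster_grid` is the package's minimal raster container: a numeric
#' matrix of cell values in geographic order (row 1 is the northernmost
#' row, column 1 the westernmost column) together with the cell size in
#' kilometres, the nodata sentinel used on disk, and the projected
#' coordinates (km) of the lower-left corner. Nodata cells are held as
#' `NA` in memory so every statistic excludes them automatically; the
#' sentinel only appears in files.
#'
#' All grids entering a joint computation must share shape, cell size and
#' origin; [check_alignment()] enforces this and nothing in the package
#' ever resamples silently.
#'
#' @param values Numeric matrix, row 1 = north.
#' @param cell_size_km Positive cell edge length in kilometres (default 25,
#'   the resolution of regional sea-ice model output).
#' @param nodata_value Sentinel written to disk for `NA` cells.
#' @param origin Numeric length-2: projected (x, y) of the lower-left
#'   corner, in kilometres.
#' @return A `raster_grid` object.
#' @examples
#' g <- raster_grid(matrix(1:6, nrow = 2, byrow = TRUE))
#' dim(g$values)
#' @export
raster_grid <- function(values, cell_size_km = 25, nodata_value = -9999,
                        origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    abort("`cell_size_km` must be a single positive number.")
  }
  if (length(origin) != 2 || !is.numeric(origin)) {
    abort("`origin` must be numeric (x, y).")
  }
  structure(
    list(
      values = values,
      n_rows = nrow(values),
      n_cols = ncol(values),
      cell_size_km = as.numeric(cell_size_km),
      nodata_value = as.numeric(nodata_value),
      origin = as.numeric(origin)
    ),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells, %.3g km cells, %d nodata\n",
    x$n_rows, x$n_cols, x$cell_size_km, sum(is.na(x$values))
  ))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Check that rasters share a grid geometry
#'
#' Any two rasters entering the same computation must agree in shape,
#' cell size and origin. Disagreement is an error, never a silent
#' resample.
#'
#' @param ... Two or more `raster_grid` / `island_grid` objects.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_alignment <- function(...) {
  grids <- list(...)
  if (length(grids) < 2) return(invisible(TRUE))
  ref <- grids[[1]]
  for (g in grids[-1]) {
    same <- g$n_rows == ref$n_rows && g$n_cols == ref$n_cols &&
      isTRUE(all.equal(g$cell_size_km, ref$cell_size_km)) &&
      isTRUE(all.equal(g$origin, ref$origin))
    if (!same) {
      abort(sprintf(
        paste0("Grids are not aligned: %dx%d @%g km origin (%g, %g) vs ",
               "%dx%d @%g km origin (%g, %g)."),
        ref$n_rows, ref$n_cols, ref$cell_size_km, ref$origin[1], ref$origin[2],
        g$n_rows, g$n_cols, g$cell_size_km, g$origin[1], g$origin[2]
      ))
    }
  }
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line ESRI ASCII header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' whitespace-separated cell values, top (northern) row first. Header
#' lengths are in projected metres and are converted to kilometres;
#' nodata cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- list()
  i <- 1
  while (i <= length(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(toks[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "cellsize", "nodata_value")) {
      break
    }
    if (length(toks) != 2 || is.na(suppressWarnings(as.numeric(toks[2])))) {
      abort(sprintf("Malformed ASCII grid header line: '%s'", lines[i]))
    }
    header[[key]] <- as.numeric(toks[2])
    i <- i + 1
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(header[[req]])) {
      abort(sprintf("ASCII grid header is missing '%s'.", req))
    }
  }
  nodata <- header[["nodata_value"]] %||% -9999
  n_rows <- as.integer(header$nrows)
  n_cols <- as.integer(header$ncols)
  data_lines <- lines[seq(i, length.out = length(lines) - i + 1)]
  if (length(data_lines) != n_rows) {
    abort(sprintf(
      "Expected %d data rows, found %d.", n_rows, length(data_lines)
    ))
  }
  rows <- lapply(seq_along(data_lines), function(r) {
    toks <- strsplit(trimws(data_lines[r]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) != n_cols || anyNA(vals)) {
      abort(sprintf(
        "Data row %d has %d values (expected %d) or non-numeric entries.",
        r, length(vals), n_cols
      ))
    }
    vals
  })
  values <- do.call(rbind, rows)
  values[values == nodata] <- NA_real_
  raster_grid(
    values,
    cell_size_km = header$cellsize / 1000,
    nodata_value = nodata,
    origin = c(header$xllcorner, header$yllcorner) / 1000
  )
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]: kilometre geometry is written back in
#' metres and `NA` cells as the grid's nodata sentinel. Values are
#' printed with enough digits that a read/write round trip reproduces
#' them.
#'
#' @param grid A [raster_grid()]. All values must be finite or `NA`.
#' @param path Output path.
#' @param digits Significant digits to print (default 12).
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(grid, path, digits = 12) {
  stopifnot(is_raster_grid(grid))
  if (any(!is.finite(grid$values) & !is.na(grid$values))) {
    abort("Grid contains non-finite values; cannot write ASCII grid.")
  }
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata_value
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$origin[1] * 1000),
    sprintf("yllcorner %.6f", grid$origin[2] * 1000),
    sprintf("cellsize %.6f", grid$cell_size_km * 1000),
    sprintf("NODATA_value %s", format(grid$nodata_value, scientific = FALSE))
  )
  body <- apply(vals, 1, function(r) {
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("Cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write records to CSV
#'
#' Writes a data frame, or a list of records sharing one schema, as a
#' CSV with a header row. Numeric columns are unquoted.
#'
#' @param rows A data frame / tibble, or a list of named lists with
#'   identical names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (is.list(rows)) {
    if (length(rows) == 0) {
      abort("Cannot infer a schema from an empty record list; pass a data frame.")
    }
    schema <- names(rows[[1]])
    if (is.null(schema) || any(!nzchar(schema))) {
      abort("Records must be named lists.")
    }
    ok <- vapply(rows, function(r) identical(names(r), schema), logical(1))
    if (!all(ok)) {
      abort(sprintf("Record %d does not match the schema of record 1.",
                    which(!ok)[1]))
    }
    df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    abort("`rows` must be a data frame or a list of records.")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
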