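#' Single-band raster on an aligned square grid
#'
#' Lightweight container for the 1-km gridded layers used throughout the
#' workflow. Values are stored as a matrix with row 1 at the top of the map
#' (raster convention); missing data are `NA`. Cell (row, col) -- 0-based --
#' has its centre at x = (col + 0.5) * cell_size, y = (row + 0.5) * cell_size,
#' with y increasing downwards alongside the row index.
#'
#' @param values numeric (or character, for categorical layers such as land
#'   cover) matrix of cell values; `NA` marks nodata.
#' @param cell_size cell edge length in metres (default 1000).
#' @param name short layer name.
#' @param units units of the values.
#' @return an object of class `wet_raster`.
#' @export
raster_layer <- function(values, cell_size = 1000, name = "", units = "") {
  values <- as.matrix(values)
  if (is.numeric(values)) storage.mode(values) <- "double"
  stopifnot(cell_size > 0)
  structure(
    list(values = values, cell_size = cell_size, name = name, units = units),
    class = "wet_raster"
  )
}

#' @export
dim.wet_raster <- function(x) dim(x$values)

#' @export
print.wet_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<wet_raster> %s [%d x %d] cell %g m%s\n",
    if (nzchar(x$name)) x$name else "(unnamed)", d[1], d[2], x$cell_size,
    if (nzchar(x$units)) paste0(" (", x$units, ")") else ""
  ))
  invisible(x)
}

#' Apply an elementwise function to one or more aligned rasters
#'
#' `NA` cells propagate. All inputs must share grid shape and cell size.
#'
#' @param f vectorised function of as many arguments as rasters supplied.
#' @param ... one or more `wet_raster` layers.
#' @param name,units metadata for the result.
#' @return a `wet_raster`.
#' @export
raster_map <- function(f, ..., name = "", units = "") {
  layers <- list(...)
  stopifnot(length(layers) >= 1)
  check_aligned(layers)
  vals <- do.call(f, lapply(layers, function(r) r$values))
  out <- raster_layer(matrix(vals, nrow(layers[[1]]$values)),
                      cell_size = layers[[1]]$cell_size,
                      name = name, units = units)
  out
}

check_aligned <- function(layers) {
  d <- dim(layers[[1]]$values)
  cs <- layers[[1]]$cell_size
  for (r in layers) {
    if (!identical(dim(r$values), d) || !isTRUE(all.equal(r$cell_size, cs))) {
      stop("rasters are not aligned to one grid; inputs must share shape and cell size")
    }
  }
  invisible(TRUE)
}

#' Cell membership of point coordinates
#'
#' Cells are half-open: a point with x in \[i * cell_size, (i+1) * cell_size)
#' falls in column i (0-based); likewise for rows in y.
#'
#' @param x,y point coordinates in metres.
#' @param cell_size cell edge length in metres.
#' @return data.frame with 0-based `row`, `col`.
#' @export
cell_of <- function(x, y, cell_size) {
  data.frame(row = floor(y / cell_size), col = floor(x / cell_size))
}

#' Cell-centre coordinates for every cell of a grid
#' @param nrow,ncol grid dimensions.
#' @param cell_size cell edge length (m).
#' @return data.frame with 0-based `row`, `col` and centre `x`, `y` (column-major order).
#' @export
cell_centres <- function(nrow, ncol, cell_size) {
  row <- rep(seq_len(nrow) - 1L, times = ncol)
  col <- rep(seq_len(ncol) - 1L, each = nrow)
  data.frame(row = row, col = col,
             x = (col + 0.5) * cell_size,
             y = (row + 0.5) * cell_size)
}

#' Raster values at point locations
#'
#' @param r a `wet_raster`.
#' @param x,y coordinates; points outside the grid give `NA`.
#' @return vector of cell values.
#' @export
raster_values_at <- function(r, x, y) {
  cc <- cell_of(x, y, r$cell_size)
  d <- dim(r$values)
  ok <- cc$row >= 0 & cc$row < d[1] & cc$col >= 0 & cc$col < d[2] &
    is.finite(cc$row) & is.finite(cc$col)
  out <- rep(r$values[1][NA], length(x))
  out[ok] <- r$values[cbind(cc$row[ok] + 1L, cc$col[ok] + 1L)]
  out
}

#' Extract a covariate table at point locations
#'
#' @param stack named list of aligned `wet_raster` layers.
#' @param x,y coordinates.
#' @return data.frame, one column per layer.
#' @export
extract_covariates <- function(stack, x, y) {
  stopifnot(length(stack) >= 1, !is.null(names(stack)))
  check_aligned(stack)
  as.data.frame(lapply(stack, raster_values_at, x = x, y = y))
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format for single-band grids. Row 1 of the matrix is
#' written first (top of the map); `NA` is written as the nodata value.
#'
#' @param r a numeric `wet_raster`.
#' @param path file path.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "wet_raster"), is.numeric(r$values))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' @rdname write_asc
#' @param name,units metadata attached to the raster read back.
#' @export
read_asc <- function(path, name = "", units = "") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  m[m == val[["nodata_value"]]] <- NA_real_
  raster_layer(m, cell_size = val[["cellsize"]], name = name, units = units)
}
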