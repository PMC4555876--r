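#' Regular raster grid
#'
#' The universal carrier for covariates, weighting layers and population
#' surfaces: a rectangular, north-up, row-major numeric matrix on a projected
#' plane. Cell `(r, c)` occupies the half-open footprint
#' `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1) s]` where `s` is the cell
#' size in metres and `(x0, y0)` the top-left corner; its centre is at
#' `(x0 + (c - 0.5) s, y0 - (r - 0.5) s)`. NoData is carried as `NA` in
#' memory; the `nodata` field is the sentinel used on disk.
#'
#' @param values numeric matrix, rows = north to south scanlines; `NA` marks
#'   NoData.
#' @param cell_size cell side in metres (> 0).
#' @param origin numeric length-2, projected `(x, y)` of the top-left corner.
#' @param nodata sentinel written to / read from disk files.
#' @param crs_label opaque string naming the projected coordinate system.
#' @return an object of class `pop_grid`.
#' @examples
#' g <- pop_grid(matrix(0, 5, 5))
#' grid_dim(g)
#' @export
pop_grid <- function(values, cell_size = 100, origin = c(0, nrow(values) * cell_size),
                     nodata = -99999, crs_label = "local-projected") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite coordinates")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), nodata = nodata,
                 crs_label = crs_label),
            class = "pop_grid")
}

#' @export
print.pop_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<pop_grid> %d x %d cells, %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf("  range [%g, %g], NoData cells: %d\n",
                min(fin), max(fin), sum(is.na(v))))
  invisible(x)
}

#' @rdname pop_grid
#' @param g,a,b `pop_grid` objects.
#' @export
grid_dim <- function(g) dim(g$values)

#' Test whether two grids share shape, cell size and origin
#' @rdname pop_grid
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) stop(what, " are not aligned (shape/cell/origin)")
  invisible(TRUE)
}

#' Coordinates of every cell centre
#' @rdname pop_grid
#' @return `grid_centres()`: a list with matrices `x` and `y` of cell-centre
#'   coordinates, same shape as the grid.
#' @export
grid_centres <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values); s <- g$cell_size
  list(x = matrix(g$origin[1] + (seq_len(nc) - 0.5) * s, nr, nc, byrow = TRUE),
       y = matrix(g$origin[2] - (seq_len(nr) - 0.5) * s, nr, nc))
}

new_like <- function(g, values) {
  pop_grid(values, cell_size = g$cell_size, origin = g$origin,
           nodata = g$nodata, crs_label = g$crs_label)
}

#' Read / write a grid as an ESRI ASCII raster
#'
#' Plain-text raster interchange. The `xllcorner`/`yllcorner` header carries
#' the lower-left corner; the in-memory origin is the top-left corner.
#'
#' @param g a [pop_grid].
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `write_grid_asc()` returns `path` invisibly; `read_grid_asc()` a
#'   [pop_grid].
#' @export
write_grid_asc <- function(g, path, digits = 10) {
  v <- g$values
  v[is.na(v)] <- g$nodata
  nr <- nrow(v); nc <- ncol(v); s <- g$cell_size
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", g$origin[1]),
           sprintf("yllcorner %.10g", g$origin[2] - nr * s),
           sprintf("cellsize %.10g", s),
           sprintf("NODATA_value %.10g", g$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # one scanline per text row, north first (ASCII-grid convention)
  body <- apply(v, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_grid_asc
#' @param crs_label coordinate-system label attached on read.
#' @export
read_grid_asc <- function(path, crs_label = "local-projected") {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  nodata <- val[["nodata_value"]]
  body <- scan(path, skip = 6L, quiet = TRUE)
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == nodata] <- NA_real_
  pop_grid(v, cell_size = val[["cellsize"]],
           origin = c(val[["xllcorner"]], val[["yllcorner"]] + nr * val[["cellsize"]]),
           nodata = nodata, crs_label = crs_label)
}
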