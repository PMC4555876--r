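#' Fill NoData cells from their nearest valid neighbour ("nibble")
#'
#' Every cell that is NoData in `grid` but lies inside the study mask
#' receives the value of the nearest non-NoData cell (Euclidean
#' centre-to-centre distance); equidistant donors resolve to the earliest
#' cell in row-major scan order. All other cells are unchanged. Continuous
#' covariates are nibbled before zonal aggregation so unit means are never
#' contaminated by missing cells.
#'
#' @param grid a [pop_grid] with `NA` marking NoData.
#' @param mask a unit raster (or any grid) aligned with `grid`; cells where
#'   the mask is non-`NA` define "inside".
#' @return a [pop_grid] with no NoData inside the mask.
#' @export
nibble_fill <- function(grid, mask) {
  stopifnot_aligned(grid, mask, "grid and mask")
  inmask <- !is.na(mask$values)
  if (all(is.na(grid$values)))
    stop("grid is entirely NoData inside the mask")
  new_like(grid, .nibble_cpp(grid$values, inmask))
}

#' Euclidean distance to the nearest feature cell
#'
#' For a binary presence grid, returns each cell's distance in metres from
#' its centre to the centre of the nearest cell with value 1 (feature cells
#' get 0). Distances are planar, computed with an exact two-pass distance
#' transform. NoData cells are treated as feature-absent but still receive
#' a distance.
#'
#' @param binary a [pop_grid] containing only 0, 1 and `NA`.
#' @return a [pop_grid] of distances in metres.
#' @export
distance_to <- function(binary) {
  v <- binary$values
  bad <- v[!is.na(v)]
  if (length(bad) && any(bad != 0 & bad != 1))
    stop("`binary` must contain only 0, 1 and NoData")
  feat <- !is.na(v) & v == 1
  if (!any(feat)) stop("no feature cells (value 1) present")
  d2 <- .edt_sq_cpp(matrix(as.integer(feat), nrow(v), ncol(v)))
  new_like(binary, sqrt(d2) * binary$cell_size)
}

# accumulate M shifted by (di, dj) into an all-zero accumulator, treating
# out-of-bounds as 0
shift_add <- function(acc, M, di, dj) {
  nr <- nrow(M); nc <- ncol(M)
  r0 <- max(1L, 1L + di); r1 <- min(nr, nr + di)
  c0 <- max(1L, 1L + dj); c1 <- min(nc, nc + dj)
  if (r0 > r1 || c0 > c1) return(acc)
  r_dst <- r0:r1
  c_dst <- c0:c1
  acc[r_dst, c_dst] <- acc[r_dst, c_dst] + M[r_dst - di, c_dst - dj, drop = FALSE]
  acc
}

#' Proportion of feature cells within a circular window
#'
#' For each cell, the count of cells with value 1 whose centres lie within
#' `radius` metres of the cell's centre (the cell itself included), divided
#' by the count of all in-bounds cells whose centres lie within the radius.
#' Values are in `[0, 1]`. NoData counts toward the denominator (it is an
#' in-bounds cell) but never the numerator.
#'
#' @param binary a [pop_grid] containing only 0, 1 and `NA`.
#' @param radius window radius in metres (default 500, the production
#'   neighbourhood).
#' @return a [pop_grid] of proportions.
#' @export
focal_proportion <- function(binary, radius = 500) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a single positive number")
  v <- binary$values
  bad <- v[!is.na(v)]
  if (length(bad) && any(bad != 0 & bad != 1))
    stop("`binary` must contain only 0, 1 and NoData")
  s <- binary$cell_size
  rmax <- floor(radius / s)
  offs <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  offs <- offs[(offs$di^2 + offs$dj^2) * s^2 <= radius^2 + 1e-9, , drop = FALSE]
  ones <- matrix(1, nrow(v), ncol(v))
  feat <- matrix(as.numeric(!is.na(v) & v == 1), nrow(v), ncol(v))
  num <- matrix(0, nrow(v), ncol(v))
  den <- matrix(0, nrow(v), ncol(v))
  for (k in seq_len(nrow(offs))) {
    num <- shift_add(num, feat, offs$di[k], offs$dj[k])
    den <- shift_add(den, ones, offs$di[k], offs$dj[k])
  }
  new_like(binary, num / den)
}

#' Topographic slope from a DEM
#'
#' Per-cell slope in degrees from a finite-difference gradient: central
#' differences in the interior, one-sided differences on the border.
#'
#' @param dem a [pop_grid] of elevations in metres.
#' @return a [pop_grid] of slope in degrees.
#' @export
slope_from_dem <- function(dem) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2L || nc < 2L) stop("DEM must be at least 2 x 2")
  s <- dem$cell_size
  denom_c <- c(1, rep(2, max(0L, nc - 2L)), 1) * s
  denom_r <- c(1, rep(2, max(0L, nr - 2L)), 1) * s
  gx <- (v[, c(2:nc, nc), drop = FALSE] - v[, c(1, 1:(nc - 1)), drop = FALSE]) /
    matrix(denom_c, nr, nc, byrow = TRUE)
  gy <- (v[c(2:nr, nr), , drop = FALSE] - v[c(1, 1:(nr - 1)), , drop = FALSE]) /
    matrix(denom_r, nr, nc)
  new_like(dem, atan(sqrt(gx^2 + gy^2)) * 180 / pi)
}
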