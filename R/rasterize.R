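#' Rasterize administrative units by cell-centre containment
#'
#' Labels every cell whose centre falls inside a unit polygon with that
#' unit's id; cells whose centre lies in no unit are NoData. The extent is
#' the bounding box of the union of the unit polygons, snapped so the
#' top-left corner coincides with the box corner. Centres exactly on a
#' shared boundary resolve to the unit with the smaller id (units are
#' claimed in increasing id order, first claim wins). A unit too small to
#' capture any cell centre is given the cell containing its interior
#' representative point, so every unit owns at least one cell and every
#' census count can be placed.
#'
#' @param units an [admin_set]; geometries must be valid polygons in a
#'   projected system.
#' @param cell_size cell side in metres (default 100, the production
#'   resolution).
#' @param extent optional `c(xmin, ymin, xmax, ymax)` overriding the derived
#'   extent (e.g. the buffered study area).
#' @return a [pop_grid] of integer unit ids (`NA` outside all units), the
#'   "unit raster".
#' @export
rasterize_units <- function(units, cell_size = 100, extent = NULL) {
  stopifnot(inherits(units, "admin_set"))
  ids <- sort(units$units$unit_id)
  if (is.null(extent)) {
    bbs <- vapply(units$geometry, polygon_bbox, numeric(4))
    extent <- c(min(bbs[1, ]), min(bbs[2, ]), max(bbs[3, ]), max(bbs[4, ]))
  }
  nc <- max(1L, ceiling((extent[3] - extent[1]) / cell_size - 1e-9))
  nr <- max(1L, ceiling((extent[4] - extent[2]) / cell_size - 1e-9))
  origin <- c(extent[1], extent[2] + nr * cell_size)
  g <- pop_grid(matrix(NA_real_, nr, nc), cell_size = cell_size,
                origin = origin, nodata = -99999)
  ctr <- grid_centres(g)
  lab <- g$values
  for (id in ids) {
    poly <- units$geometry[[as.character(id)]]
    bb <- polygon_bbox(poly)
    cand <- which(is.na(lab) &
                    ctr$x >= bb["xmin"] - cell_size & ctr$x <= bb["xmax"] + cell_size &
                    ctr$y >= bb["ymin"] - cell_size & ctr$y <= bb["ymax"] + cell_size)
    if (!length(cand)) next
    hit <- points_in_polygon(ctr$x[cand], ctr$y[cand], poly)
    lab[cand[hit]] <- id
  }
  # guarantee >= 1 cell per unit
  owned <- unique(lab[!is.na(lab)])
  for (id in setdiff(ids, owned)) {
    rp <- polygon_rep_point(units$geometry[[as.character(id)]])
    cc <- min(max(1L, 1L + floor((rp[1] - origin[1]) / cell_size)), nc)
    rr <- min(max(1L, 1L + floor((origin[2] - rp[2]) / cell_size)), nr)
    lab[rr, cc] <- id
  }
  g$values <- lab
  class(g) <- c("unit_raster", class(g))
  g
}

# relabel a fine unit raster by each unit's parent id (used for the
# coarse-to-fine holdout; avoids re-rasterizing unions)
relabel_by_parent <- function(unit_raster, fine) {
  u <- fine$units
  if (all(is.na(u$parent_id))) stop("fine units carry no parent links")
  v <- unit_raster$values
  m <- match(v, u$unit_id)
  out <- unit_raster
  out$values <- matrix(u$parent_id[m], nrow(v), ncol(v))
  out
}
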