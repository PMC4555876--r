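as_pop_surface <- function(grid, year, variant, kind) {
  grid$year <- as.integer(year)
  grid$variant <- variant
  grid$kind <- kind
  class(grid) <- unique(c("pop_surface", class(grid)))
  grid
}

#' Dasymetric disaggregation of unit counts
#'
#' Redistributes each administrative unit's population count over its cells
#' proportionally to the weighting layer: cell `i` of unit `u` receives
#' `population_u * w_i / sum(w_j, j in u)`. Per-unit cell sums reproduce
#' the input counts exactly (up to floating point); only the ratios of the
#' weights within a unit matter. Cells outside every unit are NoData even
#' where weights exist (the buffer zone carries no people). A unit whose
#' weights sum to zero falls back to uniform shares with a warning.
#'
#' @param units an [admin_set].
#' @param unit_raster the unit raster from [rasterize_units()], aligned
#'   with `weights`.
#' @param weights a weighting-layer [pop_grid] (see [predict_density()]).
#' @return a people-per-pixel [pop_grid] (`kind = "ppp"`, census-year
#'   variant).
#' @export
disaggregate <- function(units, unit_raster, weights) {
  stopifnot(inherits(units, "admin_set"))
  stopifnot_aligned(unit_raster, weights, "unit raster and weights")
  ids <- unit_raster$values
  sel <- which(!is.na(ids))
  u <- units$units
  m <- match(ids[sel], u$unit_id)
  if (anyNA(m)) stop("unit raster labels ids absent from the admin set")
  w <- weights$values[sel]
  w[is.na(w)] <- 0
  f <- factor(m, levels = seq_len(nrow(u)))
  wsum <- as.numeric(rowsum(w, f))
  ncell <- as.numeric(table(f))
  bad <- which(wsum <= 0 & ncell > 0)
  if (length(bad)) {
    if (any(u$population[bad] > 0))
      warning("unit(s) with zero total weight and positive population: ",
              paste(u$unit_id[bad][u$population[bad] > 0], collapse = ", "),
              "; falling back to uniform weights")
    uniform <- m %in% bad
    w[uniform] <- 1
    wsum[bad] <- ncell[bad]
  }
  share <- u$population[m] * w / wsum[m]
  v <- matrix(NA_real_, nrow(ids), ncol(ids))
  v[sel] <- share
  as_pop_surface(new_like(unit_raster, v), units$census_year,
                 "census-year", "ppp")
}

#' Simple areal weighting (SAW) baseline
#'
#' The uniform-density baseline: each cell of unit `u` receives
#' `population_u / n_cells_u`. Equivalent to [disaggregate()] with a
#' constant weighting layer.
#'
#' @inheritParams disaggregate
#' @return a people-per-pixel [pop_grid].
#' @export
saw_disaggregate <- function(units, unit_raster) {
  const <- new_like(unit_raster,
                    matrix(1, nrow(unit_raster$values), ncol(unit_raster$values)))
  disaggregate(units, unit_raster, const)
}

#' Convert people per pixel to people per hectare
#'
#' Divides each cell by its area in hectares (`cell_size^2 / 10000`); at
#' the production 100-m resolution the two surfaces coincide.
#'
#' @param ppp a people-per-pixel [pop_grid].
#' @return a people-per-hectare [pop_grid] (`kind = "pph"`).
#' @export
people_per_hectare <- function(ppp) {
  if (!identical(ppp$kind, "ppp")) stop("input must be a ppp surface")
  ha <- ppp$cell_size^2 / 1e4
  out <- new_like(ppp, ppp$values / ha)
  as_pop_surface(out, ppp$year, ppp$variant, "pph")
}
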