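#' Recode a land-cover raster to the working class set
#'
#' Replaces every raw class code by its mapped target code. Cells whose raw
#' code has no mapping become NoData (or `default` when given) and their
#' count is recorded in the `unmapped` attribute.
#'
#' @param raw a [pop_grid] of integer class codes.
#' @param mapping data.frame with columns `from`, `to`.
#' @param default optional target code for unmapped cells.
#' @return a [pop_grid] of recoded classes (class `landcover_grid`).
#' @export
recode_landcover <- function(raw, mapping, default = NULL) {
  stopifnot(is.data.frame(mapping), all(c("from", "to") %in% names(mapping)))
  if (nrow(mapping) == 0L) stop("empty recode mapping")
  v <- raw$values
  m <- match(v, mapping$from)
  out <- matrix(mapping$to[m], nrow(v), ncol(v))
  unmapped <- sum(!is.na(v) & is.na(m))
  if (unmapped > 0) {
    if (!is.null(default)) {
      out[!is.na(v) & is.na(m)] <- default
    } else {
      message(unmapped, " cells carried unmapped land-cover codes -> NoData")
    }
  }
  g <- new_like(raw, out)
  attr(g, "unmapped") <- unmapped
  class(g) <- c("landcover_grid", class(g))
  g
}

#' Split built-up land cover into urban and rural classes
#'
#' Mosaics a binary urban-extent layer into the land cover: cells inside the
#' urban extent become class 190 (urban built-up); built-up cells outside it
#' become class 240 (rural built-up); all other cells are unchanged.
#'
#' @param landcover a land-cover [pop_grid].
#' @param urban_extent a binary [pop_grid] aligned with `landcover`.
#' @return the land-cover grid with classes 190/240 delineated.
#' @export
mosaic_urban <- function(landcover, urban_extent) {
  stopifnot_aligned(landcover, urban_extent, "landcover and urban extent")
  v <- landcover$values
  urb <- !is.na(urban_extent$values) & urban_extent$values == 1
  builtup <- !is.na(v) & v %in% c(190, 240)
  v[builtup & !urb] <- 240
  v[urb & !is.na(v)] <- 190
  out <- new_like(landcover, v)
  class(out) <- unique(c("landcover_grid", class(out)))
  out
}

#' Combined built-up class (BLT)
#'
#' Binary union of the urban (190) and rural (240) built-up classes.
#'
#' @param landcover a land-cover [pop_grid].
#' @return a binary [pop_grid].
#' @export
built_up_class <- function(landcover) {
  v <- landcover$values
  new_like(landcover, matrix(as.numeric(!is.na(v) & v %in% c(190, 240)),
                             nrow(v), ncol(v)))
}

class_binary <- function(landcover, k) {
  v <- landcover$values
  new_like(landcover, matrix(as.numeric(!is.na(v) & v == k), nrow(v), ncol(v)))
}

#' Build the named covariate stack
#'
#' Derives the full covariate family from the prepared inputs: for every
#' land-cover class present, for the combined built-up class (`BLT`) and for
#' every binary feature layer, emits `cls_<k>` (presence), `dst_<k>`
#' (distance in metres to the nearest presence cell) and `prp_<k>`
#' (proportion of presence within the focal radius). Continuous layers are
#' nibble-filled inside the mask and passed through under their own names. A
#' class with zero presence cells has an undefined distance layer; its
#' `dst_`/`prp_` members are dropped and recorded in the `dropped`
#' attribute.
#'
#' @param landcover a land-cover [pop_grid] (recoded, urban-mosaicked).
#' @param continuous named list of continuous [pop_grid]s.
#' @param binary_features named list of binary [pop_grid]s (pre-rasterized
#'   vector features such as roads or protected areas).
#' @param mask the unit raster defining the study area.
#' @param radius focal radius in metres for the `prp_` family.
#' @return a named list of aligned grids, class `cov_stack`.
#' @export
build_stack <- function(landcover, continuous = list(), binary_features = list(),
                        mask, radius = 500) {
  stopifnot_aligned(landcover, mask, "landcover and mask")
  for (nm in names(continuous))
    stopifnot_aligned(continuous[[nm]], mask, paste0("continuous layer '", nm, "' and mask"))
  for (nm in names(binary_features))
    stopifnot_aligned(binary_features[[nm]], mask, paste0("binary layer '", nm, "' and mask"))

  stack <- list()
  dropped <- character()
  add_family <- function(stack, key, bin) {
    stack[[paste0("cls_", key)]] <- bin
    if (any(!is.na(bin$values) & bin$values == 1)) {
      stack[[paste0("dst_", key)]] <- distance_to(bin)
      stack[[paste0("prp_", key)]] <- focal_proportion(bin, radius)
    } else {
      dropped <<- c(dropped, key)
      message("class '", key, "' has no presence cells; dst_/prp_ dropped")
    }
    stack
  }

  classes <- sort(unique(landcover$values[!is.na(landcover$values)]))
  for (k in classes)
    stack <- add_family(stack, format(k), class_binary(landcover, k))
  if (any(classes %in% c(190, 240)))
    stack <- add_family(stack, "BLT", built_up_class(landcover))
  for (nm in names(binary_features))
    stack <- add_family(stack, nm, binary_features[[nm]])
  for (nm in names(continuous))
    stack[[nm]] <- nibble_fill(continuous[[nm]], mask)

  structure(stack, dropped = dropped, class = "cov_stack")
}

#' Aggregate a covariate stack to administrative units
#'
#' One row per unit: the arithmetic mean of each continuous covariate over
#' the unit's cells, and the modal value of each binary `cls_` covariate
#' (50/50 ties report 0, absence). This is the training table for the
#' density model.
#'
#' @param stack a `cov_stack` (see [build_stack()]).
#' @param unit_raster the unit raster aligned with the stack.
#' @return data.frame with `unit_id` and one column per covariate.
#' @export
zonal_aggregate <- function(stack, unit_raster) {
  stopifnot(length(stack) > 0)
  for (nm in names(stack))
    stopifnot_aligned(stack[[nm]], unit_raster, paste0("layer '", nm, "' and unit raster"))
  ids <- unit_raster$values
  sel <- which(!is.na(ids))
  if (!length(sel)) stop("unit raster labels no cells")
  f <- factor(ids[sel])
  n_by <- as.numeric(table(f))
  out <- data.frame(unit_id = as.numeric(levels(f)))
  for (nm in names(stack)) {
    v <- stack[[nm]]$values[sel]
    if (anyNA(v))
      stop("layer '", nm, "' has NoData inside units; nibble-fill it first")
    mean_u <- as.numeric(rowsum(v, f)) / n_by
    out[[nm]] <- if (startsWith(nm, "cls_")) as.numeric(mean_u > 0.5) else mean_u
  }
  out
}
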