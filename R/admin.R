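#' Administrative units with census counts
#'
#' The census input and validation frame: a set of polygons with unique
#' integer ids, an admin level, non-negative integer population counts,
#' areas in square kilometres, and optional parent links for a nested
#' hierarchy (children's counts must sum to the parent's).
#'
#' @param units data.frame with columns `unit_id`, `level`, `population`,
#'   optionally `area_km2` (computed from geometry when absent) and
#'   `parent_id`.
#' @param geometry list of polygons (matrix or list of ring matrices), one
#'   per row of `units`, in a projected coordinate system (metres).
#' @param census_year integer year of the counts.
#' @param country_code 3-letter code used in output file names.
#' @return an object of class `admin_set`.
#' @export
admin_set <- function(units, geometry, census_year, country_code = "SYN") {
  stopifnot(is.data.frame(units), is.list(geometry))
  req <- c("unit_id", "level", "population")
  if (!all(req %in% names(units)))
    stop("`units` needs columns ", paste(req, collapse = ", "))
  if (nrow(units) == 0L) stop("empty admin set")
  if (anyDuplicated(units$unit_id)) stop("unit ids must be unique")
  if (length(geometry) != nrow(units))
    stop("one geometry per unit row required")
  if (any(units$population < 0) || any(units$population != round(units$population)))
    stop("populations must be non-negative integers")
  geometry <- lapply(geometry, as_polygon)
  names(geometry) <- as.character(units$unit_id)
  if (is.null(units$area_km2))
    units$area_km2 <- vapply(geometry, polygon_area_m2, 0) / 1e6
  if (any(units$area_km2 <= 0)) stop("unit areas must be positive")
  if (is.null(units$parent_id)) units$parent_id <- NA_integer_
  out <- structure(list(units = units, geometry = geometry,
                        census_year = as.integer(census_year),
                        country_code = country_code),
                   class = "admin_set")
  check_hierarchy(out)
  out
}

check_hierarchy <- function(x) {
  u <- x$units
  if (all(is.na(u$parent_id))) return(invisible(TRUE))
  sums <- tapply(u$population, u$parent_id, sum)
  # parents present in the same set must match their children's sums
  present <- intersect(names(sums), as.character(u$unit_id))
  for (p in present) {
    pop <- u$population[match(as.integer(p), u$unit_id)]
    if (sums[[p]] != pop)
      stop("children of unit ", p, " sum to ", sums[[p]], " not ", pop)
  }
  invisible(TRUE)
}

#' @export
print.admin_set <- function(x, ...) {
  cat(sprintf("<admin_set> %s, %d units (levels %s), census %d, total pop %s\n",
              x$country_code, nrow(x$units),
              paste(sort(unique(x$units$level)), collapse = "/"),
              x$census_year,
              format(sum(x$units$population), big.mark = ",")))
  invisible(x)
}

#' Subset an admin set to one level
#' @param x an [admin_set]; `level` the admin level to keep.
#' @keywords internal
admin_level <- function(x, level) {
  keep <- x$units$level == level
  if (!any(keep)) stop("no units at level ", level)
  admin_set(x$units[keep, , drop = FALSE], x$geometry[keep],
            x$census_year, x$country_code)
}

#' Join census counts onto units from a delimited table
#'
#' @param units an [admin_set] (populations may be placeholder zeros).
#' @param table data.frame or path to a CSV with columns `unit_id`,
#'   `population`.
#' @return the admin set with populations replaced.
#' @export
join_census <- function(units, table) {
  if (is.character(table)) table <- utils::read.csv(table)
  stopifnot(all(c("unit_id", "population") %in% names(table)))
  m <- match(units$units$unit_id, table$unit_id)
  if (anyNA(m)) stop("census table missing ids: ",
                     paste(units$units$unit_id[is.na(m)], collapse = ", "))
  units$units$population <- as.numeric(table$population[m])
  check_hierarchy(units)
  units
}

# ---- GeoJSON I/O ------------------------------------------------------

#' Read / write administrative units as GeoJSON
#'
#' Plain-text vector interchange. Each feature carries `unit_id`, `level`,
#' `population`, `area_km2` and `parent_id` properties; geometries are
#' Polygon or MultiPolygon in projected metres (no holes).
#'
#' @param x an [admin_set].
#' @param path output file.
#' @return `write_units_geojson()` returns `path` invisibly;
#'   `read_units_geojson()` an [admin_set].
#' @export
write_units_geojson <- function(x, path) {
  feats <- lapply(seq_len(nrow(x$units)), function(i) {
    u <- x$units[i, ]
    parts <- x$geometry[[i]]
    coords <- lapply(parts, function(r) list(lapply(seq_len(nrow(r) + 1L), function(k) {
      kk <- if (k > nrow(r)) 1L else k
      c(r[kk, 1], r[kk, 2])
    })))
    geom <- if (length(parts) == 1L)
      list(type = "Polygon", coordinates = coords[[1]])
    else list(type = "MultiPolygon", coordinates = coords)
    list(type = "Feature",
         properties = list(unit_id = u$unit_id, level = u$level,
                           population = u$population, area_km2 = u$area_km2,
                           parent_id = u$parent_id),
         geometry = geom)
  })
  doc <- list(type = "FeatureCollection",
              properties = list(census_year = x$census_year,
                                country_code = x$country_code),
              features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_units_geojson
#' @export
read_units_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  feats <- doc$features
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    m
  }
  geometry <- lapply(feats, function(f) {
    g <- f$geometry
    if (g$type == "Polygon") lapply(g$coordinates, ring_mat)
    else if (g$type == "MultiPolygon")
      lapply(g$coordinates, function(p) ring_mat(p[[1]]))
    else stop("unsupported geometry type: ", g$type)
  })
  getp <- function(f, k) {
    v <- f$properties[[k]]
    if (is.null(v)) NA else v
  }
  units <- data.frame(
    unit_id = vapply(feats, getp, 0, k = "unit_id"),
    level = vapply(feats, getp, 0, k = "level"),
    population = vapply(feats, getp, 0, k = "population"),
    area_km2 = vapply(feats, getp, 0, k = "area_km2"),
    parent_id = vapply(feats, getp, 0, k = "parent_id"))
  admin_set(units, geometry,
            census_year = doc$properties$census_year,
            country_code = doc$properties$country_code)
}
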