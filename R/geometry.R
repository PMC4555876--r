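# Minimal planar polygon tools. A "polygon" is a list of one or more parts
# (disjoint outer rings, holes unsupported); each part is an n x 2 coordinate
# matrix in projected metres, closure implicit. Enough geometry for admin
# units that tessellate a study area; not a general computational-geometry
# layer.

as_polygon <- function(x) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !length(x) || !all(vapply(x, is.matrix, TRUE)))
    stop("a polygon is a matrix or a list of n x 2 coordinate matrices")
  lapply(x, function(m) {
    if (ncol(m) != 2L || nrow(m) < 3L) stop("each ring needs >= 3 xy rows")
    # drop an explicit closing vertex
    if (all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a polygon in square metres / square kilometres
#' @param poly a polygon (matrix or list of ring matrices).
#' @return area (shoelace formula, parts summed).
#' @keywords internal
polygon_area_m2 <- function(poly) {
  sum(vapply(as_polygon(poly), function(r) abs(ring_signed_area(r)), 0))
}

polygon_bbox <- function(poly) {
  xy <- do.call(rbind, as_polygon(poly))
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# even-odd crossing test, boundary-inclusive, vectorized over points
points_in_ring <- function(px, py, ring, eps = 1e-9) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  x <- ring[, 1]; y <- ring[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    # boundary: zero cross product and within segment bbox
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    on_i <- abs(cross) <= eps * (sqrt(seg_len2) + 1) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onedge <- onedge | on_i
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

points_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  hit <- rep(FALSE, length(px))
  for (ring in poly) hit <- hit | points_in_ring(px, py, ring)
  hit
}

# interior representative point: centroid if contained, else densified
# fallback scan over the ring bbox
polygon_rep_point <- function(poly) {
  poly <- as_polygon(poly)
  ring <- poly[[which.max(vapply(poly, function(r) abs(ring_signed_area(r)), 0))]]
  a <- ring_signed_area(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  if (points_in_polygon(cx, cy, poly)) return(c(cx, cy))
  bb <- polygon_bbox(ring)
  for (k in c(7, 17, 41)) {
    gx <- seq(bb["xmin"], bb["xmax"], length.out = k)
    gy <- seq(bb["ymin"], bb["ymax"], length.out = k)
    pts <- expand.grid(x = gx, y = gy)
    hit <- points_in_polygon(pts$x, pts$y, poly)
    if (any(hit)) return(as.numeric(pts[which(hit)[1], ]))
  }
  stop("no interior point found for polygon")
}

ensure_ccw <- function(ring) if (ring_signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring

# exact Minkowski offset of a convex ring: offset edges joined by vertex
# arcs discretized at `step_deg`
buffer_ring <- function(ring, distance, step_deg = 5) {
  ring <- ensure_ccw(ring)
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  ex <- ring[nxt, 1] - ring[, 1]
  ey <- ring[nxt, 2] - ring[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  ring <- ring[keep, , drop = FALSE]
  ex <- ex[keep]; ey <- ey[keep]; len <- len[keep]
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  # outward normal of a CCW edge
  nx <- ey / len
  ny <- -ex / len
  out <- list()
  for (i in seq_len(n)) {
    j <- nxt[i]
    out[[length(out) + 1L]] <- rbind(
      ring[i, ] + distance * c(nx[i], ny[i]),
      ring[j, ] + distance * c(nx[i], ny[i]))
    # arc around vertex j from normal i to normal j
    a0 <- atan2(ny[i], nx[i])
    a1 <- atan2(ny[j], nx[j])
    da <- (a1 - a0) %% (2 * pi)
    if (da > 1e-12 && da < pi + 1e-9) {  # convex turn
      k <- max(1L, ceiling(da / (step_deg * pi / 180)))
      ang <- a0 + da * seq_len(k - 1L) / k
      if (length(ang))
        out[[length(out) + 1L]] <- cbind(ring[j, 1] + distance * cos(ang),
                                         ring[j, 2] + distance * sin(ang))
    }
  }
  do.call(rbind, out)
}

#' Outward buffer of the admin-unit footprint
#'
#' Expands each unit polygon outward by `distance` metres (exact Minkowski
#' offset for convex rings, vertex arcs discretized) and returns the
#' collection as a multipolygon defining the processing extent. Used so
#' distance-to covariates are computed on a study area padded beyond the
#' census boundary (conventionally 10 km) and are free of edge
#' effects.
#'
#' @param units an [admin_set].
#' @param distance buffer distance in metres, `>= 0`; `0` returns the input
#'   footprint unchanged.
#' @param step_deg arc discretization step in degrees.
#' @return a list of polygons (class `multi_polygon`); membership of a point
#'   is containment in any member.
#' @export
buffer_region <- function(units, distance, step_deg = 5) {
  stopifnot(inherits(units, "admin_set"))
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("`distance` must be a single non-negative number")
  polys <- unlist(lapply(units$geometry, as_polygon), recursive = FALSE)
  if (distance == 0) {
    out <- lapply(polys, function(r) list(r))
  } else {
    out <- lapply(polys, function(r) list(buffer_ring(r, distance, step_deg)))
  }
  structure(out, class = "multi_polygon")
}
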