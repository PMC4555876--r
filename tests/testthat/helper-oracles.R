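# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most literal algorithm available (winding numbers,
# all-pairs scans, per-unit loops) and share no code with the package
# implementations they check.

# winding-number point-in-polygon (angle sum)
oracle_pip <- function(px, py, ring) {
  n <- nrow(ring)
  ang <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    a1 <- atan2(ring[k, 2] - py, ring[k, 1] - px)
    a2 <- atan2(ring[k2, 2] - py, ring[k2, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# all-pairs minimum distance to a feature cell, metres
oracle_distance_to <- function(values, cell_size) {
  nr <- nrow(values); nc <- ncol(values)
  feat <- which(!is.na(values) & values == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- (feat[, 1] - i)^2 + (feat[, 2] - j)^2
    out[i, j] <- sqrt(min(d2)) * cell_size
  }
  out
}

# exhaustive circular-window proportion
oracle_focal_prop <- function(values, cell_size, radius) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  all_ij <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  is_one <- !is.na(values) & values == 1
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- ((all_ij$i - i)^2 + (all_ij$j - j)^2) * cell_size^2
    inwin <- d2 <= radius^2 + 1e-9
    out[i, j] <- sum(is_one[cbind(all_ij$i[inwin], all_ij$j[inwin])]) / sum(inwin)
  }
  out
}

# exhaustive nearest-valid-cell fill with row-major tie-break
oracle_nibble <- function(values, inmask) {
  nr <- nrow(values); nc <- ncol(values)
  valid <- which(!is.na(values), arr.ind = TRUE)
  out <- values
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!inmask[i, j] || !is.na(values[i, j])) next
    d2 <- (valid[, 1] - i)^2 + (valid[, 2] - j)^2
    best <- min(d2)
    tied <- which(d2 <= best + 1e-9)
    rowmajor <- (valid[tied, 1] - 1) * nc + valid[tied, 2]
    pick <- tied[which.min(rowmajor)]
    out[i, j] <- values[valid[pick, 1], valid[pick, 2]]
  }
  out
}

# naive per-unit zonal means / sums
oracle_zonal_mean <- function(values, ids) {
  u <- sort(unique(ids[!is.na(ids)]))
  vapply(u, function(k) mean(values[!is.na(ids) & ids == k]), 0)
}
oracle_zonal_sum <- function(values, ids) {
  u <- sort(unique(ids[!is.na(ids)]))
  vapply(u, function(k) sum(values[!is.na(ids) & ids == k], na.rm = TRUE), 0)
}

# independent central-difference slope, degrees
oracle_slope <- function(dem, cell) {
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    jl <- max(1, j - 1); jr <- min(nc, j + 1)
    iu <- max(1, i - 1); id <- min(nr, i + 1)
    gx <- (dem[i, jr] - dem[i, jl]) / ((jr - jl) * cell)
    gy <- (dem[id, j] - dem[iu, j]) / ((id - iu) * cell)
    out[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  out
}

# random convex polygon: points on a jittered circle, ordered by angle
random_convex_ring <- function(cx, cy, rad, n = 8) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- rad * runif(n, 0.6, 1)
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

random_binary_grid <- function(nr, nc, p = 0.2, cell = 100) {
  pop_grid(matrix(rbinom(nr * nc, 1, p), nr, nc), cell_size = cell)
}

# small default world used across tests (120x120, 6 coarse x 4 children)
tiny_world <- function(seed = 42, ...) make_landscape(seed, ...)
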