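#' @keywords internal
# near-square factor pair (rows, cols) of n
grid_factors <- function(n) {
  r <- floor(sqrt(n))
  while (r > 1L && n %% r != 0L) r <- r - 1L
  c(r, n %/% r)
}

# spatially smooth standardized field: white noise passed through a circular
# moving-average filter (stands in for the autocorrelation of real
# covariates)
smooth_field <- function(n_rows, n_cols, range_cells = 12) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  offs <- expand.grid(di = -range_cells:range_cells, dj = -range_cells:range_cells)
  offs <- offs[offs$di^2 + offs$dj^2 <= range_cells^2, , drop = FALSE]
  num <- matrix(0, n_rows, n_cols)
  den <- matrix(0, n_rows, n_cols)
  ones <- matrix(1, n_rows, n_cols)
  for (k in seq_len(nrow(offs))) {
    num <- shift_add(num, z, offs$di[k], offs$dj[k])
    den <- shift_add(den, ones, offs$di[k], offs$dj[k])
  }
  s <- num / den
  (s - mean(s)) / stats::sd(s)
}

rect_ring <- function(r0, r1, c0, c1, n_rows, cell) {
  # cell-index bounds [r0, r1) x [c0, c1) -> CCW rectangle in metres
  x0 <- c0 * cell; x1 <- c1 * cell
  ytop <- (n_rows - r0) * cell; ybot <- (n_rows - r1) * cell
  rbind(c(x0, ybot), c(x1, ybot), c(x1, ytop), c(x0, ytop))
}

largest_remainder <- function(raw, total) {
  if (total == 0) return(rep(0, length(raw)))
  if (sum(raw) <= 0) raw <- rep(1, length(raw))
  quota <- total * raw / sum(raw)
  base <- floor(quota)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a seeded synthetic landscape
#'
#' Builds a fully synthetic world on which every pipeline stage can run: a
#' two-level nested rectangular tessellation of admin units, smooth
#' continuous covariates (filtered white noise), a categorical land-cover
#' field with an urban core and a built-up ring, the derived covariate
#' stack, and a ground-truth density surface
#' `exp(b0 + sum(effect_k * z_k) + noise)` (people per km2) whose integral
#' over unit cells gives integer unit counts (largest-remainder rounding
#' within each coarse unit, so the hierarchy sums exactly). The same seed
#' reproduces the identical world.
#'
#' @param seed integer seed.
#' @param n_rows,n_cols grid shape in cells (default 120 x 120 at 100 m).
#' @param n_coarse number of coarse (level-1) units.
#' @param children_per_coarse fine (level-2) units per coarse unit.
#' @param effect named coefficients on standardized covariate-stack layers
#'   driving the true log density.
#' @param noise_sd s.d. of the smooth spatial noise on the log-density
#'   scale.
#' @param cell_size cell side in metres.
#' @param base_log_density intercept `b0`; the default `log(50)` centres
#'   density near 50 people per km2.
#' @param census_year,country_code carried into the admin sets.
#' @param smooth_range filter radius (cells) of the covariate fields.
#' @param urban_radius_cells radius of the urban core; the built-up ring
#'   extends half as far again.
#' @return a list of class `synth_world`: `fine_units`, `coarse_units`,
#'   `stack`, `true_density`, `unit_raster`, `landcover`, `urban_extent`,
#'   `continuous`, `seed`, `params`.
#' @export
make_landscape <- function(seed, n_rows = 120, n_cols = 120, n_coarse = 6,
                           children_per_coarse = 4,
                           effect = c(lights = 0.45, elev = -0.2, tmean = 0.15,
                                      dst_BLT = -0.5, prp_BLT = 0.3),
                           noise_sd = 0.2, cell_size = 100,
                           base_log_density = log(50), census_year = 2010,
                           country_code = "SYN", smooth_range = 12,
                           urban_radius_cells = 12) {
  stopifnot(n_rows > 0, n_cols > 0, n_coarse > 0, children_per_coarse > 0)
  set.seed(seed)

  # ---- nested tessellation -------------------------------------------
  cf <- grid_factors(n_coarse)
  ff <- grid_factors(children_per_coarse)
  rb <- round(seq(0, n_rows, length.out = cf[1] + 1))
  cb <- round(seq(0, n_cols, length.out = cf[2] + 1))
  fine_rows <- list(); coarse_rows <- list()
  fine_geom <- list(); coarse_geom <- list()
  cid <- 0L
  for (i in seq_len(cf[1])) for (j in seq_len(cf[2])) {
    cid <- cid + 1L
    r0 <- rb[i]; r1 <- rb[i + 1]; c0 <- cb[j]; c1 <- cb[j + 1]
    coarse_rows[[cid]] <- data.frame(unit_id = cid, level = 1L, population = 0,
                                     parent_id = NA_integer_)
    coarse_geom[[cid]] <- rect_ring(r0, r1, c0, c1, n_rows, cell_size)
    frb <- round(seq(r0, r1, length.out = ff[1] + 1))
    fcb <- round(seq(c0, c1, length.out = ff[2] + 1))
    k <- 0L
    for (fi in seq_len(ff[1])) for (fj in seq_len(ff[2])) {
      k <- k + 1L
      if (frb[fi + 1] - frb[fi] < 2 || fcb[fj + 1] - fcb[fj] < 2)
        stop("grid too small: a fine unit would own fewer than 4 cells")
      fid <- cid * 1000L + k
      fine_rows[[length(fine_rows) + 1L]] <-
        data.frame(unit_id = fid, level = 2L, population = 0, parent_id = cid)
      fine_geom[[length(fine_geom) + 1L]] <-
        rect_ring(frb[fi], frb[fi + 1], fcb[fj], fcb[fj + 1], n_rows, cell_size)
    }
  }

  fine <- admin_set(do.call(rbind, fine_rows), fine_geom, census_year, country_code)
  unit_raster <- rasterize_units(fine, cell_size = cell_size,
                                 extent = c(0, 0, n_cols * cell_size, n_rows * cell_size))

  # ---- covariate fields ----------------------------------------------
  proto <- new_like(unit_raster, matrix(0, n_rows, n_cols))
  mk <- function(scale, centre) new_like(proto, smooth_field(n_rows, n_cols, smooth_range) * scale + centre)
  continuous <- list(elev = mk(300, 500), tmean = mk(5, 20),
                     precip = mk(400, 1200))

  # urban core placed away from the border
  ur <- urban_radius_cells
  ctr <- c(sample(seq(ur + 2, n_rows - ur - 1), 1),
           sample(seq(ur + 2, n_cols - ur - 1), 1))
  d_cells <- sqrt(outer((seq_len(n_rows) - ctr[1])^2,
                        (seq_len(n_cols) - ctr[2])^2, "+"))
  urban_extent <- new_like(proto, matrix(as.numeric(d_cells <= ur), n_rows, n_cols))

  # night lights: smooth background plus a bright urban bump
  lights <- smooth_field(n_rows, n_cols, smooth_range) * 0.5 +
    2 * exp(-(d_cells / (1.5 * ur))^2)
  continuous$lights <- new_like(proto, lights)

  # land cover: terciles of a smooth field, a built-up ring, urban mosaic
  lc_field <- smooth_field(n_rows, n_cols, smooth_range)
  q <- stats::quantile(lc_field, c(1 / 3, 2 / 3))
  lc <- matrix(11, n_rows, n_cols)
  lc[lc_field > q[1]] <- 40
  lc[lc_field > q[2]] <- 140
  lc[d_cells <= 1.5 * ur] <- 240
  landcover <- structure(new_like(proto, lc),
                         class = c("landcover_grid", class(proto)))
  landcover <- mosaic_urban(landcover, urban_extent)

  stack <- build_stack(landcover, continuous,
                       binary_features = list(urb = urban_extent),
                       mask = unit_raster)

  # ---- ground-truth density ------------------------------------------
  missing_fx <- setdiff(names(effect), names(stack))
  if (length(missing_fx)) stop("effect names absent from stack: ",
                               paste(missing_fx, collapse = ", "))
  eta <- matrix(base_log_density, n_rows, n_cols)
  for (nm in names(effect)) {
    z <- stack[[nm]]$values
    zs <- (z - mean(z)) / max(stats::sd(z), 1e-12)
    eta <- eta + effect[[nm]] * zs
  }
  if (noise_sd > 0) {
    nz <- smooth_field(n_rows, n_cols, max(2, smooth_range %/% 2))
    eta <- eta + noise_sd * nz
  }
  true_density <- new_like(proto, exp(eta))  # people per km2

  # ---- unit populations (hierarchy-exact integers) -------------------
  cell_km2 <- (cell_size / 1000)^2
  ids <- unit_raster$values
  raw <- tapply(true_density$values[!is.na(ids)] * cell_km2,
                ids[!is.na(ids)], sum)
  fine_raw <- as.numeric(raw[as.character(fine$units$unit_id)])
  fine_pop <- numeric(nrow(fine$units))
  for (p in unique(fine$units$parent_id)) {
    ch <- which(fine$units$parent_id == p)
    target <- round(sum(fine_raw[ch]))
    fine_pop[ch] <- largest_remainder(fine_raw[ch], target)
  }
  fine$units$population <- fine_pop
  check_hierarchy(fine)
  coarse <- aggregate_to_coarser(fine)

  structure(list(fine_units = fine, coarse_units = coarse, stack = stack,
                 true_density = true_density, unit_raster = unit_raster,
                 landcover = landcover, urban_extent = urban_extent,
                 continuous = continuous, seed = seed,
                 params = list(n_rows = n_rows, n_cols = n_cols,
                               n_coarse = n_coarse,
                               children_per_coarse = children_per_coarse,
                               effect = effect, noise_sd = noise_sd,
                               cell_size = cell_size,
                               base_log_density = base_log_density,
                               smooth_range = smooth_range,
                               urban_radius_cells = urban_radius_cells)),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world> seed %d: %d x %d cells, %d coarse / %d fine units, total pop %s\n",
              x$seed, x$params$n_rows, x$params$n_cols,
              nrow(x$coarse_units$units), nrow(x$fine_units$units),
              format(sum(x$fine_units$units$population), big.mark = ",")))
  invisible(x)
}

#' Draw a synthetic growth schedule
#'
#' Urban and rural per-annum rates drawn uniformly from stated ranges
#' (defaults: urban 0-4%/yr, rural -1-2%/yr). When a census-year surface
#' and urban mask are supplied, a consistent external total is computed as
#' the closed-form projected total
#' `U * exp(u * dt) + R * exp(r * dt)` times `perturbation`.
#'
#' @param seed integer seed.
#' @param census_year,target_year schedule years.
#' @param urban_range,rural_range uniform sampling ranges for the rates.
#' @param ppp optional census-year people-per-pixel surface.
#' @param urban_mask optional binary urban stratum grid.
#' @param perturbation multiplier on the closed-form total (1 = exactly
#'   consistent).
#' @return a [growth_schedule].
#' @export
make_growth_schedule <- function(seed, census_year = 2010, target_year = 2015,
                                 urban_range = c(0, 0.04),
                                 rural_range = c(-0.01, 0.02),
                                 ppp = NULL, urban_mask = NULL,
                                 perturbation = 1.0) {
  set.seed(seed)
  u <- stats::runif(1, urban_range[1], urban_range[2])
  r <- stats::runif(1, rural_range[1], rural_range[2])
  tot <- NULL
  if (!is.null(ppp) && !is.null(urban_mask)) {
    dt <- target_year - census_year
    urb <- !is.na(urban_mask$values) & urban_mask$values == 1
    v <- ppp$values
    U <- sum(v[urb], na.rm = TRUE)
    R <- sum(v[!urb], na.rm = TRUE)
    tot <- (U * exp(u * dt) + R * exp(r * dt)) * perturbation
  }
  growth_schedule(census_year, target_year, u, r, tot)
}

#' Write a synthetic world to pipeline input files
#'
#' Serializes the world in the formats the pipeline reads — units as
#' GeoJSON, rasters as ASCII grids, the census as CSV — so end-to-end runs
#' consume files, not in-memory objects.
#'
#' @param world a `synth_world`.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
world_to_files <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(units = file.path(dir, "units.geojson"),
                census = file.path(dir, "census.csv"),
                landcover = file.path(dir, "landcover.asc"),
                urban = file.path(dir, "urban.asc"))
  write_units_geojson(world$fine_units, paths$units)
  utils::write.csv(data.frame(unit_id = world$fine_units$units$unit_id,
                              population = world$fine_units$units$population),
                   paths$census, row.names = FALSE)
  write_grid_asc(world$landcover, paths$landcover)
  write_grid_asc(world$urban_extent, paths$urban)
  for (nm in names(world$continuous)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".asc"))
    write_grid_asc(world$continuous[[nm]], paths[[nm]])
  }
  invisible(paths)
}
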