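# small synthetic regression tables for direct forest checks
make_table <- function(n = 200, p_noise = 3, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  z <- data.frame(unit_id = seq_len(n), x1 = runif(n, -2, 2))
  for (k in seq_len(p_noise)) z[[paste0("n", k)]] <- rnorm(n)
  resp <- data.frame(unit_id = z$unit_id,
                     log_density = 2 + 1.5 * z$x1 + rnorm(n, sd = noise_sd))
  list(zonal = z, response = resp)
}

test_that("fit_forest learns a near-linear signal and reports sane OOB stats", {
  d <- make_table(200, seed = 3)
  m <- fit_forest(d$zonal, d$response, forest_params(n_trees = 300, seed = 5))
  expect_gt(m$pct_var_explained, 80)
  expect_gt(m$oob_mse, 0)
  expect_gt(m$importance[["x1"]], max(0, m$importance[c("n1", "n2", "n3")]))

  # tree ensembles cannot extrapolate beyond the training response range
  grid <- data.frame(x1 = seq(-10, 10, length.out = 50), n1 = 0, n2 = 0, n3 = 0)
  pr <- forest_predict(m, grid)
  expect_true(all(pr >= min(d$response$log_density) - 1e-12))
  expect_true(all(pr <= max(d$response$log_density) + 1e-12))
})

test_that("permutation importance of a constant covariate is exactly zero", {
  d <- make_table(80, seed = 7)
  d$zonal$const <- 1
  m <- fit_forest(d$zonal, d$response, forest_params(n_trees = 100, seed = 2))
  expect_identical(m$importance[["const"]], 0)
})

test_that("fits are bit-reproducible for a fixed seed", {
  d <- make_table(60, seed = 9)
  p <- forest_params(n_trees = 50, seed = 123)
  m1 <- fit_forest(d$zonal, d$response, p)
  m2 <- fit_forest(d$zonal, d$response, p)
  expect_identical(m1$importance, m2$importance)
  expect_identical(m1$oob_mse, m2$oob_mse)
  expect_identical(forest_predict(m1, d$zonal), forest_predict(m2, d$zonal))
})

test_that("fit_forest rejects degenerate inputs", {
  d <- make_table(10, seed = 1)
  expect_error(fit_forest(d$zonal[1, ], d$response[1, ], forest_params(n_trees = 5)),
               "at least 2")
  const <- d$response
  const$log_density <- 1
  m <- suppressMessages(
    fit_forest(d$zonal, const, forest_params(n_trees = 20, seed = 1)))
  expect_true(is.na(m$pct_var_explained))
})

test_that("select_covariates keeps informative and removes junk covariates", {
  d <- make_table(150, seed = 13)
  d$zonal$const <- 3.14
  sel <- select_covariates(d$zonal, d$response, forest_params(n_trees = 150, seed = 4))
  expect_false("const" %in% sel)
  expect_true("x1" %in% sel)
  trail <- attr(sel, "trail")
  expect_gte(length(trail), 1L)
  expect_true(all(c("covariate", "importance", "kept") %in% names(trail[[1]])))
  # spec contract: terminal set importances strictly positive on refit
  m <- fit_forest(d$zonal, d$response, forest_params(n_trees = 150, seed = 4),
                  covariates = as.character(sel))
  expect_true(all(m$importance > 0))
})

test_that("selection terminates within p iterations across seeds", {
  for (s in 1:5) {
    d <- make_table(60, p_noise = 4, seed = 100 + s)
    sel <- select_covariates(d$zonal, d$response,
                             forest_params(n_trees = 60, seed = s))
    trail <- attr(sel, "trail")
    expect_lte(length(trail), ncol(d$zonal) - 1L)
    expect_gte(length(sel), 1L)
  }
})

test_that("predict_density exponentiates the per-tree mean and stays positive", {
  w <- tiny_world(3, n_rows = 30, n_cols = 30, n_coarse = 2,
                  children_per_coarse = 2, smooth_range = 4,
                  urban_radius_cells = 4)
  zon <- zonal_aggregate(w$stack, w$unit_raster)
  resp <- log_density(w$fine_units)
  m <- fit_forest(zon, resp, forest_params(n_trees = 40, seed = 6))
  wl <- predict_density(m, w$stack, w$unit_raster)
  expect_true(all(wl$values[!is.na(wl$values)] > 0))
  expect_false(anyNA(wl$values[!is.na(w$unit_raster$values)]))

  # per-tree oracle on a handful of cells
  sel <- which(!is.na(w$unit_raster$values))[c(1, 57, 223, 600)]
  X <- as.data.frame(lapply(m$covariate_names, function(nm)
    w$stack[[nm]]$values[sel]))
  names(X) <- m$covariate_names
  per_tree <- forest_predict(m, X, per_tree = TRUE)
  expect_equal(wl$values[sel], exp(rowMeans(per_tree)), tolerance = 1e-12)

  # spatially constant covariates give a spatially constant layer
  const_stack <- w$stack
  for (nm in m$covariate_names) {
    g <- const_stack[[nm]]
    g$values[] <- mean(g$values)
    const_stack[[nm]] <- g
  }
  wl2 <- predict_density(m, const_stack, w$unit_raster)
  vals <- wl2$values[!is.na(wl2$values)]
  expect_lt(diff(range(vals)), 1e-12)
})

test_that("cross_predict equals self-donation and records provenance", {
  w <- tiny_world(4, n_rows = 30, n_cols = 30, n_coarse = 2,
                  children_per_coarse = 2, smooth_range = 4,
                  urban_radius_cells = 4)
  zon <- zonal_aggregate(w$stack, w$unit_raster)
  resp <- log_density(w$fine_units)
  m <- fit_forest(zon, resp, forest_params(n_trees = 30, seed = 8),
                  source_country = "AAA")
  self <- predict_density(m, w$stack, w$unit_raster)
  borrowed <- cross_predict(m, w$stack, w$unit_raster)
  expect_identical(borrowed$values, self$values)
  expect_identical(attr(borrowed, "source_country"), "AAA")

  # donor applied to a shifted covariate distribution stays positive
  shifted <- w$stack
  for (nm in names(shifted))
    if (!startsWith(nm, "cls_")) {
      g <- shifted[[nm]]
      g$values <- g$values + 2 * stats::sd(g$values)
      shifted[[nm]] <- g
    }
  wl <- cross_predict(m, shifted, w$unit_raster)
  expect_true(all(wl$values[!is.na(wl$values)] > 0))
})

test_that("covariate-driven worlds yield positive explained variance across seeds", {
  good <- 0L
  for (s in 1:10) {
    w <- tiny_world(700 + s, n_rows = 36, n_cols = 36, n_coarse = 3,
                    children_per_coarse = 3, smooth_range = 4,
                    urban_radius_cells = 4)
    zon <- zonal_aggregate(w$stack, w$unit_raster)
    resp <- log_density(w$fine_units)
    m <- fit_forest(zon, resp, forest_params(n_trees = 100, seed = s))
    vy <- mean((resp$log_density - mean(resp$log_density))^2)
    good <- good + (m$oob_mse < vy)
  }
  expect_gte(good, 9L)
})
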