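test_that("aggregate_to_coarser sums children and preserves totals", {
  w <- tiny_world(43, n_rows = 24, n_cols = 24, n_coarse = 2,
                  children_per_coarse = 2, smooth_range = 3,
                  urban_radius_cells = 3)
  coarse <- aggregate_to_coarser(w$fine_units)
  expect_equal(nrow(coarse$units), 2L)
  expect_equal(sum(coarse$units$population), sum(w$fine_units$units$population))
  expect_equal(coarse$units$level, rep(1L, 2))
  for (p in coarse$units$unit_id) {
    ch <- w$fine_units$units[w$fine_units$units$parent_id == p, ]
    expect_equal(coarse$units$population[coarse$units$unit_id == p],
                 sum(ch$population))
  }
  no_parents <- w$coarse_units
  expect_error(aggregate_to_coarser(no_parents), "parent")
})

test_that("unit_sums matches a naive per-unit loop", {
  set.seed(47)
  ids <- matrix(sample(c(NA, 1:6), 900, replace = TRUE), 30, 30)
  ur <- pop_grid(matrix(as.numeric(ids), 30, 30))
  g <- pop_grid(matrix(rexp(900), 30, 30))
  s <- unit_sums(g, ur)
  expect_equal(s$predicted, oracle_zonal_sum(g$values, ids), tolerance = 1e-12)

  v <- 2.5
  uni <- pop_grid(matrix(v, 30, 30))
  s2 <- unit_sums(uni, ur)
  counts <- as.numeric(table(ids))
  expect_equal(s2$predicted, v * counts)
})

test_that("error_stats reproduces hand-computed values and inequalities", {
  pred <- data.frame(unit_id = 1:3, predicted = c(12, 18, 33))
  obs <- data.frame(unit_id = 1:3, observed = c(10, 20, 30))
  r <- error_stats(pred, obs, "RF")
  expect_equal(r$rmse, sqrt(mean(c(2, -2, 3)^2)), tolerance = 1e-12)
  expect_equal(r$rmse, 2.38048, tolerance = 1e-5)
  expect_equal(r$mae, 2.33333, tolerance = 1e-5)
  expect_equal(r$pct_rmse, 11.9024, tolerance = 1e-4)

  perfect <- error_stats(data.frame(unit_id = 1:3, predicted = c(10, 20, 30)),
                         obs, "RF")
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$pct_rmse, 0)

  set.seed(53)
  for (rep in 1:10) {
    p2 <- data.frame(unit_id = 1:20, predicted = rexp(20, 1 / 100))
    o2 <- data.frame(unit_id = 1:20, observed = rexp(20, 1 / 100))
    r2 <- error_stats(p2, o2, "x")
    expect_gte(r2$rmse, r2$mae)
    expect_gte(r2$mae, 0)
  }
  expect_error(error_stats(pred[0, ], obs, "RF"), "empty")
})

test_that("avg_spatial_resolution follows the square-root formula", {
  expect_equal(avg_spatial_resolution(100, 4), 5)
  expect_equal(avg_spatial_resolution(436, 8), 7.3824, tolerance = 1e-4)
  expect_equal(avg_spatial_resolution(1000, 40),
               avg_spatial_resolution(1000, 10) / 2)
  expect_error(avg_spatial_resolution(-1, 4), "positive")
})

test_that("holdout_compare fits only on coarse units and conserves mass", {
  w <- tiny_world(59, n_coarse = 6, children_per_coarse = 4)
  res <- holdout_compare(w$fine_units, w$stack,
                         forest_params(n_trees = 60, seed = 59),
                         unit_raster = w$unit_raster, select = FALSE)
  # no fine-count leakage: the model saw exactly the coarse units
  expect_equal(length(res$model$oob_pred), nrow(w$coarse_units$units))
  expect_setequal(res$model$response$unit_id, w$coarse_units$units$unit_id)
  expect_identical(res$rf$method, "RF")
  expect_identical(res$saw$method, "SAW")
  expect_true(is.na(res$saw$oob_mse))
  expect_equal(res$rf$n_units, nrow(w$fine_units$units))

  expect_error(holdout_compare(w$coarse_units, w$stack), "parent")
})

test_that("with a constant weighting layer the two methods coincide", {
  w <- tiny_world(61, n_rows = 24, n_cols = 24, n_coarse = 2,
                  children_per_coarse = 2, smooth_range = 3,
                  urban_radius_cells = 3)
  coarse <- aggregate_to_coarser(w$fine_units)
  coarse_r <- dasypop:::relabel_by_parent(w$unit_raster, w$fine_units)
  const <- pop_grid(matrix(2, 24, 24), origin = w$unit_raster$origin)
  rf_grid <- disaggregate(coarse, coarse_r, const)
  saw_grid <- saw_disaggregate(coarse, coarse_r)
  obs <- data.frame(unit_id = w$fine_units$units$unit_id,
                    observed = w$fine_units$units$population)
  a <- error_stats(unit_sums(rf_grid, w$unit_raster), obs, "RF")
  b <- error_stats(unit_sums(saw_grid, w$unit_raster), obs, "SAW")
  expect_equal(a$rmse, b$rmse, tolerance = 1e-9)
  expect_equal(a$mae, b$mae, tolerance = 1e-9)
})

test_that("oob_intervals are the 2.5/97.5 percentiles of per-tree OOB preds", {
  d <- data.frame(unit_id = 1:40, x1 = runif(40))
  resp <- data.frame(unit_id = 1:40, log_density = 1 + d$x1 + rnorm(40, sd = 0.05))
  m <- fit_forest(d, resp, forest_params(n_trees = 80, seed = 67))
  iv <- oob_intervals(m)
  M <- m$oob_tree_pred
  for (i in c(1, 17, 40)) {
    r <- M[i, !is.na(M[i, ])]
    expect_equal(iv$lower[i], as.numeric(quantile(r, 0.025)), tolerance = 1e-12)
    expect_equal(iv$upper[i], as.numeric(quantile(r, 0.975)), tolerance = 1e-12)
  }
  expect_true(all(iv$upper >= iv$lower, na.rm = TRUE))
})

test_that("metadata_report contains the four required items", {
  d <- data.frame(unit_id = 1:30, x1 = runif(30), x2 = rnorm(30))
  resp <- data.frame(unit_id = 1:30, log_density = 1 + d$x1 + rnorm(30, 0.05))
  m <- fit_forest(d, resp, forest_params(n_trees = 40, seed = 71),
                  source_country = "CRI")
  p <- withr::local_tempfile(fileext = ".html")
  metadata_report(m, path = p,
                  provenance = data.frame(input = "units", path = "units.geojson"))
  html <- paste(readLines(p), collapse = "\n")
  expect_match(html, "CRI")
  expect_match(html, sprintf("%.6g", m$oob_mse), fixed = TRUE)
  expect_match(html, "Covariate importance")
  expect_match(html, "OOB prediction intervals")
  # importances sorted descending
  imp_order <- names(sort(m$importance, decreasing = TRUE))
  pos <- vapply(imp_order, function(nm)
    regexpr(paste0("<td>", nm, "</td>"), html, fixed = TRUE)[[1]], 0)
  expect_true(all(diff(pos) > 0))
})
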