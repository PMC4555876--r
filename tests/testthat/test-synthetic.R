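test_that("make_landscape is deterministic and hierarchy-exact", {
  w1 <- tiny_world(101, n_rows = 40, n_cols = 40, n_coarse = 2,
                   children_per_coarse = 4, smooth_range = 5,
                   urban_radius_cells = 5)
  w2 <- tiny_world(101, n_rows = 40, n_cols = 40, n_coarse = 2,
                   children_per_coarse = 4, smooth_range = 5,
                   urban_radius_cells = 5)
  expect_identical(w1$true_density$values, w2$true_density$values)
  expect_identical(w1$fine_units$units, w2$fine_units$units)
  expect_identical(lapply(w1$stack, function(g) g$values),
                   lapply(w2$stack, function(g) g$values))

  # coarse populations equal the sum of their children exactly
  for (p in w1$coarse_units$units$unit_id) {
    ch <- w1$fine_units$units[w1$fine_units$units$parent_id == p, ]
    expect_identical(sum(ch$population),
                     w1$coarse_units$units$population[
                       w1$coarse_units$units$unit_id == p])
  }
  expect_true(all(w1$true_density$values >= 0))
  expect_true(all(w1$fine_units$units$population ==
                    round(w1$fine_units$units$population)))
})

test_that("zero effects and zero noise give a flat world where RF ~ SAW", {
  w <- tiny_world(103, n_rows = 40, n_cols = 40, n_coarse = 4,
                  children_per_coarse = 2, smooth_range = 5,
                  urban_radius_cells = 5,
                  effect = c(lights = 0), noise_sd = 0)
  v <- w$true_density$values
  expect_lt(diff(range(v)) / mean(v), 1e-12)
  # per-cell truth is uniform, so unit counts are area-proportional
  counts <- as.numeric(table(w$unit_raster$values))
  pops <- w$fine_units$units$population[
    match(as.numeric(names(table(w$unit_raster$values))),
          w$fine_units$units$unit_id)]
  expected <- counts * sum(pops) / sum(counts)
  expect_lte(max(abs(pops - expected)), 1)  # largest-remainder rounding only
})

test_that("generated worlds satisfy downstream type invariants", {
  w <- tiny_world(107, n_rows = 36, n_cols = 48, n_coarse = 6,
                  children_per_coarse = 4, smooth_range = 4,
                  urban_radius_cells = 4)
  expect_s3_class(w$fine_units, "admin_set")
  expect_s3_class(w$stack, "cov_stack")
  # every fine unit owns >= 4 cells
  expect_gte(min(table(w$unit_raster$values)), 4)
  # landcover uses only the working class codes
  expect_true(all(w$landcover$values %in% c(11, 40, 140, 190, 240)))
  # urban core exists and is mosaicked to class 190
  expect_true(any(w$landcover$values == 190))
  expect_identical(which(w$landcover$values == 190),
                   which(w$urban_extent$values == 1))
})

test_that("growth schedules stay in range and are closed-form consistent", {
  set.seed(1)
  for (s in sample.int(1e6, 200)) {
    sch <- make_growth_schedule(s)
    expect_gte(sch$urban_rate, 0);  expect_lte(sch$urban_rate, 0.04)
    expect_gte(sch$rural_rate, -0.01); expect_lte(sch$rural_rate, 0.02)
  }

  sch0 <- make_growth_schedule(5, urban_range = c(0, 0), rural_range = c(0, 0))
  expect_identical(sch0$urban_rate, 0)
  expect_identical(sch0$rural_rate, 0)

  w <- tiny_world(109, n_rows = 30, n_cols = 30, n_coarse = 2,
                  children_per_coarse = 2, smooth_range = 4,
                  urban_radius_cells = 4)
  ppp <- saw_disaggregate(w$fine_units, w$unit_raster)
  sch <- make_growth_schedule(7, 2010, 2020, ppp = ppp,
                              urban_mask = w$urban_extent, perturbation = 1.0)
  proj <- project_population(ppp, w$urban_extent, sch)
  expect_equal(sum(proj$values, na.rm = TRUE), sch$unpd_total,
               tolerance = 1e-9)
})

test_that("the pipeline recovers ground truth on a low-noise world", {
  # 48 fine units: recoverability needs a training sample adequate for the
  # forest (see the methods vignette)
  w <- tiny_world(113, noise_sd = 0.05, n_coarse = 12, children_per_coarse = 4)
  zon <- zonal_aggregate(w$stack, w$unit_raster)
  resp <- log_density(w$fine_units)
  m <- fit_forest(zon, resp, forest_params(n_trees = 500, seed = 113))
  wl <- predict_density(m, w$stack, w$unit_raster)
  ppp <- disaggregate(w$fine_units, w$unit_raster, wl)
  cell_km2 <- (w$unit_raster$cell_size / 1000)^2
  truth <- w$true_density$values * cell_km2
  sel <- !is.na(ppp$values)
  expect_gt(stats::cor(ppp$values[sel], truth[sel]), 0.9)
})
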