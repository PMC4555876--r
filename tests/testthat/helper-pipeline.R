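# assemble a complete on-disk pipeline fixture from a synthetic world
pipeline_fixture <- function(seed, dir, n_trees = 60, world = NULL,
                             unadj_years = c(2015, 2020, 2025), ...) {
  world <- if (is.null(world)) make_landscape(seed, ...) else world
  paths <- world_to_files(world, dir)
  cy <- world$fine_units$census_year
  ppp <- saw_disaggregate(world$fine_units, world$unit_raster)
  sch <- lapply(seq_along(unadj_years), function(i)
    make_growth_schedule(seed + i, cy, unadj_years[i], ppp = ppp,
                         urban_mask = world$urban_extent, perturbation = 1.02))
  sched_path <- file.path(dir, "schedule.csv")
  write.csv(data.frame(
    census_year = cy,
    target_year = vapply(sch, `[[`, 0L, "target_year"),
    urban_rate = vapply(sch, `[[`, 0, "urban_rate"),
    rural_rate = vapply(sch, `[[`, 0, "rural_rate"),
    unpd_total = vapply(sch, `[[`, 0, "unpd_total")),
    sched_path, row.names = FALSE)
  list(world = world,
       config = list(iso = world$fine_units$country_code, version = "1",
                     units_path = paths$units,
                     landcover_path = paths$landcover,
                     urban_path = paths$urban,
                     continuous_paths = list(elev = paths$elev,
                                             tmean = paths$tmean,
                                             precip = paths$precip,
                                             lights = paths$lights),
                     schedule_path = sched_path,
                     cell_size = world$params$cell_size,
                     buffer_m = 0,  # synthetic units tessellate the grid
                     n_trees = n_trees, seed = seed,
                     out_dir = file.path(dir, "out")))
}
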