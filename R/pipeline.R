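#' Run configuration
#'
#' Binds input paths and settings for an end-to-end run. A config is a
#' plain list (or a JSON file holding one) with fields:
#' \describe{
#'   \item{iso}{3-letter country code used in output names.}
#'   \item{version}{version tag in output names (default `"1"`).}
#'   \item{units_path}{GeoJSON of admin units ([write_units_geojson()]
#'     layout).}
#'   \item{census_path}{optional CSV `unit_id,population` joined onto the
#'     units.}
#'   \item{landcover_path, urban_path}{ASCII-grid land cover and binary
#'     urban extent.}
#'   \item{continuous_paths}{named list of ASCII-grid continuous
#'     covariates.}
#'   \item{binary_paths}{named list of ASCII-grid binary feature layers.}
#'   \item{recode_path}{optional CSV `from,to` applied to the land cover.}
#'   \item{schedule_path}{CSV read by [read_growth_schedule()].}
#'   \item{cell_size}{working resolution in metres (default 100).}
#'   \item{buffer_m}{outward study-area buffer in metres (default 10000).}
#'   \item{n_trees, terminal_node_size, covariates_per_split, seed}{forest
#'     settings.}
#'   \item{growth_law}{`"exponential"` (default) or `"geometric"`.}
#'   \item{urban_stratum}{`"190"` (default) or `"BLT"`: which built-up
#'     cells grow at the urban rate.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config list or path to a JSON file.
#' @return validated config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(version = "1", cell_size = 100, buffer_m = 10000,
                   n_trees = 500, terminal_node_size = 1,
                   covariates_per_split = NULL, seed = 1L,
                   growth_law = "exponential", urban_stratum = "190",
                   census_path = NULL, recode_path = NULL,
                   binary_paths = list(), min_units = 10L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  req <- c("iso", "units_path", "landcover_path", "urban_path",
           "continuous_paths", "schedule_path", "out_dir")
  miss <- req[vapply(req, function(k) is.null(config[[k]]), TRUE)]
  if (length(miss)) stop("config lacks fields: ", paste(miss, collapse = ", "))
  if (!nzchar(config$version)) stop("version tag must be non-empty")
  for (p in c(config$units_path, config$landcover_path, config$urban_path,
              unlist(config$continuous_paths), unlist(config$binary_paths),
              config$schedule_path, config$census_path, config$recode_path))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  config
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

product_name <- function(iso, kind, version, year, unadj = FALSE) {
  sprintf("%s_%s_v%s_%s%s.asc", iso, kind, version, year,
          if (unadj) "_UNadj" else "")
}

#' Run the full dasymetric mapping pipeline
#'
#' Executes prepare (rasterize, stack, zonal, response), fit (covariate
#' elimination + final forest), predict (weighting layer), disaggregate
#' (people per pixel and per hectare for the census year), project (each
#' scheduled target year via urban/rural growth rates), adjust (to the
#' scheduled external totals), and report (HTML model metadata). Writes
#' the full product suite
#' `<ISO>_{ppp|pph}_v<ver>_<YEAR>[_UNadj].asc` plus `<ISO>_metadata.html`
#' and returns a manifest of files with MD5 checksums.
#'
#' @param config a [run_config()] list or JSON path.
#' @return data.frame manifest (`file`, `md5`), invisibly with attributes
#'   `model` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  units <- pipeline_stage("read-units", {
    u <- read_units_geojson(cfg$units_path)
    if (!is.null(cfg$census_path)) u <- join_census(u, cfg$census_path)
    u
  })
  fine_level <- max(units$units$level)
  fine <- admin_level(units, fine_level)

  prep <- pipeline_stage("prepare", {
    landcover <- read_grid_asc(cfg$landcover_path)
    if (!is.null(cfg$recode_path))
      landcover <- recode_landcover(landcover, utils::read.csv(cfg$recode_path))
    class(landcover) <- unique(c("landcover_grid", class(landcover)))
    urban <- read_grid_asc(cfg$urban_path)
    landcover <- mosaic_urban(landcover, urban)
    continuous <- lapply(cfg$continuous_paths, read_grid_asc)
    binaries <- lapply(cfg$binary_paths, read_grid_asc)
    extent <- NULL
    if (cfg$buffer_m > 0) {
      # processing extent padded so distance covariates escape edge effects
      bbs <- vapply(buffer_region(fine, cfg$buffer_m), polygon_bbox, numeric(4))
      extent <- c(min(bbs[1, ]), min(bbs[2, ]), max(bbs[3, ]), max(bbs[4, ]))
    }
    mask <- rasterize_units(fine, cell_size = cfg$cell_size, extent = extent)
    align_to_mask <- function(g, nm) {
      if (!grids_aligned(g, mask))
        stop("raster '", nm, "' is not aligned with the rasterized study area")
      g
    }
    landcover <- align_to_mask(landcover, "landcover")
    stack <- build_stack(landcover, continuous, binaries, mask)
    list(mask = mask, stack = stack, landcover = landcover, urban = urban)
  })

  fit <- pipeline_stage("fit", {
    zonal <- zonal_aggregate(prep$stack, prep$mask)
    resp <- log_density(fine)
    check_enough_units(nrow(resp), cfg$min_units)
    params <- forest_params(cfg$n_trees, cfg$terminal_node_size,
                            cfg$covariates_per_split, cfg$seed)
    covs <- select_covariates(zonal, resp, params, source_country = cfg$iso)
    model <- fit_forest(zonal, resp, params, covariates = as.character(covs),
                        source_country = cfg$iso)
    message(sprintf("model: %d/%d covariates kept, OOB MSE %.4g, %%var %.1f (mtry %d, %s growth, urban stratum %s)",
                    length(model$covariate_names), ncol(zonal) - 1L,
                    model$oob_mse, model$pct_var_explained, model$mtry,
                    cfg$growth_law, cfg$urban_stratum))
    list(model = model, trail = attr(covs, "trail"))
  })

  weights <- pipeline_stage("predict",
    predict_density(fit$model, prep$stack, prep$mask))

  ppp <- pipeline_stage("disaggregate", disaggregate(fine, prep$mask, weights))

  urban_stratum <- pipeline_stage("stratum", {
    if (identical(cfg$urban_stratum, "BLT")) built_up_class(prep$landcover)
    else class_binary(prep$landcover, 190)
  })

  outputs <- list()
  add_out <- function(outputs, grid, kind, year, unadj = FALSE) {
    outputs[[product_name(cfg$iso, kind, cfg$version, year, unadj)]] <- grid
    outputs
  }
  outputs <- add_out(outputs, ppp, "ppp", units$census_year)
  outputs <- add_out(outputs, people_per_hectare(ppp), "pph", units$census_year)

  schedules <- pipeline_stage("read-schedule", read_growth_schedule(cfg$schedule_path))
  for (sch in schedules) {
    proj <- pipeline_stage(paste0("project-", sch$target_year),
      project_population(ppp, urban_stratum, sch, law = cfg$growth_law))
    outputs <- add_out(outputs, proj, "ppp", sch$target_year)
    outputs <- add_out(outputs, people_per_hectare(proj), "pph", sch$target_year)
    if (!is.null(sch$unpd_total)) {
      adj <- pipeline_stage(paste0("adjust-", sch$target_year),
        unpd_adjust(proj, sch$unpd_total))
      outputs <- add_out(outputs, adj, "ppp", sch$target_year, unadj = TRUE)
      outputs <- add_out(outputs, people_per_hectare(adj), "pph",
                         sch$target_year, unadj = TRUE)
    }
  }

  report_path <- file.path(cfg$out_dir, sprintf("%s_metadata.html", cfg$iso))
  pipeline_stage("report",
    metadata_report(fit$model, path = report_path,
                    selection_trail = fit$trail,
                    provenance = data.frame(
                      input = c("units", "landcover", "urban extent",
                                names(cfg$continuous_paths)),
                      path = c(cfg$units_path, cfg$landcover_path,
                               cfg$urban_path,
                               unlist(cfg$continuous_paths)))))

  files <- character()
  for (nm in names(outputs)) {
    p <- file.path(cfg$out_dir, nm)
    write_grid_asc(outputs[[nm]], p)
    files <- c(files, p)
  }
  files <- c(files, report_path)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "model") <- fit$model
  attr(manifest, "out_dir") <- cfg$out_dir
  invisible(manifest)
}

#' Run the coarse-to-fine holdout validation
#'
#' Invokes [holdout_compare()] on the configured inputs and writes both
#' method rows as a delimited table (`method`, `unit_level`, `n_units`,
#' `oob_mse`, `pct_var_explained`, `rmse`, `pct_rmse`, `mae`); the SAW row
#' leaves the model-fit columns empty.
#'
#' @param config a [run_config()] list or JSON path.
#' @return list from [holdout_compare()], invisibly, with attribute
#'   `table_path`.
#' @export
run_validation <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  units <- read_units_geojson(cfg$units_path)
  if (!is.null(cfg$census_path)) units <- join_census(units, cfg$census_path)
  fine <- admin_level(units, max(units$units$level))

  landcover <- read_grid_asc(cfg$landcover_path)
  class(landcover) <- unique(c("landcover_grid", class(landcover)))
  landcover <- mosaic_urban(landcover, read_grid_asc(cfg$urban_path))
  continuous <- lapply(cfg$continuous_paths, read_grid_asc)
  binaries <- lapply(cfg$binary_paths, read_grid_asc)
  mask <- rasterize_units(fine, cell_size = cfg$cell_size)
  stack <- build_stack(landcover, continuous, binaries, mask)

  params <- forest_params(cfg$n_trees, cfg$terminal_node_size,
                          cfg$covariates_per_split, cfg$seed)
  res <- holdout_compare(fine, stack, params, unit_raster = mask)
  tab <- rbind(res$rf, res$saw)
  path <- file.path(cfg$out_dir, sprintf("%s_validation.csv", cfg$iso))
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  attr(res, "table_path") <- path
  invisible(res)
}
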