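#' Aggregate a fine admin level to its parents
#'
#' One unit per parent: population summed over children, geometry the
#' multipolygon collection of the children's parts, area summed, level
#' decremented. Total population is preserved exactly.
#'
#' @param fine an [admin_set] whose units carry `parent_id` links.
#' @return an [admin_set] at the coarser level.
#' @export
aggregate_to_coarser <- function(fine) {
  u <- fine$units
  if (all(is.na(u$parent_id))) stop("fine units carry no parent links")
  if (anyNA(u$parent_id)) stop("some units lack parent links")
  parents <- sort(unique(u$parent_id))
  rows <- lapply(parents, function(p) {
    ch <- u[u$parent_id == p, , drop = FALSE]
    data.frame(unit_id = p, level = ch$level[1] - 1L,
               population = sum(ch$population),
               area_km2 = sum(ch$area_km2), parent_id = NA_integer_)
  })
  geometry <- lapply(parents, function(p) {
    ids <- as.character(u$unit_id[u$parent_id == p])
    unlist(fine$geometry[ids], recursive = FALSE)
  })
  admin_set(do.call(rbind, rows), geometry, fine$census_year,
            fine$country_code)
}

#' Sum a population surface within each admin unit
#'
#' @param grid a population [pop_grid].
#' @param unit_raster the aligned unit raster of the validation units.
#' @return data.frame with columns `unit_id`, `predicted`.
#' @export
unit_sums <- function(grid, unit_raster) {
  stopifnot_aligned(grid, unit_raster, "grid and unit raster")
  ids <- unit_raster$values
  sel <- which(!is.na(ids))
  f <- factor(ids[sel])
  v <- grid$values[sel]
  v[is.na(v)] <- 0
  data.frame(unit_id = as.numeric(levels(f)),
             predicted = as.numeric(rowsum(v, f)))
}

#' Prediction-error statistics over validation units
#'
#' RMSE, MAE, and RMSE expressed as a percentage of the mean observed
#' population of the validation units
#' (`100 * rmse / mean(observed)`).
#'
#' @param predicted data.frame with `unit_id` and `predicted`.
#' @param observed data.frame with `unit_id` and `observed` (or
#'   `population`).
#' @param method_label `"RF"` or `"SAW"` (free-form).
#' @param unit_level optional admin level of the validation units.
#' @param oob_mse,pct_var_explained optional model-fit statistics carried
#'   into the report (RF rows only).
#' @return a one-row data.frame of class `validation_report` with columns
#'   `method`, `unit_level`, `n_units`, `oob_mse`, `pct_var_explained`,
#'   `rmse`, `pct_rmse`, `mae`.
#' @export
error_stats <- function(predicted, observed, method_label,
                        unit_level = NA_integer_, oob_mse = NA_real_,
                        pct_var_explained = NA_real_) {
  if (!"observed" %in% names(observed) && "population" %in% names(observed))
    observed$observed <- observed$population
  stopifnot(all(c("unit_id", "predicted") %in% names(predicted)),
            all(c("unit_id", "observed") %in% names(observed)))
  if (nrow(predicted) == 0L || nrow(observed) == 0L) stop("empty input tables")
  m <- match(observed$unit_id, predicted$unit_id)
  if (anyNA(m)) stop("unit ids differ between predicted and observed")
  err <- predicted$predicted[m] - observed$observed
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  mo <- mean(observed$observed)
  if (mo == 0) stop("mean observed population is zero; %RMSE undefined")
  out <- data.frame(method = method_label, unit_level = unit_level,
                    n_units = length(err), oob_mse = oob_mse,
                    pct_var_explained = pct_var_explained,
                    rmse = rmse, pct_rmse = 100 * rmse / mo, mae = mae)
  class(out) <- c("validation_report", class(out))
  out
}

#' Coarse-to-fine holdout comparison of RF and SAW disaggregation
#'
#' The validation design: fine-level counts are aggregated to the next
#' coarser level; a forest is fitted on the coarse units only (the fine
#' counts never enter fitting); the coarse counts are disaggregated to the
#' grid by the forest weighting layer and by simple areal weighting; both
#' grids are summed back over the fine units and compared with the observed
#' fine counts.
#'
#' @param fine an [admin_set] with parent links.
#' @param stack the `cov_stack` over the study area.
#' @param params a [forest_params].
#' @param unit_raster optional fine-unit raster aligned with the stack
#'   (rasterized from `fine` at the stack's resolution when omitted).
#' @param select run iterative covariate elimination before the final fit.
#' @return list with elements `rf` and `saw` ([error_stats()] rows), and
#'   `model` (the coarse-level `pop_forest`).
#' @export
holdout_compare <- function(fine, stack, params = forest_params(),
                            unit_raster = NULL, select = TRUE) {
  if (all(is.na(fine$units$parent_id))) stop("fine units carry no parent links")
  if (length(unique(fine$units$parent_id)) < 2L)
    stop("degenerate hierarchy: need at least two parent units")
  if (is.null(unit_raster))
    unit_raster <- rasterize_units(fine, cell_size = stack[[1]]$cell_size)
  stopifnot_aligned(unit_raster, stack[[1]], "unit raster and stack")

  coarse <- aggregate_to_coarser(fine)
  coarse_raster <- relabel_by_parent(unit_raster, fine)
  zonal <- zonal_aggregate(stack, coarse_raster)
  resp <- log_density(coarse)

  covs <- if (select) select_covariates(zonal, resp, params,
                                        source_country = fine$country_code)
          else covariate_columns(zonal)
  model <- fit_forest(zonal, resp, params, covariates = as.character(covs),
                      source_country = fine$country_code)
  weights <- predict_density(model, stack, coarse_raster)

  rf_grid <- disaggregate(coarse, coarse_raster, weights)
  saw_grid <- saw_disaggregate(coarse, coarse_raster)

  obs <- data.frame(unit_id = fine$units$unit_id,
                    observed = fine$units$population)
  lvl <- fine$units$level[1]
  rf_rep <- error_stats(unit_sums(rf_grid, unit_raster), obs, "RF",
                        unit_level = lvl, oob_mse = model$oob_mse,
                        pct_var_explained = model$pct_var_explained)
  saw_rep <- error_stats(unit_sums(saw_grid, unit_raster), obs, "SAW",
                         unit_level = lvl)
  list(rf = rf_rep, saw = saw_rep, model = model,
       selection_trail = attr(covs, "trail"))
}

#' Average spatial resolution of an administrative partition
#'
#' The effective cell size of a set of units: the square root of the
#' surface area divided by the number of units (the cell size the units
#' would have if all were equal squares).
#'
#' @param area_km2 total surface area in square kilometres.
#' @param n_units number of administrative units.
#' @return resolution in kilometres.
#' @export
avg_spatial_resolution <- function(area_km2, n_units) {
  if (area_km2 <= 0 || n_units <= 0) stop("inputs must be positive")
  sqrt(area_km2 / n_units)
}

#' OOB prediction intervals per unit
#'
#' Central 95% interval (2.5th-97.5th percentile) of the per-tree
#' out-of-bag predictions for each training unit.
#'
#' @param model a `pop_forest` fitted with OOB tree predictions retained.
#' @param probs interval quantiles.
#' @return data.frame `unit_id`, `oob_mean`, `lower`, `upper` (log-density
#'   scale; `NA` for units never out of bag).
#' @export
oob_intervals <- function(model, probs = c(0.025, 0.975)) {
  M <- model$oob_tree_pred
  qs <- t(apply(M, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(c(NA_real_, NA_real_))
    stats::quantile(r, probs = probs, names = FALSE)
  }))
  data.frame(unit_id = model$response$unit_id,
             oob_mean = as.numeric(model$oob_pred),
             lower = qs[, 1], upper = qs[, 2])
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(df, 1L, function(r)
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table border='1' cellspacing='0' cellpadding='3'>", head,
         paste(rows, collapse = "\n"), "</table>")
}

#' Model metadata report
#'
#' Writes a self-contained HTML report describing (i) the country the model
#' is based on, (ii) its prediction error (OOB MSE and % variance
#' explained), (iii) the relative importance of each covariate (sorted
#' descending), and (iv) the per-unit OOB prediction intervals, plus the
#' covariate-elimination audit trail and input-dataset provenance.
#'
#' @param model a `pop_forest`.
#' @param reports optional list/data.frame of [error_stats()] rows.
#' @param provenance optional data.frame describing input datasets.
#' @param path output `.html` file.
#' @param selection_trail optional trail from [select_covariates()].
#' @return `path`, invisibly.
#' @export
metadata_report <- function(model, reports = NULL, provenance = NULL,
                            path, selection_trail = NULL) {
  imp <- sort(model$importance, decreasing = TRUE)
  parts <- c(
    "<html><head><title>Density model metadata</title></head><body>",
    sprintf("<h1>Population density model &mdash; %s</h1>",
            html_escape(model$source_country)),
    sprintf("<p>Source country: <b>%s</b></p>", html_escape(model$source_country)),
    "<h2>Prediction error</h2>",
    sprintf("<p>OOB MSE (log density): <b>%.6g</b><br/>%% variance explained: <b>%.2f</b><br/>Trees: %d, covariates per split: %d, terminal node size: %d, seed: %d</p>",
            model$oob_mse, model$pct_var_explained, length(model$trees),
            model$mtry, model$params$terminal_node_size, model$params$seed),
    "<h2>Covariate importance</h2>",
    html_table(data.frame(covariate = names(imp),
                          importance = as.numeric(imp))),
    "<h2>OOB prediction intervals (95%, log density)</h2>",
    html_table(oob_intervals(model)))
  if (!is.null(selection_trail)) {
    parts <- c(parts, "<h2>Covariate elimination audit trail</h2>")
    for (i in seq_along(selection_trail))
      parts <- c(parts, sprintf("<h3>Iteration %d</h3>", i),
                 html_table(selection_trail[[i]]))
  }
  if (!is.null(reports)) {
    rep_df <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
    parts <- c(parts, "<h2>Validation</h2>", html_table(rep_df))
  }
  if (!is.null(provenance))
    parts <- c(parts, "<h2>Input datasets</h2>", html_table(provenance))
  parts <- c(parts, "</body></html>")
  writeLines(parts, path)
  invisible(path)
}
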