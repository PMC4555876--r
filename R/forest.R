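#' Forest hyperparameters
#'
#' Defaults follow the production configuration: 500 trees, terminal node
#' size 1 (trees grown to purity), and the regression default of `p/3`
#' covariates tried at each split (chosen at fit time when `NULL`).
#'
#' @param n_trees number of trees.
#' @param terminal_node_size minimum observations in a terminal node.
#' @param covariates_per_split covariates sampled at each split (`mtry`);
#'   `NULL` means `max(1, floor(p / 3))`.
#' @param seed integer seed making fits bit-reproducible.
#' @return a list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, terminal_node_size = 1,
                          covariates_per_split = NULL, seed = 1L) {
  stopifnot(n_trees >= 1, terminal_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 terminal_node_size = as.integer(terminal_node_size),
                 covariates_per_split = covariates_per_split,
                 seed = as.integer(seed)),
            class = "forest_params")
}

covariate_columns <- function(zonal) setdiff(names(zonal), "unit_id")

make_xy <- function(zonal, response, covariates = NULL) {
  m <- match(response$unit_id, zonal$unit_id)
  if (anyNA(m)) stop("response contains unit ids absent from the zonal table")
  covs <- if (is.null(covariates)) covariate_columns(zonal) else covariates
  missing <- setdiff(covs, names(zonal))
  if (length(missing)) stop("zonal table lacks covariates: ",
                            paste(missing, collapse = ", "))
  X <- as.matrix(zonal[m, covs, drop = FALSE])
  if (!is.numeric(X)) stop("covariate columns must be numeric")
  if (anyNA(X)) stop("NA in covariate columns")
  list(X = X, y = response$log_density, covs = covs)
}

#' Fit the density-weighting forest
#'
#' Bootstrap-aggregated regression trees on the per-unit covariate table,
#' response = log population density. Reports the out-of-bag (OOB) mean
#' squared error, the percentage of response variance it explains
#' (`100 * (1 - oob_mse / var(y))`), and OOB permutation importance per
#' covariate (mean increase in OOB MSE when that covariate's out-of-bag
#' values are shuffled).
#'
#' @param zonal data.frame from [zonal_aggregate()].
#' @param response data.frame from [log_density()].
#' @param params a [forest_params] object.
#' @param covariates optional character vector restricting the covariate
#'   set (e.g. the output of [select_covariates()]).
#' @param source_country provenance tag carried into predictions and
#'   reports.
#' @return an object of class `pop_forest`.
#' @export
fit_forest <- function(zonal, response, params = forest_params(),
                       covariates = NULL, source_country = "SYN") {
  xy <- make_xy(zonal, response, covariates)
  n <- nrow(xy$X); p <- ncol(xy$X)
  if (n < 2) stop("need at least 2 units with a finite response")
  mtry <- params$covariates_per_split
  if (is.null(mtry)) mtry <- max(1L, p %/% 3L)
  mtry <- min(as.integer(mtry), p)
  set.seed(params$seed)
  fit <- .rf_fit_cpp(xy$X, xy$y, params$n_trees, mtry,
                     params$terminal_node_size, TRUE)
  imp <- stats::setNames(as.numeric(fit$importance), xy$covs)
  vy <- mean((xy$y - mean(xy$y))^2)
  pct <- if (vy > 0) 100 * (1 - fit$oob_mse / vy) else NA_real_
  if (vy == 0) message("constant response: % variance explained unavailable")
  structure(list(trees = fit$trees,
                 covariate_names = xy$covs,
                 importance = imp,
                 oob_mse = fit$oob_mse,
                 pct_var_explained = pct,
                 oob_pred = stats::setNames(as.numeric(fit$oob_pred),
                                            response$unit_id),
                 oob_tree_pred = fit$oob_tree_pred,
                 response = response,
                 mtry = mtry,
                 params = params,
                 source_country = source_country),
            class = "pop_forest")
}

#' @export
print.pop_forest <- function(x, ...) {
  cat(sprintf("<pop_forest> %s: %d trees, mtry %d, %d covariates\n",
              x$source_country, length(x$trees), x$mtry,
              length(x$covariate_names)))
  cat(sprintf("  OOB MSE %.4g, %% variance explained %.1f\n",
              x$oob_mse, x$pct_var_explained))
  invisible(x)
}

#' Predict with a fitted forest on new rows
#'
#' Mean over trees of the per-tree predicted log density; with
#' `per_tree = TRUE`, the full rows-by-trees prediction matrix.
#'
#' @param model a `pop_forest`.
#' @param newdata data.frame or matrix holding the model's covariates.
#' @param per_tree return the per-tree matrix instead of the mean.
#' @return numeric vector (or matrix) of log-density predictions.
#' @export
forest_predict <- function(model, newdata, per_tree = FALSE) {
  X <- as.matrix(as.data.frame(newdata)[, model$covariate_names, drop = FALSE])
  if (anyNA(X)) stop("NA in prediction covariates")
  if (per_tree) .rf_predict_all_cpp(model$trees, X)
  else .rf_predict_cpp(model$trees, X)
}

#' Iterative covariate elimination
#'
#' The conservative selection loop: fit on all covariates, drop every
#' covariate whose permutation importance is zero or negative, refit, and
#' repeat until every remaining covariate has strictly positive importance
#' (or a single covariate remains). Eliminates redundant covariates and
#' covariates that would degrade the prediction.
#'
#' @inheritParams fit_forest
#' @return character vector of selected covariate names, with attribute
#'   `trail`: a list of per-iteration data.frames (`covariate`,
#'   `importance`, `kept`).
#' @export
select_covariates <- function(zonal, response, params = forest_params(),
                              source_country = "SYN") {
  covs <- covariate_columns(zonal)
  trail <- list()
  repeat {
    model <- fit_forest(zonal, response, params, covariates = covs,
                        source_country = source_country)
    imp <- model$importance
    keep <- imp > 0
    trail[[length(trail) + 1L]] <- data.frame(covariate = names(imp),
                                              importance = as.numeric(imp),
                                              kept = keep, row.names = NULL)
    if (all(keep) || length(covs) == 1L) break
    if (!any(keep)) {
      warning("elimination removed every covariate; keeping the highest-importance one")
      covs <- names(imp)[which.max(imp)]
      break
    }
    covs <- names(imp)[keep]
  }
  structure(covs, trail = trail)
}

#' Predict the dasymetric weighting layer
#'
#' Runs the fitted forest on every in-mask cell of the covariate stack: the
#' per-cell mean of the trees' log-density predictions, exponentiated to
#' the people-per-km2 scale (weights are strictly positive, so every cell
#' of a populated unit can receive people). Cells outside the mask are
#' NoData.
#'
#' @param model a `pop_forest`.
#' @param stack a `cov_stack` supplying every model covariate, aligned with
#'   `mask`.
#' @param mask the unit raster defining the study area.
#' @return a [pop_grid] weighting layer (class `weight_layer`).
#' @export
predict_density <- function(model, stack, mask) {
  missing <- setdiff(model$covariate_names, names(stack))
  if (length(missing)) stop("stack lacks model covariates: ",
                            paste(missing, collapse = ", "))
  for (nm in model$covariate_names)
    stopifnot_aligned(stack[[nm]], mask, paste0("layer '", nm, "' and mask"))
  sel <- which(!is.na(mask$values))
  X <- vapply(model$covariate_names, function(nm) stack[[nm]]$values[sel],
              numeric(length(sel)))
  if (length(sel) == 1L) X <- matrix(X, nrow = 1L)
  if (anyNA(X)) stop("NoData inside mask; nibble-fill covariates first")
  pred <- .rf_predict_cpp(model$trees, X)
  v <- matrix(NA_real_, nrow(mask$values), ncol(mask$values))
  v[sel] <- exp(pred)
  out <- new_like(mask, v)
  attr(out, "source_country") <- model$source_country
  class(out) <- c("weight_layer", class(out))
  out
}

#' Predict a weighting layer with a donor-country model
#'
#' Ecozone model borrowing: when too few units exist to fit a model, a
#' model fitted on a covariate-compatible donor country predicts the
#' target's weighting layer. Identical contract to [predict_density()]; the
#' output's `source_country` attribute records the donor.
#'
#' @param donor_model a `pop_forest` fitted elsewhere.
#' @param target_stack the target country's `cov_stack`.
#' @param target_mask the target country's unit raster.
#' @return a weighting-layer [pop_grid] with donor provenance.
#' @export
cross_predict <- function(donor_model, target_stack, target_mask) {
  predict_density(donor_model, target_stack, target_mask)
}

#' Warn when a country has too few units to fit its own model
#' @param n_units number of units with a finite response.
#' @param minimum threshold below which borrowing is suggested.
#' @keywords internal
check_enough_units <- function(n_units, minimum = 10L) {
  if (n_units < minimum)
    warning("only ", n_units, " units (< ", minimum,
            "); consider borrowing a donor-country model via cross_predict()")
  invisible(n_units >= minimum)
}
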