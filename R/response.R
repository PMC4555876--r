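#' Log population-density response
#'
#' One row per unit with positive population: the natural log of people per
#' square kilometre, `ln(population / area_km2)`. The log transform
#' normalizes the heavily right-skewed density distribution before model
#' fitting. Zero-population units have no finite log density; they are
#' excluded from the table (recorded in the `excluded` attribute) but still
#' receive cells — and a zero share — downstream.
#'
#' @param units an [admin_set] with positive areas.
#' @return data.frame with columns `unit_id`, `log_density`.
#' @export
log_density <- function(units) {
  u <- units$units
  if (any(u$area_km2 <= 0)) stop("unit areas must be positive")
  zero <- u$population == 0
  if (all(zero)) stop("all units have zero population; no response to fit")
  if (any(zero))
    message(sum(zero), " zero-population unit(s) excluded from the response: ",
            paste(u$unit_id[zero], collapse = ", "))
  out <- data.frame(unit_id = u$unit_id[!zero],
                    log_density = log(u$population[!zero] / u$area_km2[!zero]))
  attr(out, "excluded") <- u$unit_id[zero]
  out
}
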