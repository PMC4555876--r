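#' Growth-rate schedule
#'
#' Census year, target year, per-annum urban and rural growth rates
#' (fractions, e.g. 0.02 for 2%/yr), and an optional external national
#' total for the target year to adjust to.
#'
#' @param census_year,target_year integers, `target_year >= census_year`.
#' @param urban_rate,rural_rate per-annum fractional rates, `> -1`.
#' @param unpd_total optional national person count for `target_year`.
#' @return a list of class `growth_schedule`.
#' @export
growth_schedule <- function(census_year, target_year, urban_rate, rural_rate,
                            unpd_total = NULL) {
  if (target_year < census_year) stop("target_year must be >= census_year")
  if (urban_rate <= -1 || rural_rate <= -1) stop("rates must exceed -1")
  structure(list(census_year = as.integer(census_year),
                 target_year = as.integer(target_year),
                 urban_rate = urban_rate, rural_rate = rural_rate,
                 unpd_total = unpd_total),
            class = "growth_schedule")
}

#' Project a population surface with urban/rural growth rates
#'
#' Multiplies urban cells by the urban growth factor and all other in-area
#' cells by the rural factor, over `target_year - census_year` years. The
#' default growth law is continuous exponential, `exp(rate * dt)` (UN
#' annual growth rates are conventionally exponential); a geometric law
#' `(1 + rate)^dt` is available. Relative spatial pattern within each
#' stratum is preserved exactly.
#'
#' @param ppp a people-per-pixel [pop_grid].
#' @param urban_mask a binary [pop_grid] aligned with `ppp`; 1 marks the
#'   urban stratum (conventionally land-cover class 190, configurably the
#'   combined built-up class).
#' @param schedule a [growth_schedule].
#' @param law `"exponential"` (default) or `"geometric"`.
#' @return the projected [pop_grid] (`variant = "projected"`, year
#'   updated).
#' @export
project_population <- function(ppp, urban_mask, schedule,
                               law = c("exponential", "geometric")) {
  law <- match.arg(law)
  stopifnot(inherits(schedule, "growth_schedule"))
  stopifnot_aligned(ppp, urban_mask, "ppp and urban mask")
  dt <- schedule$target_year - schedule$census_year
  fac <- function(rate) if (law == "exponential") exp(rate * dt) else (1 + rate)^dt
  v <- ppp$values
  urb <- !is.na(urban_mask$values) & urban_mask$values == 1
  inarea <- !is.na(v)
  v[inarea & urb] <- v[inarea & urb] * fac(schedule$urban_rate)
  v[inarea & !urb] <- v[inarea & !urb] * fac(schedule$rural_rate)
  as_pop_surface(new_like(ppp, v), schedule$target_year, "projected", ppp$kind)
}

#' Adjust a surface to an external national total
#'
#' Rescales every in-area cell by a single national factor
#' `target_total / current_total`, so the grid total matches the external
#' (UN Population Division style) estimate while the spatial pattern is
#' untouched. Idempotent.
#'
#' @param ppp a people-per-pixel [pop_grid].
#' @param target_total national person count to match (`>= 0`).
#' @return the adjusted [pop_grid] (`variant = "projected-UNadj"`).
#' @export
unpd_adjust <- function(ppp, target_total) {
  if (target_total < 0) stop("target_total must be >= 0")
  cur <- sum(ppp$values, na.rm = TRUE)
  if (cur <= 0 && target_total > 0)
    stop("current national total is zero; cannot scale to a positive target")
  v <- ppp$values
  if (cur > 0) v <- v * (target_total / cur)
  as_pop_surface(new_like(ppp, v), ppp$year, "projected-UNadj", ppp$kind)
}

#' Read a growth-rate schedule table
#'
#' Delimited table with columns `census_year`, `target_year`, `urban_rate`,
#' `rural_rate` and optional `unpd_total`; one row per target year.
#'
#' @param path CSV file path.
#' @return list of [growth_schedule] objects, one per row.
#' @export
read_growth_schedule <- function(path) {
  tb <- utils::read.csv(path)
  req <- c("census_year", "target_year", "urban_rate", "rural_rate")
  if (!all(req %in% names(tb)))
    stop("schedule needs columns ", paste(req, collapse = ", "))
  lapply(seq_len(nrow(tb)), function(i) {
    tot <- if ("unpd_total" %in% names(tb) && is.finite(tb$unpd_total[i]))
      tb$unpd_total[i] else NULL
    growth_schedule(tb$census_year[i], tb$target_year[i],
                    tb$urban_rate[i], tb$rural_rate[i], tot)
  })
}
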