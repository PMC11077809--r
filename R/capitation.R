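#' Per-area observed versus predicted cost summary
#'
#' Observed and predicted mean annual cost per patient for each health area,
#' their difference, and cross-sectional indices with the system average set
#' to 100. Because a gamma/log GLM does not guarantee that predictions sum to
#' observed costs, predictions are multiplicatively calibrated to the observed
#' system mean before index computation (the factor is kept as an attribute),
#' so the Total row balances exactly.
#'
#' @param records Person data frame with `area_id` and `cost_eur`.
#' @param predictions Per-record predicted costs (same order as `records`).
#' @param calibrate Rescale predictions to the observed system total
#'   (default `TRUE`).
#' @return Data frame of class `area_summary` with columns `area_id`,
#'   `observed`, `predicted`, `difference`, `observed_index`,
#'   `predicted_index`; last row is the system `Total`. Attribute
#'   `calibration_factor` holds the rescaling applied.
#' @export
area_cost_summary <- function(records, predictions, calibrate = TRUE) {
  if (nrow(records) != length(predictions))
    stop("every record needs a prediction")
  fac <- if (calibrate) mean(records$cost_eur) / mean(predictions) else 1
  pred <- predictions * fac
  f <- factor(records$area_id)
  obs_m <- as.numeric(tapply(records$cost_eur, f, mean))
  pred_m <- as.numeric(tapply(pred, f, mean))
  sys_obs <- mean(records$cost_eur)
  sys_pred <- mean(pred)
  out <- data.frame(
    area_id = c(levels(f), "Total"),
    observed = c(obs_m, sys_obs),
    predicted = c(pred_m, sys_pred),
    difference = c(obs_m - pred_m, sys_obs - sys_pred),
    observed_index = 100 * c(obs_m, sys_obs) / sys_obs,
    predicted_index = 100 * c(pred_m, sys_pred) / sys_pred
  )
  attr(out, "calibration_factor") <- fac
  class(out) <- c("area_summary", "data.frame")
  out
}

#' Need index of each health area
#'
#' The need index is the cross-sectional index of the predicted values on the
#' unit scale: predicted index / 100. Doubling every area's predicted mean
#' leaves it unchanged.
#'
#' @param area_summary An [area_cost_summary()] result (or any data frame
#'   with `area_id` and `predicted_index`).
#' @return Named vector of unit-scale need indices (Total row excluded).
#'   Report at 5 decimals.
#' @export
need_index <- function(area_summary) {
  x <- area_summary[area_summary$area_id != "Total", , drop = FALSE]
  if (any(x$predicted_index <= 0)) stop("predicted system mean must be positive")
  setNames(x$predicted_index / 100, x$area_id)
}

#' Adjusted (equivalent) population of an area
#'
#' Covered population multiplied by the unit-scale need index; the allocation
#' base of the capitated budget. Full precision is kept; report rounded to
#' whole persons.
#'
#' @param covered Covered population (persons, >= 0).
#' @param need Unit-scale need index (> 0).
#' @return `covered * need`, unrounded.
#' @export
adjusted_population <- function(covered, need) {
  if (any(covered < 0)) stop("covered population must be >= 0")
  if (any(need <= 0)) stop("need index must be > 0")
  covered * need
}

#' Three-way allocation of a fixed budget across health areas
#'
#' Allocates `budget` (millions of euros) by three criteria: covered
#' population shares, adjusted-population shares (covered population times
#' need index), and historical cost shares. The reported difference is
#' adjusted-population allocation minus historical allocation, computed
#' before any rounding; each criterion distributes exactly the budget.
#'
#' @param budget Total budget in millions of euros (> 0).
#' @param areas Data frame with `area_id`, `covered_population`, `need_index`
#'   and `historical_share` (shares must sum to 1 within `1e-6`).
#' @return Data frame of class `area_finance` with columns `area_id`,
#'   `covered_population`, `need_index`, `adjusted_population`,
#'   `alloc_population`, `alloc_adjusted`, `alloc_historical`, `difference`
#'   (all allocations unrounded, in millions of euros).
#' @export
allocate_budget <- function(budget, areas) {
  if (!is.numeric(budget) || length(budget) != 1 || budget <= 0)
    stop("budget must be a single positive amount")
  req <- c("area_id", "covered_population", "need_index", "historical_share")
  miss <- setdiff(req, names(areas))
  if (length(miss)) stop("areas is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(areas$covered_population <= 0))
    stop("covered populations must be positive")
  if (abs(sum(areas$historical_share) - 1) > 1e-6)
    stop("historical shares must sum to 1 (tolerance 1e-6)")
  adj <- adjusted_population(areas$covered_population, areas$need_index)
  out <- data.frame(
    area_id = areas$area_id,
    covered_population = areas$covered_population,
    need_index = areas$need_index,
    adjusted_population = adj,
    alloc_population = budget * areas$covered_population /
      sum(areas$covered_population),
    alloc_adjusted = budget * adj / sum(adj),
    alloc_historical = budget * areas$historical_share
  )
  out$difference <- out$alloc_adjusted - out$alloc_historical
  class(out) <- c("area_finance", "data.frame")
  out
}

#' Round an area finance table to reporting precision
#'
#' Millions of euros to whole numbers, differences to 2 decimals, need
#' indices to 5 decimals, adjusted populations to whole persons.
#'
#' @param x An [allocate_budget()] result.
#' @return Data frame with the rounded reporting columns.
#' @export
format_area_finance <- function(x) {
  data.frame(
    area_id = x$area_id,
    covered_population = round(x$covered_population),
    need_index = round(x$need_index, 5),
    adjusted_population = round(x$adjusted_population),
    alloc_population = round(x$alloc_population),
    alloc_adjusted = round(x$alloc_adjusted),
    alloc_historical = round(x$alloc_historical),
    difference = round(x$difference, 2)
  )
}
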