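#' Average marginal effect of a binary design indicator
#'
#' The average, across all records, of the predicted cost with the indicator
#' forced to 1 minus the predicted cost with it forced to 0. For indicators
#' belonging to a mutually exclusive set (age bands, AMG codes), forcing one
#' on switches the record's sibling indicators off, so "0" means the
#' reference level (age band 0, AMG 1).
#'
#' @param model A converged `cost_glm`.
#' @param records Person data frame over which to average.
#' @param variable Design column name: `"sex"`, `"age_band_<b>"` or
#'   `"amg_<code>"`.
#' @return The average marginal effect in euros per year.
#' @export
average_marginal_effect <- function(model, records, variable) {
  X <- build_design(records, model$encoding)$X
  if (!variable %in% colnames(X))
    stop("not a binary design indicator: ", variable)
  if (variable == "(Intercept)") stop("not a binary design indicator: (Intercept)")
  sib <- if (startsWith(variable, "age_band_")) {
    grep("^age_band_", colnames(X), value = TRUE)
  } else if (startsWith(variable, "amg_")) {
    grep("^amg_", colnames(X), value = TRUE)
  } else variable
  X1 <- X; X1[, sib] <- 0; X1[, variable] <- 1
  X0 <- X; X0[, sib] <- 0
  mu1 <- predict(model, list(X = X1))$mu
  mu0 <- predict(model, list(X = X0))$mu
  mean(mu1 - mu0)
}

#' Per-group means of individual predicted costs
#'
#' Averages the per-record predictions within each group -- not the
#' prediction at group-mean covariates. With a log link the ratio of two
#' group means therefore differs from `exp()` of the coefficient difference
#' whenever the groups have different age/sex compositions, which is exactly
#' how the published relative weights behave.
#'
#' @param model A converged `cost_glm`.
#' @param records Person data frame.
#' @param grouping Column of `records` to group by (default `"amg_code"`).
#' @return Named numeric vector of group mean predicted costs.
#' @export
group_predicted_means <- function(model, records, grouping = "amg_code") {
  mu <- predict(model, records)$mu
  f <- factor(records[[grouping]])
  out <- tapply(mu, f, mean)
  setNames(as.numeric(out), names(out))
}

#' Relative cost weights versus the healthy base group
#'
#' @param group_means Named vector of per-AMG predicted mean costs.
#' @param base_code Base group code (default 1, the healthy population).
#' @return Named vector of weights `mean_g / mean_base`; the base weight is
#'   exactly 1. Report at 3 decimals.
#' @export
relative_weights <- function(group_means, base_code = 1) {
  base <- group_means[as.character(base_code)]
  if (is.na(base) || length(base) != 1)
    stop("base group ", base_code, " missing from group_means")
  if (base <= 0) stop("base group mean must be positive")
  group_means / as.numeric(base)
}

#' Per-AMG effect surface of a fitted cost model
#'
#' Coefficients, average marginal effects, predicted mean costs and relative
#' weights for every AMG code present in the data, plus rows for the sex
#' indicator and the age bands (whose weights are not defined and reported
#' `NA`).
#'
#' @param model A converged `cost_glm`.
#' @param records Person data frame.
#' @return Data frame of class `weight_table` with columns `term`,
#'   `amg_code`, `coefficient`, `avg_marginal_effect`, `predicted_mean`,
#'   `relative_weight`.
#' @export
weight_table <- function(model, records) {
  cf <- model$coefficients
  amg_terms <- grep("^amg_", names(cf), value = TRUE)
  age_terms <- grep("^age_band_", names(cf), value = TRUE)
  gm <- group_predicted_means(model, records, "amg_code")
  rw <- relative_weights(gm)
  am <- group_predicted_means(model, records, "age_band")
  amg_codes <- sub("^amg_", "", amg_terms)
  rows <- list()
  rows$sex <- data.frame(term = "sex", amg_code = NA_integer_,
                         coefficient = unname(cf["sex"]),
                         avg_marginal_effect =
                           average_marginal_effect(model, records, "sex"),
                         predicted_mean = NA_real_,
                         relative_weight = NA_real_)
  rows$age <- data.frame(
    term = age_terms, amg_code = NA_integer_,
    coefficient = unname(cf[age_terms]),
    avg_marginal_effect = vapply(age_terms, function(v)
      average_marginal_effect(model, records, v), numeric(1)),
    predicted_mean = as.numeric(am[sub("^age_band_", "", age_terms)]),
    relative_weight = NA_real_)
  base <- data.frame(term = "amg_1", amg_code = 1L,
                     coefficient = NA_real_, avg_marginal_effect = NA_real_,
                     predicted_mean = as.numeric(gm["1"]),
                     relative_weight = as.numeric(rw["1"]))
  rows$amg <- rbind(base, data.frame(
    term = amg_terms, amg_code = as.integer(amg_codes),
    coefficient = unname(cf[amg_terms]),
    avg_marginal_effect = vapply(amg_terms, function(v)
      average_marginal_effect(model, records, v), numeric(1)),
    predicted_mean = as.numeric(gm[amg_codes]),
    relative_weight = as.numeric(rw[amg_codes])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}
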