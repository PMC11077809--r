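#' Generate a synthetic person-level cost population
#'
#' Draws `n_persons` records with the statistical structure the capitation
#' analysis assumes: each person gets an area (multinomial over area shares),
#' an AMG code (area-tilted multinomial over the configured AMG shares), an
#' integer age from a per-AMG truncated normal on \[0, 105\] whose mean matches
#' the configured group mean, a sex indicator (1 = female) from the per-AMG
#' female share, and a strictly positive annual cost from a gamma distribution
#' whose log mean is linear in sex, age band and AMG (see [sample_costs()]).
#' Identical configurations and seeds give byte-identical tables.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `person_id`, `area_id`, `sex`, `age_years`,
#'   `age_band`, `amg_code`, `cost_eur`.
#' @export
#' @examples
#' pop <- generate_population(sim_config(n_persons = 500, seed = 7))
#' stopifnot(all(pop$cost_eur > 0))
generate_population <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- config$n_persons
  empty <- data.frame(person_id = integer(), area_id = character(),
                      sex = integer(), age_years = integer(),
                      age_band = integer(), amg_code = integer(),
                      cost_eur = numeric())
  if (n == 0L) return(empty)
  set.seed(config$seed)
  areas <- config$areas
  gp <- config$group_profile
  codes <- as.integer(names(config$amg_shares))

  area_idx <- sample.int(nrow(areas), n, replace = TRUE, prob = areas$share)

  # Area-tilted AMG shares: p_g * cost_g^tilt, renormalised. The published
  # group mean cost orders groups by expected resource use.
  base_cost <- murcia_group_summary()
  gcost <- base_cost$mean_cost[match(codes, base_cost$amg_code)]
  gcost[is.na(gcost)] <- mean(base_cost$mean_cost)
  amg <- integer(n)
  for (a in seq_len(nrow(areas))) {
    ia <- which(area_idx == a)
    if (!length(ia)) next
    w <- config$amg_shares * gcost^areas$tilt[a]
    if (any(!is.finite(w)) || sum(w) <= 0)
      stop("area tilt for ", areas$area_id[a],
           " does not produce a valid probability vector")
    amg[ia] <- codes[sample.int(length(codes), length(ia), replace = TRUE,
                                prob = w / sum(w))]
  }

  gi <- match(amg, gp$amg_code)
  loc <- vapply(seq_len(nrow(gp)), function(i)
    truncnorm_location(gp$mean_age[i], gp$sd_age[i]), numeric(1))
  age <- pmax(0L, pmin(105L,
    as.integer(round(rtruncnorm(n, loc[gi], gp$sd_age[gi])))))
  sex <- as.integer(runif(n) < gp$pct_female[gi] / 100)

  records <- data.frame(
    person_id = seq_len(n),
    area_id = areas$area_id[area_idx],
    sex = sex,
    age_years = age,
    age_band = age_band(age),
    amg_code = amg,
    cost_eur = NA_real_
  )
  sample_costs(records, config$true_coefficients, config$gamma_shape,
               area_multipliers = setNames(areas$cost_multiplier,
                                           areas$area_id))
}

#' Draw gamma-distributed annual costs for person records
#'
#' Realises the cost model the analysis is built to recover: each person's
#' cost is drawn from a gamma distribution with shape `gamma_shape` and mean
#' `exp(x' beta) * m_a`, where `x` is the sex/age-band/AMG design row and
#' `m_a` an optional per-area multiplier that distorts realised costs away
#' from need (creating over/under-funded areas). Variance is
#' `mean^2 / gamma_shape`, the variance-proportional-to-mean-squared family
#' the model selection stage is expected to identify.
#'
#' @param records Person data frame (costs may be missing).
#' @param true_coefficients Named log-scale coefficients covering every sex,
#'   age-band and AMG level present in `records`.
#' @param gamma_shape Positive gamma shape.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so [generate_population()] stays a single reproducible stream).
#' @param area_multipliers Optional named vector of per-area cost multipliers.
#' @return `records` with `cost_eur` filled; all costs strictly positive.
#' @export
sample_costs <- function(records, true_coefficients, gamma_shape,
                         seed = NULL, area_multipliers = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  mu <- linear_predictor_mu(records, true_coefficients)
  if (!is.null(area_multipliers)) {
    m <- area_multipliers[as.character(records$area_id)]
    if (anyNA(m))
      stop("no area multiplier for area(s): ",
           paste(unique(records$area_id[is.na(m)]), collapse = ", "))
    mu <- mu * as.numeric(m)
  }
  records$cost_eur <- rgamma(nrow(records), shape = gamma_shape,
                             rate = gamma_shape / mu)
  records
}

# exp(x'beta) for each record under a named coefficient vector; errors on a
# level with no matching coefficient.
linear_predictor_mu <- function(records, coefficients) {
  eta <- rep(unname(coefficients["(Intercept)"]), nrow(records))
  if (is.na(eta[1])) stop("coefficients must include \"(Intercept)\"")
  if (any(records$sex != 0)) {
    if (!"sex" %in% names(coefficients))
      stop("no coefficient for level: sex")
    eta <- eta + coefficients["sex"] * records$sex
  }
  band <- records$age_band
  need <- setdiff(unique(band), 0L)
  for (b in need) {
    nm <- paste0("age_band_", b)
    if (!nm %in% names(coefficients)) stop("no coefficient for level: ", nm)
    eta <- eta + coefficients[nm] * (band == b)
  }
  for (g in setdiff(unique(records$amg_code), 1L)) {
    nm <- paste0("amg_", g)
    if (!nm %in% names(coefficients)) stop("no coefficient for level: ", nm)
    eta <- eta + coefficients[nm] * (records$amg_code == g)
  }
  exp(unname(eta))
}

#' Summarise a person table by Adjusted Morbidity Group
#'
#' One row per AMG present in the data plus a `Total` row, mirroring the
#' published group characterisation: mean and SD of age and cost, percentage
#' of women, and group sizes. The total mean cost equals the n-weighted
#' average of the group means by construction.
#'
#' @param records Non-empty person data frame.
#' @return Data frame with columns `amg_code` (character; last row `"Total"`),
#'   `mean_age`, `mean_cost`, `pct_female`, `sd_age`, `sd_cost`, `n`.
#' @export
summarize_groups <- function(records) {
  if (!nrow(records)) stop("records must be non-empty")
  f <- factor(records$amg_code)
  grp <- data.frame(
    amg_code = levels(f),
    mean_age = as.numeric(tapply(records$age_years, f, mean)),
    mean_cost = as.numeric(tapply(records$cost_eur, f, mean)),
    pct_female = 100 * as.numeric(tapply(records$sex, f, mean)),
    sd_age = as.numeric(tapply(records$age_years, f, sd)),
    sd_cost = as.numeric(tapply(records$cost_eur, f, sd)),
    n = as.integer(table(f))
  )
  tot <- data.frame(
    amg_code = "Total",
    mean_age = mean(records$age_years),
    mean_cost = mean(records$cost_eur),
    pct_female = 100 * mean(records$sex),
    sd_age = sd(records$age_years),
    sd_cost = sd(records$cost_eur),
    n = nrow(records)
  )
  rbind(grp, tot)
}
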