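# Reduced covariate set used by the simulation-based tests: sex, four
# non-reference age bands, and six AMG codes spanning the morbidity range
# (healthy, low-complexity acute, low/high-complexity chronic, neoplasm),
# with the published coefficient values.
reduced_coefs <- function() {
  c("(Intercept)" = 5.731, sex = -0.126,
    age_band_20 = -0.429, age_band_40 = -0.249,
    age_band_60 = -0.198, age_band_80 = -0.228,
    amg_101 = 0.095, amg_321 = 0.653, amg_331 = 1.659,
    amg_335 = 4.026, amg_401 = 3.131)
}

# Person table on the reduced design with gamma costs from the package's
# own cost sampler.
make_reduced_population <- function(n, seed, gamma_shape = 0.5,
                                    coefs = reduced_coefs()) {
  set.seed(seed)
  amg <- sample(c(1L, 101L, 321L, 331L, 335L, 401L), n, replace = TRUE,
                prob = c(0.30, 0.20, 0.20, 0.15, 0.10, 0.05))
  band <- sample(c(0L, 20L, 40L, 60L, 80L), n, replace = TRUE)
  rec <- data.frame(person_id = seq_len(n), area_id = "A",
                    sex = rbinom(n, 1, 0.5), age_years = band,
                    age_band = band, amg_code = amg, cost_eur = NA_real_)
  sample_costs(rec, coefs, gamma_shape)
}

# Minimal hand-built person table.
toy_records <- function(sex, age, amg, cost = NULL) {
  data.frame(person_id = seq_along(sex), area_id = "A", sex = sex,
             age_years = age, age_band = age_band(age), amg_code = amg,
             cost_eur = if (is.null(cost)) NA_real_ else cost)
}
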