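#' The Adjusted Morbidity Group catalogue
#'
#' The AMG stratifier classifies every insured person into one of 31 mutually
#' exclusive groups: the healthy population (code 1) plus six morbidity groups
#' (acute pathology, pregnancy/childbirth, chronic disease in 1 system, in 2-3
#' systems, in 4 or more systems, and neoplasms), each split into 5 complexity
#' levels. Codes follow the convention `<group digit><complexity>`: 101-105
#' acute, 201-205 pregnancy, 311-315 chronic in 1 system, 321-325 chronic in
#' 2-3 systems, 331-335 chronic in 4+ systems, 401-405 neoplasms.
#'
#' @return A data frame with one row per AMG code and columns `amg_code`
#'   (integer), `group` (character label) and `complexity` (integer 1-5, `NA`
#'   for the healthy group).
#' @export
#' @examples
#' cat31 <- amg_catalog()
#' table(cat31$group)
amg_catalog <- function() {
  data.frame(
    amg_code = c(1L, 101:105, 201:205, 311:315, 321:325, 331:335, 401:405),
    group = c(
      "healthy",
      rep("acute", 5),
      rep("pregnancy", 5),
      rep("chronic-1-system", 5),
      rep("chronic-2-3", 5),
      rep("chronic-4plus", 5),
      rep("neoplasm", 5)
    ),
    complexity = c(NA_integer_, rep(1:5, 6))
  )
}

#' Published group-level summary of the 2017 Murcian analytic population
#'
#' Per-AMG mean age, mean annual cost, percentage of women, standard
#' deviations and group sizes for the 1,251,108 cost-incurring residents of
#' the Murcia region in 2017, as published in the study this package builds
#' on. These moments are the calibration targets of [sim_config()] and the
#' inputs of the arithmetic reproduction checks.
#'
#' @return Data frame with columns `amg_code`, `mean_age`, `mean_cost`,
#'   `pct_female`, `sd_age`, `sd_cost`, `n`.
#' @export
murcia_group_summary <- function() {
  x <- matrix(c(
      1, 29.75,   217.95,  38.81, 17.84,  1649.53,  59406,
    101, 23.96,   242.02,  40.97, 17.35,  1416.63,  63069,
    102, 22.30,   338.14,  42.62, 17.83,   945.04,  40396,
    103, 18.82,   490.77,  45.93, 17.94,  1914.75,  28366,
    104, 14.74,   713.83,  49.23, 17.31,  1829.18,  17678,
    105,  9.61,  1510.94,  51.35, 15.44,  3692.16,   9398,
    201, 31.31,  1323.92, 100.00,  6.29,  1617.92,   5448,
    202, 31.87,  2265.04, 100.00,  6.09,  1979.63,   8504,
    203, 32.03,  2824.10, 100.00,  6.11,  2054.58,   6473,
    204, 32.23,  3526.77, 100.00,  6.25,  2726.36,   5424,
    205, 33.16,  4910.26, 100.00,  6.42,  5406.10,   2019,
    311, 27.50,   251.55,  47.24, 15.66,  1207.10,  51168,
    312, 31.48,   337.31,  41.26, 18.79,  1550.15,  85983,
    313, 31.05,   541.05,  42.45, 19.40,  4046.06,  60803,
    314, 30.10,   828.60,  44.60, 21.07,  2901.36,  46292,
    315, 28.19,  1962.88,  44.89, 23.25,  6029.96,  19558,
    321, 32.89,   402.78,  52.95, 17.48,  1304.25, 133841,
    322, 40.78,   731.48,  51.49, 19.57,  2420.03, 148624,
    323, 47.53,  1221.10,  50.68, 20.36,  3213.40,  77502,
    324, 53.49,  2016.29,  48.55, 20.75,  3880.43,  44931,
    325, 61.34,  4645.00,  40.59, 19.86,  8752.23,  16830,
    331, 49.91,  1173.00,  68.30, 18.92,  3010.10, 135466,
    332, 64.75,  2659.36,  65.35, 15.77,  4917.98,  96693,
    333, 70.87,  4494.43,  59.80, 14.09,  6789.83,  31732,
    334, 75.04,  7046.22,  53.81, 13.00, 10394.44,  23185,
    335, 78.62, 13135.77,  50.34, 10.92, 15821.16,  11186,
    401, 56.92,  5275.08,  52.42, 17.11,  8030.34,   6984,
    402, 66.53,  9960.65,  48.43, 14.83, 12529.17,   6287,
    403, 70.65, 14769.87,  42.88, 13.81, 17427.73,   3757,
    404, 73.89, 18873.63,  37.26, 12.35, 22535.54,   2845,
    405, 76.69, 24280.64,  32.62, 10.83, 23529.62,   1260
  ), ncol = 7, byrow = TRUE)
  out <- as.data.frame(x)
  names(out) <- c("amg_code", "mean_age", "mean_cost", "pct_female",
                  "sd_age", "sd_cost", "n")
  out$amg_code <- as.integer(out$amg_code)
  out$n <- as.integer(out$n)
  out
}

#' Published gamma/log coefficient set of the Murcian cost model
#'
#' Coefficients (log scale) of the selected gamma GLM with logarithmic link:
#' intercept, a female indicator, 17 five-year age-band offsets (reference
#' band 0) and 30 AMG offsets (reference AMG 1). They are the default "true"
#' coefficients of the synthetic-population generator.
#'
#' @return Named numeric vector in the canonical design-column order used by
#'   [build_design()].
#' @export
murcia_coefficients <- function() {
  age <- c(-0.509, -0.475, -0.428, -0.429, -0.389, -0.303, -0.276, -0.249,
           -0.230, -0.186, -0.206, -0.198, -0.161, -0.137, -0.155, -0.228,
           -0.311)
  names(age) <- paste0("age_band_", seq(5, 85, by = 5))
  amg <- c(0.095, 0.416, 0.761, 1.085, 1.762,
           1.911, 2.445, 2.665, 2.886, 3.213,
           0.198, 0.445, 0.908, 1.308, 2.122,
           0.653, 1.201, 1.683, 2.169, 2.976,
           1.659, 2.443, 2.961, 3.406, 4.026,
           3.131, 3.739, 4.126, 4.360, 4.611)
  names(amg) <- paste0("amg_", amg_catalog()$amg_code[-1])
  c("(Intercept)" = 5.731, sex = -0.126, age, amg)
}

#' Published per-AMG effect surface of the Murcian cost model
#'
#' Average marginal effects, predicted mean costs and relative weights versus
#' the healthy base group, as published for the selected gamma/log model.
#'
#' @return Data frame with columns `amg_code`, `coefficient`,
#'   `avg_marginal_effect`, `predicted_mean`, `relative_weight`.
#' @export
murcia_weight_table <- function() {
  x <- matrix(c(
      1,    NA,        NA,   215.57,   1.000,
    101, 0.095,     22.01,   239.45,   1.111,
    102, 0.416,    114.47,   336.07,   1.559,
    103, 0.761,    253.22,   488.33,   2.265,
    104, 1.085,    435.12,   710.44,   3.296,
    105, 1.762,   1070.60,  1499.98,   6.958,
    201, 1.911,   1278.68,  1325.84,   6.150,
    202, 2.445,   2336.80,  2273.03,  10.544,
    203, 2.665,   2966.31,  2835.37,  13.153,
    204, 2.886,   3756.16,  3543.37,  16.437,
    205, 3.213,   5296.28,  4951.63,  22.970,
    311, 0.198,     48.47,   252.75,   1.172,
    312, 0.445,    124.37,   337.69,   1.566,
    313, 0.908,    328.04,   542.61,   2.517,
    314, 1.308,    598.74,   826.14,   3.832,
    315, 2.122,   1629.81,  1951.76,   9.054,
    321, 0.653,    204.43,   404.73,   1.877,
    322, 1.201,    515.29,   732.52,   3.398,
    323, 1.683,    972.45,  1225.20,   5.684,
    324, 2.169,   1719.05,  2035.35,   9.442,
    325, 2.976,   4131.53,  4665.86,  21.644,
    331, 1.659,    944.12,  1168.28,   5.419,
    332, 2.443,   2331.91,  2671.43,  12.392,
    333, 2.961,   4063.36,  4512.83,  20.934,
    334, 3.406,   6467.34,  7029.94,  32.611,
    335, 4.026,  12216.92, 12991.52,  60.266,
    401, 3.131,   4858.91,  5346.30,  24.801,
    402, 3.739,   9109.43, 10022.15,  46.491,
    403, 4.126,  13525.69, 14816.30,  68.730,
    404, 4.360,  17150.43, 18797.00,  87.196,
    405, 4.611,  22094.56, 24150.32, 112.029
  ), ncol = 5, byrow = TRUE)
  out <- as.data.frame(x)
  names(out) <- c("amg_code", "coefficient", "avg_marginal_effect",
                  "predicted_mean", "relative_weight")
  out$amg_code <- as.integer(out$amg_code)
  out
}

#' Published per-area observed and predicted average costs
#'
#' Observed and model-predicted average annual cost per patient for the nine
#' health areas of the Murcian Health Service, with the system total.
#'
#' @return Data frame with columns `area_id`, `observed`, `predicted`,
#'   `difference`, `observed_index`, `predicted_index`; the last row is the
#'   system total.
#' @export
murcia_area_costs <- function() {
  out <- data.frame(
    area_id = c(paste0("Area ", c("I", "II", "III", "IV", "V", "VI", "VII",
                                  "VIII", "IX")), "Total"),
    observed  = c(1445.20, 1538.25, 1406.21, 1610.49, 1425.95, 1369.53,
                  1473.27, 1553.30, 1678.93, 1473.07),
    predicted = c(1455.45, 1505.97, 1385.48, 1499.33, 1336.79, 1496.10,
                  1527.42, 1454.58, 1511.97, 1473.07),
    difference = c(-10.25, 32.28, 20.73, 111.16, 89.16, -126.57, -54.15,
                   98.72, 166.96, 0.00),
    observed_index  = c(98.11, 104.43, 95.46, 109.33, 96.80, 92.97, 100.01,
                        105.45, 113.98, 100.00),
    predicted_index = c(98.80, 102.23, 94.05, 101.78, 90.75, 101.56, 103.69,
                        98.75, 102.64, 100.00)
  )
  out
}

#' Published per-area financing inputs and simulated capitation allocations
#'
#' Covered populations (from health cards, including persons who incurred no
#' cost), need indices, adjusted populations and the three allocations of the
#' fixed 1842 million euro budget for the nine Murcian health areas.
#'
#' @return Data frame with columns `area_id`, `covered_population`,
#'   `need_index`, `adjusted_population`, `alloc_population`,
#'   `alloc_adjusted`, `alloc_historical`, `difference`.
#' @export
murcia_area_finance <- function() {
  data.frame(
    area_id = paste0("Area ", c("I", "II", "III", "IV", "V", "VI", "VII",
                                "VIII", "IX")),
    covered_population = c(269627L, 288536L, 180577L, 69947L, 60828L,
                           272042L, 204969L, 109851L, 54874L),
    need_index = c(0.98804, 1.02234, 0.94054, 1.01783, 0.90749, 1.01564,
                   1.03690, 0.98745, 1.02641),
    adjusted_population = c(266402L, 294981L, 169840L, 71194L, 55201L,
                            276296L, 212532L, 108473L, 56323L),
    alloc_population = c(329L, 352L, 220L, 85L, 74L, 332L, 250L, 134L, 67L),
    alloc_adjusted   = c(325L, 360L, 207L, 87L, 67L, 337L, 259L, 132L, 69L),
    alloc_historical = c(317L, 365L, 210L, 102L, 74L, 294L, 260L, 139L, 81L),
    difference = c(7.44, -5.02, -2.62, -15.28, -6.96, 42.76, -0.88, -6.87,
                   -12.59)
  )
}

#' Fixed regional budget of the capitation simulation, in millions of euros
#' @return The scalar 1842.
#' @export
murcia_budget <- function() 1842
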