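test_that("published area indices are the printed ratios to the system mean", {
  tab <- murcia_area_costs()
  areas <- tab[tab$area_id != "Total", ]
  total <- tab[tab$area_id == "Total", ]
  # the printed means are themselves rounded to cents, so recomputed indices
  # can differ from the printed ones by one unit in the last place
  expect_lt(max(abs(100 * areas$observed / total$observed -
                      areas$observed_index)), 0.015)
  expect_lt(max(abs(100 * areas$predicted / total$predicted -
                      areas$predicted_index)), 0.015)
  expect_equal(round(areas$observed - areas$predicted, 2), areas$difference)
})

test_that("area summary balances and indexes a synthetic population", {
  pop <- make_reduced_population(6000, seed = 81)
  pop$area_id <- sample(c("N", "S", "E"), 6000, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2))
  m <- fit_cost_glm(pop, "gamma", "log")
  asum <- area_cost_summary(pop, predict(m, pop)$mu)
  tot <- asum[asum$area_id == "Total", ]
  expect_equal(tot$observed, tot$predicted, tolerance = 1e-9)
  expect_equal(tot$difference, 0, tolerance = 1e-9)
  per <- asum[asum$area_id != "Total", ]
  ns <- table(factor(pop$area_id, levels = per$area_id))
  expect_lt(abs(weighted.mean(per$observed_index, as.numeric(ns)) - 100), 0.01)
  expect_lt(abs(weighted.mean(per$predicted_index, as.numeric(ns)) - 100), 0.01)
  # single area: both indices are 100 by construction
  one <- area_cost_summary(transform(pop, area_id = "ALL"),
                           predict(m, pop)$mu)
  expect_equal(one$observed_index, c(100, 100))
  ni <- need_index(asum)
  expect_equal(unname(ni), per$predicted_index / 100)
  # scale invariance: doubling predictions changes no index
  asum2 <- area_cost_summary(pop, 2 * predict(m, pop)$mu)
  expect_equal(need_index(asum2), ni, tolerance = 1e-12)
})

test_that("adjusted populations reproduce the published table", {
  fin <- murcia_area_finance()
  adj <- adjusted_population(fin$covered_population, fin$need_index)
  # the published need index is cut at 5 decimals, worth up to one person
  expect_lte(max(abs(round(adj) - fin$adjusted_population)), 1)
  expect_equal(adjusted_population(269627, 0.98804), 266402, tolerance = 1e-5)
  expect_equal(adjusted_population(1000, 1.0), 1000)
  expect_error(adjusted_population(10, 0), "> 0")
})

test_that("budget allocation reproduces the published simulation", {
  fin <- murcia_area_finance()
  fin$historical_share <- fin$alloc_historical / sum(fin$alloc_historical)
  out <- allocate_budget(murcia_budget(), fin)
  rep_ <- format_area_finance(out)
  expect_equal(rep_$alloc_population, fin$alloc_population)
  expect_equal(rep_$alloc_adjusted, fin$alloc_adjusted)
  expect_equal(rep_$alloc_historical, fin$alloc_historical)
  expect_lte(max(abs(rep_$adjusted_population - fin$adjusted_population)), 1)
  # printed differences use unrounded historical figures; the integer
  # historical column bounds the discrepancy by half a million euros
  expect_lt(max(abs(out$difference - fin$difference)), 0.51)
  expect_equal(rep_$alloc_population[fin$area_id == "Area II"], 352L)
})

test_that("every allocation rule conserves the budget (fuzz)", {
  set.seed(82)
  for (k in 1:25) {
    n_areas <- sample(3:20, 1)
    sh <- rgamma(n_areas, 1); sh <- sh / sum(sh)
    areas <- data.frame(
      area_id = paste0("A", seq_len(n_areas)),
      covered_population = sample(1e3:1e6, n_areas),
      need_index = runif(n_areas, 0.7, 1.3),
      historical_share = sh
    )
    budget <- runif(1, 10, 5000)
    out <- allocate_budget(budget, areas)
    expect_lt(abs(sum(out$alloc_population) - budget), 1e-9 * budget)
    expect_lt(abs(sum(out$alloc_adjusted) - budget), 1e-9 * budget)
    expect_lt(abs(sum(out$alloc_historical) - budget), 1e-9 * budget)
    expect_lt(abs(sum(out$difference)), 1e-9 * budget)
  }
})

test_that("allocations respond monotonically to need", {
  base <- data.frame(area_id = c("a", "b", "c"),
                     covered_population = c(1000, 2000, 3000),
                     need_index = c(1, 1, 1),
                     historical_share = c(0.2, 0.3, 0.5))
  # equal unit needs: allocation by population equals allocation by
  # adjusted population
  eq <- allocate_budget(600, base)
  expect_equal(eq$alloc_population, eq$alloc_adjusted, tolerance = 1e-12)
  # raising one area's need raises its adjusted allocation, lowers the others'
  up <- base; up$need_index[1] <- 1.2
  out <- allocate_budget(600, up)
  expect_gt(out$alloc_adjusted[1], eq$alloc_adjusted[1])
  expect_lt(out$alloc_adjusted[2], eq$alloc_adjusted[2])
  expect_gt(adjusted_population(1000, 1.2), adjusted_population(1000, 1.1))
  # brute-force oracle over a grid of 3-area share configurations
  for (ni in seq(0.8, 1.3, by = 0.1)) {
    cfg <- base; cfg$need_index[2] <- ni
    got <- allocate_budget(100, cfg)$alloc_adjusted[2]
    adj <- cfg$covered_population * cfg$need_index
    expect_equal(got, 100 * adj[2] / sum(adj), tolerance = 1e-12)
  }
})

test_that("allocation inputs are validated", {
  areas <- data.frame(area_id = "a", covered_population = 10,
                      need_index = 1, historical_share = 0.9)
  expect_error(allocate_budget(100, areas), "sum to 1")
  areas$historical_share <- 1
  expect_error(allocate_budget(0, areas), "positive")
  expect_error(allocate_budget(100, areas[, -2]), "missing column")
})
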