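test_that("catalogue has 31 codes, 5 complexity levels per non-healthy group", {
  cat31 <- amg_catalog()
  expect_equal(nrow(cat31), 31L)
  expect_false(any(duplicated(cat31$amg_code)))
  tab <- table(cat31$group)
  expect_equal(unname(tab["healthy"]), 1L, ignore_attr = TRUE)
  for (g in setdiff(names(tab), "healthy")) {
    expect_equal(sort(cat31$complexity[cat31$group == g]), 1:5,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate configurations: empty population and one-point mixture", {
  expect_equal(nrow(generate_population(sim_config(0, seed = 1))), 0L)
  cfg <- sim_config(50, seed = 2, amg_shares = c(`1` = 1.0))
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 50L)
  expect_true(all(pop$amg_code == 1L))
  expect_true(all(pop$cost_eur > 0))
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(10, seed = 1, amg_shares = c(`1` = 0.7, `101` = 0.2)),
               "sum to 1")
  expect_error(sim_config(10, seed = 1, amg_shares = c(`9` = 1)), "unknown AMG")
  expect_error(sim_config(10, seed = 1, gamma_shape = 0), "positive")
  expect_error(sim_config(10), "seed")
})

test_that("generation is deterministic given the configuration and seed", {
  cfg <- sim_config(2000, seed = 99)
  expect_identical(generate_population(cfg), generate_population(cfg))
})

test_that("AMG draws follow the configured shares (multinomial oracle)", {
  n <- 100000
  pop <- generate_population(sim_config(n, seed = 4))
  shares <- with(murcia_group_summary(), setNames(n / sum(n), amg_code))
  counts <- table(factor(pop$amg_code, levels = names(shares)))
  for (g in names(shares)) {
    p <- shares[[g]]
    expect_lt(abs(counts[[g]] - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("per-group age and sex composition is recovered", {
  pop <- generate_population(sim_config(100000, seed = 5))
  gp <- murcia_group_summary()
  for (i in seq_len(nrow(gp))) {
    g <- pop[pop$amg_code == gp$amg_code[i], ]
    if (nrow(g) < 30) next
    se_age <- gp$sd_age[i] / sqrt(nrow(g))
    expect_lt(abs(mean(g$age_years) - gp$mean_age[i]), 4 * se_age + 0.5)
    pf <- gp$pct_female[i] / 100
    se_f <- sqrt(max(pf * (1 - pf), 1e-12) / nrow(g))
    expect_lte(abs(mean(g$sex) - pf), 4 * se_f)
  }
})

test_that("cost sampler hits the configured mean and coefficient of variation", {
  rec <- toy_records(rep(0L, 200000), rep(0L, 200000), rep(1L, 200000))
  # nearly deterministic gamma: mean recovers exp(intercept)
  x <- sample_costs(rec, c("(Intercept)" = log(100)), gamma_shape = 1e6,
                    seed = 10)
  expect_lt(abs(mean(x$cost_eur) - 100) / 100, 0.001)
  # unit shape: coefficient of variation 1
  y <- sample_costs(rec[1:100000, ], c("(Intercept)" = log(100)),
                    gamma_shape = 1, seed = 11)
  cv <- sd(y$cost_eur) / mean(y$cost_eur)
  expect_lt(abs(cv - 1), 0.02)
  expect_true(all(y$cost_eur > 0))
  # single record: strictly positive support
  one <- sample_costs(rec[1, ], c("(Intercept)" = log(5)), 0.5, seed = 12)
  expect_gt(one$cost_eur, 0)
})

test_that("area cost multipliers scale realised means", {
  rec <- toy_records(rep(0L, 100000), rep(0L, 100000), rep(1L, 100000))
  x <- sample_costs(rec, c("(Intercept)" = log(100)), gamma_shape = 0.5,
                    seed = 13, area_multipliers = c(A = 1.07))
  se <- sd(x$cost_eur) / sqrt(nrow(x))
  expect_lt(abs(mean(x$cost_eur) - 107), 3 * se)
})

test_that("cost sampler names unknown factor levels", {
  rec <- toy_records(0L, 0L, 999L)
  expect_error(sample_costs(rec, reduced_coefs(), 0.5, seed = 1), "amg_999")
  rec2 <- toy_records(0L, 47L, 1L)
  expect_error(sample_costs(rec2, reduced_coefs(), 0.5, seed = 1),
               "age_band_45")
})

test_that("group summary satisfies its aggregation invariants", {
  rec <- toy_records(c(0L, 1L), c(10L, 20L), c(101L, 101L), cost = c(100, 200))
  gs <- summarize_groups(rec)
  expect_equal(gs$mean_cost[gs$amg_code == "101"], 150)
  expect_equal(gs$n[gs$amg_code == "101"], 2L)
  expect_equal(gs$mean_cost[gs$amg_code == "Total"], 150)
  expect_error(summarize_groups(rec[0, ]), "non-empty")

  pop <- make_reduced_population(5000, seed = 6)
  gs <- summarize_groups(pop)
  grp <- gs[gs$amg_code != "Total", ]
  tot <- gs[gs$amg_code == "Total", ]
  expect_equal(sum(grp$n), tot$n)
  expect_lt(abs(weighted.mean(grp$mean_cost, grp$n) - tot$mean_cost), 0.01)
})

test_that("YAML generator configurations round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_persons: 120",
    "seed: 17",
    "gamma_shape: 1.5",
    "amg_shares:",
    "  '1': 0.6",
    "  '321': 0.4",
    "areas:",
    "  - area_id: north",
    "    share: 0.5",
    "    tilt: 0.1",
    "    cost_multiplier: 1.1",
    "  - area_id: south",
    "    share: 0.5",
    "    tilt: -0.1",
    "    cost_multiplier: 0.9"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$gamma_shape, 1.5)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 120L)
  expect_setequal(unique(pop$amg_code), c(1L, 321L))
  expect_setequal(unique(pop$area_id), c("north", "south"))
  # seed override and mandatory-seed error
  expect_identical(generate_population(read_sim_config(path, seed = 17)), pop)
  writeLines("n_persons: 5", path)
  expect_error(read_sim_config(path), "seed")
})

test_that("published group table recombines to the published totals", {
  gs <- murcia_group_summary()
  expect_equal(sum(gs$n), 1251108L)
  expect_lt(abs(weighted.mean(gs$mean_cost, gs$n) - 1472.43), 0.01)
  expect_equal(sum(gs$n[gs$amg_code %in% c(321, 322, 331)]), 417931L)
})
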