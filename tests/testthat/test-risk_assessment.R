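test_that("risk categories follow the published rule including boundaries", {
  cfg <- risk_config()
  expect_equal(classify(4.0, 25, cfg), "HIGH")
  expect_equal(classify(3.5, 25, cfg), "MODERATE")
  expect_equal(classify(3.5, 15, cfg), "MILD")
  expect_equal(classify(2.0, 60, cfg), "NONE")
  # boundary conventions: loss at the cutoffs belongs to the middle band,
  # anemia exactly at the threshold is "not over"
  expect_equal(classify(3.8, 25, cfg), "MODERATE")
  expect_equal(classify(3.1, 25, cfg), "MODERATE")
  expect_equal(classify(3.8, 20, cfg), "MILD")
  expect_equal(classify(4.5, 20, cfg), "MILD")  # high loss, low anemia
})

test_that("classification is exhaustive and mutually exclusive over the plane", {
  cfg <- risk_config()
  grid <- expand.grid(loss = seq(0, 8, by = 0.1), anemia = seq(0, 60, by = 1))
  cats <- classify(grid$loss, grid$anemia, cfg)
  expect_true(all(cats %in% c("HIGH", "MODERATE", "MILD", "NONE")))
  # re-derive from the rule independently
  ref <- with(grid, ifelse(loss < 3.1, "NONE",
                           ifelse(loss > 3.8,
                                  ifelse(anemia > 20, "HIGH", "MILD"),
                                  ifelse(anemia > 20, "MODERATE", "MILD"))))
  expect_equal(cats, ref)
})

test_that("tertile cutoffs are the 1/3 and 2/3 empirical quantiles", {
  cuts <- tertile_cutoffs(1:9)
  bands <- cut(1:9, c(-Inf, cuts[["lo"]], cuts[["hi"]], Inf))
  expect_equal(unname(table(bands)), array(c(3, 3, 3)))
  expect_equal(unname(tertile_cutoffs(rep(2.5, 6))), c(2.5, 2.5))
  expect_error(tertile_cutoffs(c(1, 2)), class = "ferro_domain_error")
})

test_that("fixed mode keeps the published cutoffs, recompute derives them", {
  losses <- tibble::tibble(country = sprintf("C%d", 1:9),
                           group = "women_15_49",
                           median_loss_pct = as.numeric(1:9))
  anemia <- tibble::tibble(country = losses$country, group = "women_15_49",
                           anemia_pct = 30)
  fixed <- assess_risk(losses, anemia, risk_config())
  expect_equal(fixed$category[losses$median_loss_pct == 3], "NONE")
  expect_equal(fixed$category[losses$median_loss_pct == 4], "HIGH")
  rec <- assess_risk(losses, anemia, risk_config(tertile_mode = "RECOMPUTE"))
  expect_equal(unname(table(rec$category)[c("NONE", "MODERATE", "HIGH")]),
               array(c(3, 3, 3)))
})

test_that("population aggregation conserves totals and computes shares", {
  assessment <- tibble::tibble(
    country = c("A", "B"), group = "women_15_49",
    median_loss_pct = c(5, 1), anemia_pct = c(30, 30),
    category = c("HIGH", "NONE"))
  pop <- tibble::tibble(country = c("A", "B"), group = "women_15_49",
                        headcount = c(10, 10))
  agg <- aggregate_population(assessment, pop)
  expect_equal(agg$headcount[agg$category == "HIGH"], 10)
  expect_equal(agg$share_pct[agg$category == "HIGH"], 50)
  expect_equal(sum(agg$headcount), sum(pop$headcount))

  one <- aggregate_population(assessment[1, ], pop[1, ])
  expect_equal(one$share_pct[one$category == "HIGH"], 100)

  expect_error(aggregate_population(assessment, pop[1, ]),
               class = "ferro_lookup_error")
})

test_that("population totals are conserved on a synthetic world", {
  w <- tiny_world(seed = 25, n_countries = 9)
  ir <- iron_supply(disaggregate(w$supply, w$foods, w$gdd, w$energy)[
    c("country", "food_id", "group", "g_per_day")], w$foods)
  sim <- simulate_losses(ir, w$foods, w$eco2_effects, w$gdd,
                         n_draws = 100, seed = 1, keep_draws = FALSE)
  risk <- assess_risk(sim$summary, w$anemia,
                      risk_config(tertile_mode = "RECOMPUTE"))
  agg <- aggregate_population(risk, w$population)
  expect_equal(sum(agg$headcount), sum(w$population$headcount))
  # recomputed tertiles on >= 3 distinct losses leave no empty loss band
  per_country <- tapply(risk$median_loss_pct, risk$country, median)
  cuts <- tertile_cutoffs(as.numeric(per_country))
  expect_true(any(per_country < cuts[["lo"]]))
  expect_true(any(per_country > cuts[["hi"]]))
})

test_that("top lost sources convert mg per person to aggregate kg per day", {
  cat0 <- audit_catalog()
  # 20 mg/d of wheat iron at an expected -5% is 1 mg/d lost per person;
  # a million-person group then loses 1 kg/d
  sup <- tibble::tibble(country = "A", group = "women_15_49",
                        food_id = c("wheat", "sorghum"),
                        g_per_day = c(20 / 3.5 * 100, 100))
  ir <- iron_supply(sup, cat0)
  assessment <- tibble::tibble(country = "A", group = "women_15_49",
                               median_loss_pct = 5, anemia_pct = 30,
                               category = "HIGH")
  pop <- tibble::tibble(country = "A", group = "women_15_49", headcount = 1e6)
  top <- top_lost_sources(ir, cat0, degenerate_effects(wheat = -5),
                          assessment, pop)
  expect_equal(top$kg_per_day[top$food_id == "wheat"], 1)
  expect_equal(top$kg_per_day[top$food_id == "sorghum"], 0)
  expect_equal(top$rank[top$food_id == "sorghum"], max(top$rank))
})

test_that("top lost sources match a naive triple-loop recomputation", {
  w <- tiny_world(seed = 41, n_countries = 6)
  ir <- iron_supply(disaggregate(w$supply, w$foods, w$gdd, w$energy)[
    c("country", "food_id", "group", "g_per_day")], w$foods)
  sim <- simulate_losses(ir, w$foods, w$eco2_effects, w$gdd,
                         n_draws = 100, seed = 1, keep_draws = FALSE)
  risk <- assess_risk(sim$summary, w$anemia,
                      risk_config(tertile_mode = "RECOMPUTE"))
  top <- top_lost_sources(ir, w$foods, w$eco2_effects, risk, w$population)
  exp_eff <- expected_effect_by_food(w$foods, w$eco2_effects)
  ref <- setNames(rep(0, nrow(w$foods)), w$foods$food_id)
  for (i in seq_len(nrow(risk))) {
    if (risk$category[i] != "HIGH") next
    hc <- w$population$headcount[w$population$country == risk$country[i] &
                                   w$population$group == risk$group[i]]
    sub <- ir$by_food[ir$by_food$country == risk$country[i] &
                        ir$by_food$group == risk$group[i], ]
    for (j in seq_len(nrow(sub))) {
      e <- exp_eff$expected_pct_change[exp_eff$food_id == sub$food_id[j]]
      ref[sub$food_id[j]] <- ref[sub$food_id[j]] +
        sub$iron_mg_per_day[j] * (-e / 100) * hc * 1e-6
    }
  }
  expect_gt(sum(ref), 0)  # the world contains high-risk populations
  expect_equal(top$kg_per_day, unname(ref[top$food_id]))
})
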