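test_that("vegetarian transform zeroes animal foods and conserves energy", {
  cat0 <- audit_catalog()
  # 50% of calories from beef: vegetal inflation factor exactly 2
  sup <- tibble::tibble(country = "A", group = "NATIONAL",
                        food_id = c("wheat", "beef"),
                        g_per_day = c(100, 340 / 250 * 100))
  veg <- vegetarian_transform(sup, cat0)
  expect_equal(veg$factors$factor, 2.0)
  expect_equal(veg$supply$g_per_day[veg$supply$food_id == "beef"], 0)
  expect_equal(veg$supply$g_per_day[veg$supply$food_id == "wheat"], 200)

  # no animal foods: identity, factor 1
  veg2 <- vegetarian_transform(sup[1, ], cat0)
  expect_equal(veg2$factors$factor, 1.0)
  expect_equal(veg2$supply$g_per_day, sup$g_per_day[1])

  # a country with only animal calories cannot be made vegetarian
  expect_error(vegetarian_transform(sup[2, ], cat0),
               class = "ferro_scenario_error")
})

test_that("vegetarian energy audit matches the baseline on synthetic worlds", {
  w <- tiny_world(seed = 14, n_countries = 6)
  veg <- vegetarian_transform(w$supply, w$foods)
  kcal <- function(s) {
    m <- merge(s, w$foods[c("food_id", "kcal_per_100g")], by = "food_id")
    tapply(m$g_per_day * m$kcal_per_100g / 100, m$country, sum)
  }
  base <- kcal(w$supply); after <- kcal(veg$supply)
  expect_equal(unname(after[names(base)]), unname(base), tolerance = 1e-9)
  animal_ids <- w$foods$food_id[w$foods$is_animal]
  expect_true(all(veg$supply$g_per_day[veg$supply$food_id %in% animal_ids] == 0))
})

test_that("scenario deltas are zero for identical or already-vegetarian diets", {
  losses <- tibble::tibble(country = c("A", "B"), group = "NATIONAL",
                           median_loss_pct = c(3, 4))
  expect_equal(scenario_loss_delta(losses, losses)$delta_pct, c(0, 0))
  mismatched <- losses; mismatched$country <- c("A", "C")
  expect_error(scenario_loss_delta(losses, mismatched),
               class = "ferro_domain_error")
})

test_that("the vegetarian increment is nonnegative when animal iron exists and effects are losses", {
  for (s in c(2, 16)) {
    w <- tiny_world(seed = s, n_countries = 5)
    # force pure losses: degenerate negative effects so the sign check is exact
    eff <- w$eco2_effects
    eff$ci_lo <- NA_real_; eff$ci_hi <- NA_real_
    eff <- apply_zero_effect_rule(eff)
    ir0 <- iron_supply(w$supply, w$foods)
    veg <- vegetarian_transform(w$supply, w$foods)
    ir1 <- iron_supply(veg$supply, w$foods)
    s0 <- simulate_losses(ir0, w$foods, eff, n_draws = 10, seed = 1)
    s1 <- simulate_losses(ir1, w$foods, eff, n_draws = 10, seed = 1)
    delta <- scenario_loss_delta(s0$summary, s1$summary)
    sh <- source_decomposition(ir0, w$foods)
    has_animal <- sh$animal[match(delta$country, sh$country)] > 0
    expect_true(all(delta$delta_pct[has_animal] >= -1e-9))
  }
})

test_that("diversity count is the minimal prefix reaching the threshold", {
  one <- tibble::tibble(food_id = "a", iron_mg_per_day = 3)
  expect_equal(diversity_count(one), 1L)
  four <- tibble::tibble(food_id = letters[1:4], iron_mg_per_day = rep(2, 4))
  expect_equal(diversity_count(four, 0.99), 4L)
  expect_equal(diversity_count(four, 0.5), 2L)
  expect_error(diversity_count(tibble::tibble(food_id = "a", iron_mg_per_day = 0)),
               class = "ferro_domain_error")

  # brute-force oracle on random vectors, plus threshold monotonicity
  set.seed(71)
  for (i in 1:60) {
    n <- sample(3:25, 1)
    v <- tibble::tibble(food_id = sprintf("f%02d", 1:n),
                        iron_mg_per_day = rlnorm(n, 0, 1.5))
    for (th in c(0.9, 0.99)) {
      sorted <- sort(v$iron_mg_per_day, decreasing = TRUE)
      k <- which(cumsum(sorted) / sum(sorted) >= th - 1e-12)[1]
      expect_equal(diversity_count(v, th), as.integer(k))
    }
    expect_lte(diversity_count(v, 0.9), diversity_count(v, 0.99))
  }
})

test_that("the diversity regression recovers exact fits and degenerate slopes", {
  pts <- tibble::tibble(country = sprintf("C%d", 1:6),
                        anemia_pct = c(5, 10, 20, 30, 40, 55),
                        wild_flag = FALSE)
  pts$n_sources <- 30 - 4 * log(pts$anemia_pct)
  fit <- diversity_anemia_fit(pts)
  expect_equal(fit$intercept, 30, tolerance = 1e-9)
  expect_equal(fit$slope, -4, tolerance = 1e-9)
  expect_equal(fit$r, -1, tolerance = 1e-9)

  flat <- pts; flat$n_sources <- 12
  expect_equal(diversity_anemia_fit(flat)$slope, 0, tolerance = 1e-12)

  pts$wild_flag <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_error(diversity_anemia_fit(pts, exclude_wild = TRUE),
               class = "ferro_fit_error")
  expect_error(diversity_anemia_fit(dplyr::mutate(pts, anemia_pct = 0),
                                    exclude_wild = FALSE),
               class = "ferro_domain_error")
})

test_that("generated worlds yield a negative diversity-anemia slope, with and without wild exclusion", {
  w <- tiny_world(seed = 7, n_countries = 20, n_foods = 30)
  ir <- iron_supply(w$supply, w$foods)
  pts <- diversity_points(ir, w$foods, w$anemia)
  expect_true(any(pts$wild_flag) && any(!pts$wild_flag))
  expect_lt(diversity_anemia_fit(pts)$slope, 0)
  expect_lt(diversity_anemia_fit(pts, exclude_wild = TRUE)$slope, 0)
  # alternative log-response reading also reports a negative association
  expect_lt(diversity_anemia_fit(pts, log_response = TRUE)$slope, 0)
})
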