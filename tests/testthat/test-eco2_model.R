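test_that("non-significant crop changes are zeroed at alpha = 0.05", {
  eff <- tibble::tibble(
    crop_or_category = c("sorghum", "potato", "wheat"),
    level = "CROP",
    mean_pct_change = c(1.2, -0.7, -5.1),
    ci_lo = c(-1, -3, -7), ci_hi = c(3, 2, -3.5),
    n_samples = c(10, 12, 120),
    p_value = c(0.153, 0.555, 0.001))
  z <- apply_zero_effect_rule(eff)
  expect_equal(z$mean_pct_change, c(0, 0, -5.1))
  expect_equal(z$ci_lo, c(0, 0, -7))
  expect_equal(z$ci_hi, c(0, 0, -3.5))
})

test_that("category pooling is the sample-count-weighted average", {
  eff <- tibble::tibble(
    crop_or_category = c("a", "b"), level = "CROP",
    mean_pct_change = c(-5, -10), ci_lo = c(-8, -14), ci_hi = c(-2, -6),
    n_samples = c(10, 30), p_value = 0.01)
  pooled <- pool_category(eff, "C3_GRAIN")
  expect_equal(pooled$mean_pct_change, -8.75)  # (-5*10 - 10*30)/40
  expect_equal(pooled$n_samples, 40)
  expect_equal(pooled$ci_lo, (10 * -8 + 30 * -14) / 40)
  expect_equal(pool_category(eff[1, ])$mean_pct_change, -5)  # identity
  eq <- eff; eq$n_samples <- c(20, 20)
  expect_equal(pool_category(eq)$mean_pct_change, mean(eq$mean_pct_change))
  expect_error(pool_category(eff[0, ]), class = "ferro_domain_error")
})

test_that("symmetric intervals reduce the fit to a normal law", {
  f <- fit_skew_normal(-5, -8, -2)
  expect_equal(f$alpha, 0, tolerance = 1e-6)
  expect_equal(f$xi, -5, tolerance = 1e-8)
  expect_equal(f$omega, 3 / qnorm(0.975), tolerance = 1e-8)
})

test_that("asymmetric feasible intervals fit with the correct skew sign and reproduce their quantiles", {
  f <- fit_skew_normal(-5, -9, -2.9)
  expect_lt(f$alpha, 0)
  q <- qskewnorm(c(0.025, 0.5, 0.975), f$xi, f$omega, f$alpha)
  expect_equal(q, c(-9, -5, -2.9), tolerance = 1e-7)
  # right-skewed case
  g <- fit_skew_normal(2, 0.5, 5)
  expect_gt(g$alpha, 0)
  expect_equal(qskewnorm(c(0.025, 0.5, 0.975), g$xi, g$omega, g$alpha),
               c(0.5, 2, 5), tolerance = 1e-7)
})

test_that("intervals beyond the skew-normal asymmetry limit raise a fit error", {
  err <- tryCatch(fit_skew_normal(-5, -10, -3), error = identity)
  expect_s3_class(err, "ferro_fit_error")
  expect_match(conditionMessage(err), "residual")
  expect_error(fit_skew_normal(-5, -3, -10), class = "ferro_domain_error")
  expect_error(fit_skew_normal(-12, -10, -3), class = "ferro_fit_error")
})

test_that("the skew-normal CDF, quantile and sampler agree with each other", {
  for (alpha in c(-4, 0, 2.5)) {
    p <- c(0.01, 0.2, 0.5, 0.9, 0.99)
    q <- qskewnorm(p, 1, 2, alpha)
    expect_equal(pskewnorm(q, 1, 2, alpha), p, tolerance = 1e-9)
    set.seed(99)
    x <- rskewnorm(2e5, 1, 2, alpha)
    expect_equal(mean(x), skewnorm_mean(1, 2, alpha), tolerance = 0.02)
    expect_equal(unname(quantile(x, 0.5)), qskewnorm(0.5, 1, 2, alpha),
                 tolerance = 0.03)
  }
})

test_that("effect resolution prefers crop rows, falls back to categories, zeroes the rest", {
  w <- tiny_world(seed = 12)
  res <- resolve_effects(w$foods, w$eco2_effects)
  dist_of <- function(id) res$dists[[res$foods$dist_id[res$foods$food_id == id]]]
  # wheat has a crop-level row: its law matches the fitted crop interval
  wheat_row <- w$eco2_effects[w$eco2_effects$crop_or_category == "wheat", ]
  fw <- fit_skew_normal(wheat_row$mean_pct_change, wheat_row$ci_lo, wheat_row$ci_hi)
  expect_equal(dist_of("wheat")$xi, fw$xi)
  # beans has no crop row: uses the LEGUME category law
  bean_row <- w$eco2_effects[w$eco2_effects$crop_or_category == "LEGUME", ]
  fb <- fit_skew_normal(bean_row$mean_pct_change, bean_row$ci_lo, bean_row$ci_hi)
  expect_equal(dist_of("beans")$xi, fb$xi)
  # animal and zero-effect foods map to the shared zero law (dist_id 0)
  for (id in c("beef", "milk", "sorghum", "potato")) {
    expect_equal(res$foods$dist_id[res$foods$food_id == id], 0L)
  }
  # an affected food with no entry anywhere is a configuration error
  eff2 <- w$eco2_effects[w$eco2_effects$crop_or_category != "MAIZE" &
                           w$eco2_effects$crop_or_category != "maize", ]
  expect_error(resolve_effects(w$foods, eff2), class = "ferro_config_error")
})

test_that("all-degenerate effects give a point mass at zero across every draw", {
  cat0 <- audit_catalog()
  sup <- tibble::tibble(country = "A", group = "women_15_49",
                        food_id = c("sorghum", "beef"), g_per_day = c(200, 50))
  ir <- iron_supply(sup, cat0)
  eff <- degenerate_effects()
  sim <- simulate_losses(ir, cat0, eff, n_draws = 1000, seed = 3)
  expect_equal(unname(sim$draws[, 1]), rep(0, 1000))
  expect_equal(sim$summary$median_loss_pct, 0)
})

test_that("a single food with a degenerate -5% effect loses exactly 5%", {
  cat0 <- audit_catalog()
  sup <- tibble::tibble(country = "A", group = "women_15_49",
                        food_id = "wheat", g_per_day = 120)
  ir <- iron_supply(sup, cat0)
  sim <- simulate_losses(ir, cat0, degenerate_effects(wheat = -5),
                         n_draws = 250, seed = 1)
  expect_equal(unname(sim$draws[, 1]), rep(5, 250))
})

test_that("losses are reproducible under a fixed seed and change with it", {
  w <- tiny_world(seed = 31, n_countries = 3)
  ir <- iron_supply(disaggregate(w$supply, w$foods, w$gdd, w$energy)[
    c("country", "food_id", "group", "g_per_day")], w$foods)
  s1 <- simulate_losses(ir, w$foods, w$eco2_effects, w$gdd, n_draws = 100, seed = 5)
  s2 <- simulate_losses(ir, w$foods, w$eco2_effects, w$gdd, n_draws = 100, seed = 5)
  s3 <- simulate_losses(ir, w$foods, w$eco2_effects, w$gdd, n_draws = 100, seed = 6)
  expect_identical(s1$draws, s2$draws)
  expect_false(identical(s1$draws, s3$draws))
})

test_that("every draw's loss is a convex combination of its per-food losses", {
  w <- tiny_world(seed = 19, n_countries = 4)
  ir <- iron_supply(w$supply, w$foods)
  sim <- simulate_losses(ir, w$foods, w$eco2_effects, w$gdd,
                         n_draws = 300, seed = 2)
  neg <- -sim$effect_draws  # per-draw per-entry losses, positive = loss
  lo <- apply(cbind(0, neg), 1, min)  # unaffected foods contribute 0
  hi <- apply(cbind(0, neg), 1, max)
  for (u in seq_len(ncol(sim$draws))) {
    expect_true(all(sim$draws[, u] >= lo - 1e-12))
    expect_true(all(sim$draws[, u] <= hi + 1e-12))
  }
})

test_that("raising an affected food's iron share raises the expected loss", {
  cat0 <- audit_catalog()
  eff <- degenerate_effects(wheat = -6, legume = -3)
  mk <- function(wheat_g) {
    sup <- tibble::tibble(country = "A", group = "women_15_49",
                          food_id = c("wheat", "sorghum"),
                          g_per_day = c(wheat_g, 200))
    simulate_losses(iron_supply(sup, cat0), cat0, eff,
                    n_draws = 50, seed = 4)$summary$mean_loss_pct
  }
  losses <- vapply(c(20, 60, 150, 400), mk, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("intake perturbations have unit mean and propagate factor uncertainty", {
  b <- cameroon_fixture()
  d <- disaggregate(b$supply, b$foods, b$gdd, b$energy, "women_15_49")
  ir <- iron_supply(d[c("country", "food_id", "group", "g_per_day")], b$foods)
  # with sd 0 the draws collapse onto the deterministic loss
  gdd0 <- b$gdd; gdd0$factor_sd <- 0
  eff <- degenerate_effects(wheat = -5, legume = -4)
  s0 <- simulate_losses(ir, b$foods, eff, gdd0, n_draws = 50, seed = 1)
  expect_equal(stats::sd(s0$draws[, 1]), 0)
  # with sd > 0 the spread is nonzero but the mean loss is stable
  eff_c3 <- b$eco2_effects  # pumpkin/cassava unaffected -> zero loss anyway
  s1 <- simulate_losses(ir, b$foods, eff_c3, b$gdd, n_draws = 200, seed = 1)
  expect_equal(unname(s1$draws[, 1]), rep(0, 200))  # no affected food
})
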