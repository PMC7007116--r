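# shared fixtures: all synthetic, built in code at test time

tiny_world <- function(seed = 1, n_countries = 6, n_foods = 18, ...) {
  generate_world(world_config(n_countries = n_countries, n_foods = n_foods,
                              seed = seed, ...))
}

# a hand-built single-country bundle where every number is easy to audit:
# two affected foods, one zero-effect food, one animal food
audit_catalog <- function() {
  tibble::tibble(
    food_id = c("wheat", "beans", "sorghum", "beef"),
    food_name = c("Wheat", "Beans", "Sorghum", "Beef"),
    genus_group = c("cereals", "pulses", "cereals", "meat"),
    gdd_group = c("refined_grains", "beans_legumes", NA, "red_meat"),
    eco2_category = c("C3_GRAIN", "LEGUME", "ZERO_EFFECT", "ANIMAL"),
    iron_mg_per_100g = c(3.5, 6.5, 3.4, 2.6),
    kcal_per_100g = c(340, 340, 340, 250),
    is_animal = c(FALSE, FALSE, FALSE, TRUE),
    is_wild = FALSE
  )
}

# degenerate (point-mass) effect rows for exact arithmetic in tests
degenerate_effects <- function(wheat = -5, legume = -4) {
  tibble::tibble(
    crop_or_category = c("wheat", "LEGUME"),
    level = c("CROP", "CATEGORY"),
    mean_pct_change = c(wheat, legume),
    ci_lo = NA_real_, ci_hi = NA_real_,
    n_samples = c(100, 50), p_value = 1e-4
  )
}
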