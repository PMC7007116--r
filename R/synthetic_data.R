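# Synthetic world generator: builds complete, internally consistent input
# bundles (all seven tables) with the statistical structure the analysis
# assumes, so every downstream stage can be exercised without external
# datasets. Each table draws from its own RNG stream, derived from the
# master seed by a fixed offset, so adding or regenerating one table never
# perturbs the others.

seed_offsets <- c(foods = 11L, supply = 23L, gdd = 37L, energy = 47L,
                  anemia = 59L, population = 71L, eco2 = 83L)

#' Configuration for a synthetic world
#'
#' @param n_countries Number of countries to generate.
#' @param n_foods Number of foods in the catalog (minimum 10).
#' @param staple_share Fraction of national calories supplied by the
#'   country's staple grain (default 0.4).
#' @param anemia_range Two-element range of anemia prevalence percentages
#'   across countries.
#' @param diversity_anemia_slope Strength of the built-in negative
#'   association between anemia and diet concentration; larger magnitude
#'   concentrates iron into fewer foods in high-anemia countries.
#' @param wild_country_fraction Fraction of countries given substantial
#'   wild-harvest food supply.
#' @param seed Master RNG seed; the whole bundle is a deterministic
#'   function of the configuration including this seed.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(n_countries = 20, n_foods = 30, staple_share = 0.4,
                         anemia_range = c(5, 60), diversity_anemia_slope = 1.5,
                         wild_country_fraction = 0.25, seed = 1L) {
  if (n_foods < 10) stop_config("n_foods must be >= 10")
  if (!(staple_share > 0 && staple_share < 1)) {
    stop_config("staple_share must lie strictly between 0 and 1")
  }
  if (n_countries < 1) stop_config("n_countries must be >= 1")
  if (length(anemia_range) != 2 || anemia_range[1] >= anemia_range[2] ||
      anemia_range[1] < 0 || anemia_range[2] > 100) {
    stop_config("anemia_range must be an increasing pair within [0, 100]")
  }
  structure(list(n_countries = as.integer(n_countries),
                 n_foods = as.integer(n_foods),
                 staple_share = staple_share, anemia_range = anemia_range,
                 diversity_anemia_slope = diversity_anemia_slope,
                 wild_country_fraction = wild_country_fraction,
                 seed = as.integer(seed)),
            class = "world_config")
}

# fixed core foods present in every world; the remainder are generic
# vegetal foods. Densities are typical table values (mg iron and kcal per
# 100 g edible portion).
core_foods <- function() {
  tibble(
    food_id = c("wheat", "rice", "maize", "beans", "field_peas", "sorghum",
                "potato", "cassava", "beef", "fish", "milk", "eggs",
                "leafy_greens", "wild_greens"),
    food_name = c("Wheat", "Rice", "Maize", "Beans, dry", "Field peas",
                  "Sorghum", "Potatoes", "Cassava", "Beef", "Fish, fresh",
                  "Milk", "Eggs", "Leafy green vegetables", "Wild leafy greens"),
    genus_group = c("cereals", "cereals", "cereals", "pulses", "pulses",
                    "cereals", "starchy_roots", "starchy_roots", "meat",
                    "fish", "dairy", "eggs", "vegetables", "vegetables"),
    gdd_group = c("refined_grains", "refined_grains", "refined_grains",
                  "beans_legumes", "beans_legumes", "refined_grains",
                  NA, NA, "red_meat", "seafood", "dairy", "eggs",
                  "vegetables", "vegetables"),
    eco2_category = c("C3_GRAIN", "C3_GRAIN", "MAIZE", "LEGUME", "LEGUME",
                      "ZERO_EFFECT", "ZERO_EFFECT", "OTHER_VEGETAL",
                      "ANIMAL", "ANIMAL", "ANIMAL", "ANIMAL",
                      "OTHER_VEGETAL", "OTHER_VEGETAL"),
    iron_mg_per_100g = c(3.5, 1.3, 2.7, 6.5, 4.5, 3.4, 0.8, 0.3, 2.6, 1.0,
                         0.05, 1.8, 2.5, 3.0),
    kcal_per_100g = c(340, 360, 365, 340, 345, 340, 77, 160, 250, 120,
                      62, 150, 30, 35),
    is_animal = c(rep(FALSE, 8), rep(TRUE, 4), FALSE, FALSE),
    is_wild = c(rep(FALSE, 13), TRUE)
  )
}

generate_foods <- function(cfg) {
  withr::with_seed(cfg$seed + seed_offsets[["foods"]], {
    foods <- core_foods()
    if (cfg$n_foods < nrow(foods)) foods <- foods[seq_len(cfg$n_foods), ]
    n_extra <- cfg$n_foods - nrow(foods)
    if (n_extra > 0) {
      gdd_pool <- c("vegetables", "fruits", "beans_legumes", "nuts_seeds", NA)
      extra <- tibble(
        food_id = sprintf("veg_%02d", seq_len(n_extra)),
        food_name = sprintf("Vegetal food %02d", seq_len(n_extra)),
        genus_group = sample(c("vegetables", "fruits", "nuts"), n_extra, TRUE),
        gdd_group = sample(gdd_pool, n_extra, TRUE),
        eco2_category = sample(c("OTHER_VEGETAL", "LEGUME", "ZERO_EFFECT"),
                               n_extra, TRUE, prob = c(0.6, 0.2, 0.2)),
        iron_mg_per_100g = round(rlnorm(n_extra, log(1.5), 0.6), 2),
        kcal_per_100g = round(runif(n_extra, 25, 380), 0),
        is_animal = FALSE,
        is_wild = FALSE
      )
      extra$gdd_group[extra$eco2_category == "LEGUME"] <- "beans_legumes"
      foods <- bind_rows(foods, extra)
    }
    foods
  })
}

# effect table mirroring the crop-level estimates and sample-weighted
# category pools of the field-trial meta-analysis: C3 grains, legumes and
# maize decline 3-10%; sorghum and potato changes are non-significant
generate_effects <- function(cfg) {
  withr::with_seed(cfg$seed + seed_offsets[["eco2"]], {
    crops <- tibble(
      crop_or_category = c("wheat", "rice", "maize", "field_peas",
                           "sorghum", "potato"),
      level = "CROP",
      mean_pct_change = c(round(runif(4, -10, -3), 2), 1.2, -0.7),
      n_samples = c(120, 90, 50, 30, 10, 12),
      p_value = c(1e-4, 1e-3, 0.01, 0.02, 0.153, 0.555)
    )
    half <- runif(6, 1.5, 3.5)
    skew <- runif(6, 0.72, 1.38)  # mild asymmetry, within skew-normal reach
    crops$ci_lo <- crops$mean_pct_change - half * skew
    crops$ci_hi <- crops$mean_pct_change + half / skew
    cats <- tibble(
      crop_or_category = c("C3_GRAIN", "LEGUME", "MAIZE"),
      level = "CATEGORY",
      mean_pct_change = round(runif(3, -9, -4), 2),
      n_samples = c(200, 80, 50),
      p_value = c(1e-4, 1e-3, 0.01)
    )
    halfc <- runif(3, 1.5, 3)
    skewc <- runif(3, 0.75, 1.3)
    cats$ci_lo <- cats$mean_pct_change - halfc * skewc
    cats$ci_hi <- cats$mean_pct_change + halfc / skewc
    cols <- c("crop_or_category", "level", "mean_pct_change",
              "ci_lo", "ci_hi", "n_samples", "p_value")
    bind_rows(crops[cols], cats[cols])
  })
}

#' Generate a complete synthetic input bundle
#'
#' Builds all seven input tables for a configurable number of countries
#' and foods. Food supplies are right-skewed (log-normal) with one
#' dominant staple grain per country; supplies are rescaled so each
#' country's dietary energy audit matches its stated national calorie
#' supply exactly. Relative-intake factors are log-normal around 1 with
#' standard deviations in 0.02-0.15. Elevated-CO2 effects for C3 grains,
#' legumes and maize fall in the measured -10% to -3% range; sorghum and
#' potato carry non-significant changes. High-anemia countries concentrate
#' their supply (and hence iron) in fewer foods, so a negative
#' diversity-anemia association is built in and recoverable downstream.
#'
#' @param cfg A [world_config()].
#' @return A bundle: named list of tibbles `foods`, `supply`, `gdd`,
#'   `energy`, `anemia`, `population`, `eco2_effects`.
#' @export
generate_world <- function(cfg = world_config()) {
  if (!inherits(cfg, "world_config")) stop_config("cfg must be a world_config")
  foods <- generate_foods(cfg)
  effects <- generate_effects(cfg)
  countries <- sprintf("Country_%03d", seq_len(cfg$n_countries))
  groups <- study_groups()

  anemia_tbl <- withr::with_seed(cfg$seed + seed_offsets[["anemia"]], {
    base <- runif(cfg$n_countries, cfg$anemia_range[1], cfg$anemia_range[2])
    tidyr::crossing(country = countries, group = groups$group) %>%
      arrange(match(country, countries)) %>%
      mutate(anemia_pct = round(pmin(pmax(
        base[match(country, countries)] + rnorm(n(), 0, 2), 0), 100), 1))
  })
  # country-level severity in [0,1] drives diet concentration below
  sev_tbl <- anemia_tbl %>% group_by(country) %>%
    summarise(anemia_mean = mean(anemia_pct), .groups = "drop")
  severity <- (sev_tbl$anemia_mean - cfg$anemia_range[1]) /
    diff(cfg$anemia_range)
  severity <- pmin(pmax(severity, 0), 1)[match(countries, sev_tbl$country)]

  energy_tbl <- withr::with_seed(cfg$seed + seed_offsets[["energy"]], {
    nat <- round(runif(cfg$n_countries, 2000, 2900), 0)
    bind_rows(
      tibble(country = countries, group = "NATIONAL", kcal_per_day = nat),
      tidyr::crossing(country = countries, group = groups$group) %>%
        mutate(kcal_per_day = round(ifelse(group == "children_1_5",
                                           runif(n(), 1200, 1500),
                                           runif(n(), 2000, 2400)), 0))
    )
  })
  nat_energy <- energy_tbl$kcal_per_day[energy_tbl$group == "NATIONAL"]
  names(nat_energy) <- energy_tbl$country[energy_tbl$group == "NATIONAL"]

  supply_tbl <- withr::with_seed(cfg$seed + seed_offsets[["supply"]], {
    wild_cut <- ceiling(cfg$wild_country_fraction * cfg$n_countries)
    wild_countries <- if (wild_cut > 0) sample(countries, wild_cut) else character(0)
    staples <- c("wheat", "rice", "maize")
    rows <- lapply(seq_along(countries), function(i) {
      co <- countries[i]
      # concentration: high-anemia countries get a wider log-normal spread,
      # so fewer foods carry the bulk of supply and iron
      sdlog <- 0.5 + cfg$diversity_anemia_slope * severity[i]
      g <- rlnorm(nrow(foods), meanlog = log(20), sdlog = sdlog)
      # poorer (high-anemia) countries eat fewer animal-source foods
      g[foods$is_animal] <- g[foods$is_animal] * (1.7 - 1.5 * severity[i])
      g[foods$is_wild] <- if (co %in% wild_countries) {
        rlnorm(sum(foods$is_wild), log(150), 0.3)
      } else 0
      kcal <- g * foods$kcal_per_100g / 100
      staple <- staples[1 + (i %% length(staples))]
      si <- match(staple, foods$food_id)
      # boost the staple so it carries staple_share of calories
      other <- sum(kcal[-si])
      kcal[si] <- other * cfg$staple_share / (1 - cfg$staple_share)
      g[si] <- kcal[si] * 100 / foods$kcal_per_100g[si]
      # rescale everything so the energy audit matches the stated supply
      scale <- nat_energy[[co]] / sum(g * foods$kcal_per_100g / 100)
      tibble(country = co, food_id = foods$food_id, group = "NATIONAL",
             g_per_day = g * scale)
    })
    bind_rows(rows) %>% filter(g_per_day > 0)
  })

  gdd_tbl <- withr::with_seed(cfg$seed + seed_offsets[["gdd"]], {
    gdd_groups <- sort(unique(foods$gdd_group[!is.na(foods$gdd_group)]))
    tidyr::crossing(country = countries, gdd_group = gdd_groups,
                    group = groups$group) %>%
      left_join(groups, by = "group") %>%
      mutate(factor = rlnorm(n(), 0, 0.08),
             factor_sd = runif(n(), 0.02, 0.15)) %>%
      select("country", "gdd_group", "sex", "age_lo", "age_hi",
             "factor", "factor_sd")
  })

  population_tbl <- withr::with_seed(cfg$seed + seed_offsets[["population"]], {
    gdp <- round(rlnorm(cfg$n_countries, log(20000), 0.5) *
                   exp(-2.5 * severity), 0)  # poorer where anemia is high
    tidyr::crossing(country = countries, group = groups$group) %>%
      arrange(match(country, countries)) %>%
      mutate(headcount = round(ifelse(group == "children_1_5",
                                      rlnorm(n(), log(2e6), 1),
                                      rlnorm(n(), log(6e6), 1)), 0),
             gdp_per_capita = gdp[match(country, countries)])
  })

  bundle <- list(foods = foods, supply = supply_tbl,
                 gdd = validate_gdd_factors(gdd_tbl), energy = energy_tbl,
                 anemia = anemia_tbl, population = population_tbl,
                 eco2_effects = effects)
  validate_food_catalog(bundle$foods)
  validate_supply_table(bundle$supply)
  validate_energy_profiles(bundle$energy)
  validate_anemia(bundle$anemia)
  validate_population(bundle$population)
  validate_eco2_effects(bundle$eco2_effects)
  bundle
}

#' The printed worked-example fixture (Cameroon)
#'
#' A minimal bundle encoding the published worked example of the two
#' disaggregation paths: pumpkins/squash/gourds at a national 23.8 g/d
#' with a vegetables relative-intake factor of 0.958 (4.2% below average)
#' for women of childbearing age, and cassava at a national 216.8 g/d
#' with no dietary-database group, scaled instead by a dietary-energy
#' factor of +0.9% (national calorie supply 2175 kcal/d, the woman's
#' requirement encoded as 2175 x 1.009 so the factor is exactly +0.9%).
#'
#' @return A bundle (named list of the seven input tibbles) for the single
#'   country `"Cameroon"`.
#' @export
cameroon_fixture <- function() {
  foods <- tibble(
    food_id = c("pumpkin", "cassava"),
    food_name = c("Pumpkins, squash and gourds", "Cassava"),
    genus_group = c("vegetables", "starchy_roots"),
    gdd_group = c("vegetables", NA),
    eco2_category = c("OTHER_VEGETAL", "OTHER_VEGETAL"),
    iron_mg_per_100g = c(0.8, 0.3),
    kcal_per_100g = c(26, 160),
    is_animal = FALSE, is_wild = FALSE
  )
  supply <- tibble(country = "Cameroon",
                   food_id = c("pumpkin", "cassava"),
                   group = "NATIONAL", g_per_day = c(23.8, 216.8))
  gdd <- tibble(country = "Cameroon", gdd_group = "vegetables",
                sex = "F", age_lo = 15, age_hi = 49,
                factor = 0.958, factor_sd = 0.05)
  energy <- tibble(country = "Cameroon",
                   group = c("NATIONAL", "women_15_49", "children_1_5"),
                   kcal_per_day = c(2175, 2175 * 1.009, 1350))
  anemia <- tibble(country = "Cameroon",
                   group = c("children_1_5", "women_15_49"),
                   anemia_pct = c(57, 41))
  population <- tibble(country = "Cameroon",
                       group = c("children_1_5", "women_15_49"),
                       headcount = c(3.4e6, 5.6e6))
  effects <- tibble(crop_or_category = "C3_GRAIN", level = "CATEGORY",
                    mean_pct_change = -6, ci_lo = -9, ci_hi = -3.5,
                    n_samples = 200, p_value = 1e-4)
  list(foods = foods, supply = supply, gdd = validate_gdd_factors(gdd),
       energy = energy, anemia = anemia, population = population,
       eco2_effects = effects)
}
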