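# Vegetarian counterfactual and the dietary-diversity statistic with its
# anemia association and wild-harvest exclusion.

#' Vegetarian diet counterfactual
#'
#' Removes all animal-source foods (meat, fish, dairy, eggs) from each
#' country's national-average diet and replaces their calories with a
#' proportional increase in the remaining vegetal foods: every vegetal
#' supply is multiplied by one country-level factor
#' `total_energy / vegetal_energy`, so total dietary energy is conserved
#' exactly.
#'
#' @param national Supply tibble restricted to `group == "NATIONAL"`.
#' @param catalog Food catalog tibble.
#' @return A list with `supply` (the transformed national supply tibble,
#'   animal rows at zero) and `factors` (tibble `country, factor`).
#' @export
vegetarian_transform <- function(national, catalog) {
  validate_supply_table(national)
  national <- national[national$group == "NATIONAL", ]
  df <- national %>%
    left_join(catalog[c("food_id", "is_animal", "kcal_per_100g")],
              by = "food_id")
  if (any(is.na(df$is_animal))) {
    stop_lookup(paste0("food(s) missing from catalog: ",
                       paste(unique(df$food_id[is.na(df$is_animal)]),
                             collapse = ", ")))
  }
  df$kcal <- df$g_per_day * df$kcal_per_100g / 100
  audit <- df %>% group_by(.data$country) %>%
    summarise(total = sum(.data$kcal),
              vegetal = sum(.data$kcal[!.data$is_animal]), .groups = "drop")
  if (any(audit$vegetal <= 0)) {
    stop_scenario(paste0("zero vegetal energy, no vegetarian diet for: ",
                         paste(audit$country[audit$vegetal <= 0], collapse = ", ")))
  }
  audit$factor <- audit$total / audit$vegetal
  df <- df %>% left_join(audit[c("country", "factor")], by = "country") %>%
    mutate(g_per_day = ifelse(.data$is_animal, 0,
                              .data$g_per_day * .data$factor))
  list(supply = df[c("country", "food_id", "group", "g_per_day")],
       factors = audit[c("country", "factor")])
}

#' Incremental loss of a scenario over the baseline
#'
#' @param base_losses,scenario_losses Loss summary tibbles
#'   (`country, group, median_loss_pct`) computed with identical seeds
#'   and draw counts.
#' @return A tibble `country, group, delta_pct`: scenario median loss
#'   minus baseline median loss, in percentage points.
#' @export
scenario_loss_delta <- function(base_losses, scenario_losses) {
  key <- function(df) sort(paste(df$country, df$group))
  if (!identical(key(base_losses), key(scenario_losses))) {
    stop_domain("baseline and scenario cover different country/group sets")
  }
  base_losses %>%
    select("country", "group", base = "median_loss_pct") %>%
    inner_join(select(scenario_losses, "country", "group",
                      scen = "median_loss_pct"),
               by = c("country", "group")) %>%
    mutate(delta_pct = .data$scen - .data$base) %>%
    select("country", "group", "delta_pct")
}

#' Number of foods supplying a given share of dietary iron
#'
#' Foods are ranked by iron contribution (ties broken by `food_id` so the
#' count is deterministic) and the statistic is the smallest prefix whose
#' cumulative share reaches the threshold. The default 99% threshold
#' excludes foods consumed in negligible (<<1%) proportions.
#'
#' @param iron_by_food Tibble `food_id, iron_mg_per_day` for one
#'   country/group (extra columns ignored).
#' @param threshold Cumulative share to reach, in (0, 1]; default 0.99.
#' @return Integer count of foods.
#' @export
diversity_count <- function(iron_by_food, threshold = 0.99) {
  v <- iron_by_food$iron_mg_per_day
  total <- sum(v)
  if (!is.finite(total) || total <= 0) {
    stop_domain("zero total iron: diversity undefined")
  }
  ord <- order(-v, iron_by_food$food_id)
  cum <- cumsum(v[ord]) / total
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Country-level diversity points
#'
#' Computes the iron-source diversity count per country on national-average
#' diets, joins mean anemia prevalence across the study groups, and flags
#' countries whose share of dietary iron from wild-harvest foods exceeds
#' `wild_share_cut` (a proxy for reliance on foods unaccounted in national
#' statistics).
#'
#' @param iron Result of [iron_supply()] on national supplies.
#' @param catalog Food catalog tibble.
#' @param anemia Anemia tibble.
#' @param threshold Diversity cumulative-share threshold (default 0.99).
#' @param wild_share_cut Wild-harvest iron share above which a country is
#'   flagged (default 0.05).
#' @return A tibble `country, n_sources, anemia_pct, wild_flag`.
#' @export
diversity_points <- function(iron, catalog, anemia, threshold = 0.99,
                             wild_share_cut = 0.05) {
  nat <- iron$by_food[iron$by_food$group == "NATIONAL", ]
  wild_ids <- catalog$food_id[catalog$is_wild]
  countries <- unique(nat$country)
  pts <- lapply(countries, function(co) {
    sub <- nat[nat$country == co, ]
    wshare <- sum(sub$iron_mg_per_day[sub$food_id %in% wild_ids]) /
      sum(sub$iron_mg_per_day)
    tibble(country = co,
           n_sources = diversity_count(sub, threshold),
           wild_flag = wshare > wild_share_cut)
  })
  an <- anemia %>% group_by(.data$country) %>%
    summarise(anemia_pct = mean(.data$anemia_pct), .groups = "drop")
  bind_rows(pts) %>% inner_join(an, by = "country") %>%
    select("country", "n_sources", "anemia_pct", "wild_flag")
}

#' Regression of iron-source diversity on log anemia prevalence
#'
#' Ordinary least squares of the diversity count on the natural logarithm
#' of anemia prevalence; a negative slope means countries with more
#' anemia draw their iron from fewer foods. Optionally drops
#' wild-harvest-flagged countries first, mirroring the robustness check
#' against unaccounted wild foods.
#'
#' @param points Tibble of diversity points
#'   (`country, n_sources, anemia_pct, wild_flag`).
#' @param exclude_wild Drop flagged countries before fitting.
#' @param log_response Regress `log(n_sources)` on `anemia_pct` instead
#'   (alternative reading of a "logarithmic relationship").
#' @return A list with `intercept`, `slope`, `r`, `n`.
#' @export
diversity_anemia_fit <- function(points, exclude_wild = FALSE,
                                 log_response = FALSE) {
  if (exclude_wild) points <- points[!points$wild_flag, ]
  if (nrow(points) < 3) stop_fit("fewer than 3 points after exclusion")
  if (any(points$anemia_pct <= 0)) stop_domain("anemia_pct must be > 0")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else cor(x, y)
  }
  if (log_response) {
    fit <- lm(log(n_sources) ~ anemia_pct, data = points)
    r <- safe_cor(points$anemia_pct, log(points$n_sources))
  } else {
    fit <- lm(n_sources ~ log(anemia_pct), data = points)
    r <- safe_cor(log(points$anemia_pct), points$n_sources)
  }
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r = r, n = nrow(points))
}
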