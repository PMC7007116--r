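# Dietary iron accounting: per-food and total iron supply per country and
# age-sex group, and the decomposition of total iron by effect class.

#' Iron supplied by one food
#'
#' @param supply Edible supply in g/person/day, `>= 0`.
#' @param iron_density Iron density in mg per 100 g edible portion, `>= 0`.
#' @return Iron supply in mg/person/day, `supply * iron_density / 100`.
#' @export
iron_from_food <- function(supply, iron_density) {
  if (any(!is.finite(supply) | supply < 0) ||
      any(!is.finite(iron_density) | iron_density < 0)) {
    stop_domain("supply and iron_density must be finite and >= 0")
  }
  supply * iron_density / 100
}

#' Compute dietary iron supply per food and in total
#'
#' @param supply A supply tibble (`country, food_id, group, g_per_day`),
#'   national or disaggregated.
#' @param catalog Food catalog tibble.
#' @return A list with `by_food` (tibble `country, group, food_id,
#'   iron_mg_per_day`) and `totals` (tibble `country, group,
#'   total_iron_mg_per_day`).
#' @export
iron_supply <- function(supply, catalog) {
  validate_food_catalog(catalog)
  unknown <- setdiff(supply$food_id, catalog$food_id)
  if (length(unknown) > 0) {
    stop_lookup(paste0("food(s) missing from catalog: ",
                       paste(unknown, collapse = ", ")))
  }
  by_food <- supply %>%
    left_join(catalog[c("food_id", "iron_mg_per_100g")], by = "food_id") %>%
    mutate(iron_mg_per_day = iron_from_food(.data$g_per_day,
                                            .data$iron_mg_per_100g)) %>%
    select("country", "group", "food_id", "iron_mg_per_day")
  totals <- by_food %>%
    group_by(.data$country, .data$group) %>%
    summarise(total_iron_mg_per_day = sum(.data$iron_mg_per_day),
              .groups = "drop")
  list(by_food = by_food, totals = totals)
}

#' Decompose dietary iron by effect class
#'
#' Splits each country/group's total iron across three source classes:
#' vegetal foods whose iron content declines under elevated CO2 (C3
#' grains, legumes, maize), vegetal foods with no or unknown effect, and
#' animal-source foods.
#'
#' @param iron The result of [iron_supply()].
#' @param catalog Food catalog tibble.
#' @return A tibble `country, group, affected_vegetal, unaffected_vegetal,
#'   animal` of shares summing to 1 per row.
#' @export
source_decomposition <- function(iron, catalog) {
  cls <- ifelse(catalog$eco2_category == "ANIMAL", "animal",
                ifelse(catalog$eco2_category %in% affected_categories(),
                       "affected_vegetal", "unaffected_vegetal"))
  classes <- tibble(food_id = catalog$food_id, class = cls)
  agg <- iron$by_food %>%
    left_join(classes, by = "food_id") %>%
    group_by(.data$country, .data$group, .data$class) %>%
    summarise(iron = sum(.data$iron_mg_per_day), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "iron",
                       values_fill = 0)
  for (col in c("affected_vegetal", "unaffected_vegetal", "animal")) {
    if (!col %in% names(agg)) agg[[col]] <- 0
  }
  tot <- agg$affected_vegetal + agg$unaffected_vegetal + agg$animal
  if (any(tot <= 0)) {
    bad <- paste(agg$country[tot <= 0], agg$group[tot <= 0])
    stop_domain(paste0("zero total iron, shares undefined for: ",
                       paste(bad, collapse = "; ")))
  }
  agg %>%
    mutate(affected_vegetal = .data$affected_vegetal / tot,
           unaffected_vegetal = .data$unaffected_vegetal / tot,
           animal = .data$animal / tot) %>%
    select("country", "group", "affected_vegetal", "unaffected_vegetal",
           "animal")
}

#' Correlation between income and nonanimal iron share
#'
#' Descriptive reporting statistic: Pearson correlation between the
#' logarithm of GDP per capita and the share of dietary iron from
#' nonanimal sources, computed on national-average diets.
#'
#' @param shares Output of [source_decomposition()].
#' @param population Population tibble carrying a `gdp_per_capita` column.
#' @param group Group token to use (default `"NATIONAL"`).
#' @return A list with `r` (the correlation) and `n` (countries used).
#' @export
income_iron_correlation <- function(shares, population, group = "NATIONAL") {
  if (!"gdp_per_capita" %in% names(population)) {
    stop_schema("population table has no gdp_per_capita column")
  }
  gdp <- population %>% distinct(.data$country, .data$gdp_per_capita)
  df <- shares[shares$group == group, ] %>%
    mutate(nonanimal = 1 - .data$animal) %>%
    inner_join(gdp, by = "country") %>%
    filter(is.finite(.data$gdp_per_capita), .data$gdp_per_capita > 0)
  if (nrow(df) < 3) stop_domain("fewer than 3 countries with GDP data")
  list(r = cor(log(df$gdp_per_capita), df$nonanimal), n = nrow(df))
}
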