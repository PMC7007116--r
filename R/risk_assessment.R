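# Risk stratification: cross per-country median iron losses with anemia
# prevalence, aggregate vulnerable populations per category, and account
# for the top dietary sources of lost iron among high-risk populations.

#' Risk-classification configuration
#'
#' Defaults reproduce the published rule: loss tertile cutoffs 3.1% and
#' 3.8% crossed with a 20% anemia-prevalence threshold. With
#' `tertile_mode = "RECOMPUTE"` the cutoffs are re-derived as the 1/3 and
#' 2/3 empirical quantiles of the per-country median losses at hand.
#'
#' @param anemia_threshold Anemia prevalence threshold, percent, in (0, 100).
#' @param loss_cut_lo,loss_cut_hi Loss tertile cutoffs, percent,
#'   `loss_cut_lo < loss_cut_hi`.
#' @param tertile_mode `"FIXED"` (published cutoffs) or `"RECOMPUTE"`.
#' @param high_loss_low_anemia Category for the cell the published rule
#'   leaves unstated (loss above the upper cutoff but anemia at or below
#'   the threshold); default `"MILD"`.
#' @return A `risk_config` list.
#' @export
risk_config <- function(anemia_threshold = 20, loss_cut_lo = 3.1,
                        loss_cut_hi = 3.8, tertile_mode = c("FIXED", "RECOMPUTE"),
                        high_loss_low_anemia = "MILD") {
  tertile_mode <- match.arg(tertile_mode)
  if (!(loss_cut_lo < loss_cut_hi)) stop_config("loss_cut_lo must be < loss_cut_hi")
  if (!(anemia_threshold > 0 && anemia_threshold < 100)) {
    stop_config("anemia_threshold must lie in (0, 100)")
  }
  if (!high_loss_low_anemia %in% c("MILD", "MODERATE", "HIGH", "NONE")) {
    stop_config("high_loss_low_anemia must be a valid category")
  }
  structure(list(anemia_threshold = anemia_threshold,
                 loss_cut_lo = loss_cut_lo, loss_cut_hi = loss_cut_hi,
                 tertile_mode = tertile_mode,
                 high_loss_low_anemia = high_loss_low_anemia),
            class = "risk_config")
}

#' Assign a risk category from loss and anemia prevalence
#'
#' HIGH: loss above the upper cutoff and anemia above the threshold.
#' MODERATE / MILD: loss within the middle band (inclusive at both ends),
#' split by the anemia threshold. NONE: loss below the lower cutoff,
#' regardless of anemia. Loss above the upper cutoff with anemia at or
#' below the threshold goes to the configured `high_loss_low_anemia`
#' category (MILD by default). Anemia exactly at the threshold counts as
#' "not over" it.
#'
#' @param loss_pct Percentage dietary iron loss (vectorised).
#' @param anemia_pct Anemia prevalence, percent (vectorised).
#' @param cfg A [risk_config()].
#' @return Character vector of `"HIGH"`, `"MODERATE"`, `"MILD"`, `"NONE"`.
#' @export
classify <- function(loss_pct, anemia_pct, cfg = risk_config()) {
  if (any(!is.finite(loss_pct)) || any(!is.finite(anemia_pct))) {
    stop_domain("loss and anemia must be finite")
  }
  high_anemia <- anemia_pct > cfg$anemia_threshold
  ifelse(loss_pct < cfg$loss_cut_lo, "NONE",
         ifelse(loss_pct > cfg$loss_cut_hi,
                ifelse(high_anemia, "HIGH", cfg$high_loss_low_anemia),
                ifelse(high_anemia, "MODERATE", "MILD")))
}

#' Empirical loss tertile cutoffs
#'
#' @param losses Numeric vector of per-country median losses, length >= 3.
#' @return Named numeric vector `c(lo, hi)`: the 1/3 and 2/3 empirical
#'   quantiles.
#' @export
tertile_cutoffs <- function(losses) {
  if (length(losses) < 3) stop_domain("tertile cutoffs need >= 3 countries")
  q <- quantile(losses, probs = c(1, 2) / 3, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Classify every country/group and attach losses and anemia
#'
#' @param losses Loss summary tibble (`country, group, median_loss_pct`, as
#'   from [simulate_losses()]`$summary`).
#' @param anemia Anemia tibble.
#' @param cfg A [risk_config()]; with `tertile_mode = "RECOMPUTE"` the
#'   cutoffs are re-derived from the per-country losses first.
#' @return A tibble `country, group, median_loss_pct, anemia_pct, category`.
#' @export
assess_risk <- function(losses, anemia, cfg = risk_config()) {
  if (cfg$tertile_mode == "RECOMPUTE") {
    per_country <- losses %>% group_by(.data$country) %>%
      summarise(m = median(.data$median_loss_pct), .groups = "drop")
    cuts <- tertile_cutoffs(per_country$m)
    cfg$loss_cut_lo <- cuts[["lo"]]
    cfg$loss_cut_hi <- cuts[["hi"]]
  }
  df <- losses %>%
    inner_join(anemia, by = c("country", "group"))
  if (nrow(df) < nrow(losses)) {
    miss <- dplyr::anti_join(losses, anemia, by = c("country", "group"))
    stop_lookup(paste0("no anemia prevalence for: ",
                       paste(utils::head(paste(miss$country, miss$group), 5),
                             collapse = "; ")))
  }
  df %>%
    mutate(category = classify(.data$median_loss_pct, .data$anemia_pct, cfg)) %>%
    select("country", "group", "median_loss_pct", "anemia_pct", "category")
}

#' Aggregate vulnerable populations per risk category
#'
#' @param assessment Output of [assess_risk()].
#' @param population Population tibble.
#' @return A tibble `category, headcount, share_pct` (share of the total
#'   covered population across both study groups), all four categories
#'   present.
#' @export
aggregate_population <- function(assessment, population) {
  df <- assessment %>% left_join(population, by = c("country", "group"))
  if (any(is.na(df$headcount))) {
    miss <- df[is.na(df$headcount), ]
    stop_lookup(paste0("no population row for: ",
                       paste(utils::head(paste(miss$country, miss$group), 5),
                             collapse = "; ")))
  }
  total <- sum(df$headcount)
  out <- df %>% group_by(.data$category) %>%
    summarise(headcount = sum(.data$headcount), .groups = "drop")
  all_cats <- tibble(category = c("HIGH", "MODERATE", "MILD", "NONE"))
  out <- all_cats %>% left_join(out, by = "category") %>%
    mutate(headcount = ifelse(is.na(.data$headcount), 0, .data$headcount),
           share_pct = 100 * .data$headcount / total)
  out
}

#' Top dietary sources of lost iron among high-risk populations
#'
#' For each food, sums over all HIGH-risk (country, group) units the
#' product of per-capita iron from that food (mg/person/day), the food's
#' expected fractional loss under elevated CO2, and the group headcount,
#' converted to kg/day. Both study groups contribute.
#'
#' @param iron Result of [iron_supply()] on disaggregated supplies.
#' @param catalog Food catalog tibble.
#' @param effects Effect tibble.
#' @param assessment Output of [assess_risk()].
#' @param population Population tibble.
#' @param alpha Significance level for the zero-effect rule.
#' @return A tibble `food_id, kg_per_day, rank` sorted by decreasing
#'   aggregate daily iron lost.
#' @export
top_lost_sources <- function(iron, catalog, effects, assessment, population,
                             alpha = 0.05) {
  exp_eff <- expected_effect_by_food(catalog, effects, alpha)
  high <- assessment[assessment$category == "HIGH", c("country", "group")]
  df <- iron$by_food %>%
    inner_join(high, by = c("country", "group")) %>%
    left_join(population[c("country", "group", "headcount")],
              by = c("country", "group")) %>%
    left_join(exp_eff, by = "food_id")
  if (any(is.na(df$headcount))) {
    stop_lookup("population rows missing for high-risk country/groups")
  }
  # expected loss fraction is positive for declines (negative pct change)
  out <- df %>%
    mutate(kg = .data$iron_mg_per_day * (-.data$expected_pct_change / 100) *
             .data$headcount * 1e-6) %>%
    group_by(.data$food_id) %>%
    summarise(kg_per_day = sum(.data$kg), .groups = "drop") %>%
    arrange(dplyr::desc(.data$kg_per_day)) %>%
    mutate(rank = dplyr::row_number())
  out
}
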