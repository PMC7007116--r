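# Age-sex disaggregation of national-average food supplies: foods with a
# dietary-database group are scaled by that group's relative-intake
# factor; all others are assumed eaten in proportion to the age-sex
# group's average dietary energy requirement.

#' Scale a national supply by a relative-intake factor
#'
#' @param national_supply National-average supply in g/person/day, `>= 0`.
#' @param factor Dimensionless relative-intake multiplier, `> 0`
#'   (1.0 = eaten at the national average).
#' @return The group supply in g/person/day, `national_supply * factor`.
#' @export
gdd_scale <- function(national_supply, factor) {
  if (any(!is.finite(national_supply) | national_supply < 0)) {
    stop_domain("national_supply must be finite and >= 0")
  }
  if (any(!is.finite(factor) | factor <= 0)) {
    stop_domain("relative-intake factor must be finite and > 0")
  }
  national_supply * factor
}

#' Energy-requirement fallback scaling factor
#'
#' For foods without a dietary-database group, intake is assumed
#' proportional to the group's average dietary energy requirement
#' relative to the national calorie supply.
#'
#' @param group_requirement Group average energy requirement, kcal/day, `> 0`.
#' @param national_supply_kcal National calorie supply, kcal/person/day, `> 0`.
#' @return The dimensionless factor `group_requirement / national_supply_kcal`.
#' @export
energy_fallback_factor <- function(group_requirement, national_supply_kcal) {
  if (any(!is.finite(group_requirement) | group_requirement <= 0) ||
      any(!is.finite(national_supply_kcal) | national_supply_kcal <= 0)) {
    stop_domain("energy inputs must be finite and > 0")
  }
  group_requirement / national_supply_kcal
}

#' Disaggregate national supplies to age-sex groups
#'
#' Every (country, food) in the national supply table is mapped to each
#' requested group: if the food has a dietary-database group and a factor
#' row exists for that (country, group), the national supply is scaled by
#' the factor (`GDD_MATCHED`); otherwise by the group's energy-requirement
#' factor (`ENERGY_FALLBACK`). Missing factor rows for a food that does
#' have a group fall back to energy scaling rather than erroring, so
#' partial factor coverage stays usable.
#'
#' @param national Supply tibble with `group == "NATIONAL"` rows.
#' @param catalog Food catalog tibble.
#' @param gdd Relative-intake factor tibble (as from [load_gdd_factors()]).
#' @param energy Energy-profile tibble with `NATIONAL` and per-group rows.
#' @param groups Character vector of group tokens to produce
#'   (default both study groups).
#' @return A tibble `country, food_id, group, g_per_day, provenance` with
#'   provenance `"GDD_MATCHED"` or `"ENERGY_FALLBACK"`.
#' @export
disaggregate <- function(national, catalog, gdd, energy,
                         groups = study_groups()$group) {
  validate_supply_table(national)
  validate_food_catalog(catalog)
  national <- national[national$group == "NATIONAL", ]
  unknown <- setdiff(national$food_id, catalog$food_id)
  if (length(unknown) > 0) {
    stop_lookup(paste0("food(s) missing from catalog: ",
                       paste(unknown, collapse = ", ")))
  }
  if (!"group" %in% names(gdd)) gdd <- validate_gdd_factors(gdd)
  nat_kcal <- energy[energy$group == "NATIONAL", c("country", "kcal_per_day")]
  req <- energy[energy$group != "NATIONAL", ]

  out <- lapply(groups, function(g) {
    df <- national %>%
      left_join(catalog[c("food_id", "gdd_group")], by = "food_id") %>%
      left_join(gdd[gdd$group == g, c("country", "gdd_group", "factor")],
                by = c("country", "gdd_group"))
    df <- df %>%
      left_join(rename(nat_kcal, nat_kcal = "kcal_per_day"), by = "country") %>%
      left_join(rename(req[req$group == g, c("country", "kcal_per_day")],
                       req_kcal = "kcal_per_day"), by = "country")
    need_fb <- is.na(df$factor)
    if (any(need_fb & (is.na(df$nat_kcal) | is.na(df$req_kcal)))) {
      miss <- unique(df$country[need_fb & (is.na(df$nat_kcal) | is.na(df$req_kcal))])
      stop_lookup(paste0("no energy profile for fallback in: ",
                         paste(miss, collapse = ", "), " (group ", g, ")"))
    }
    fb <- energy_fallback_factor(df$req_kcal[need_fb], df$nat_kcal[need_fb])
    scaled <- numeric(nrow(df))
    scaled[!need_fb] <- gdd_scale(df$g_per_day[!need_fb], df$factor[!need_fb])
    scaled[need_fb] <- df$g_per_day[need_fb] * fb
    tibble(country = df$country, food_id = df$food_id, group = g,
           g_per_day = scaled,
           provenance = ifelse(need_fb, "ENERGY_FALLBACK", "GDD_MATCHED"))
  })
  bind_rows(out)
}
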