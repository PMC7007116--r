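# Readers, writers and validators for the delimited-text input/output
# schemas. All tables are comma-separated UTF-8 with one header line and
# "." as the decimal mark; country names are opaque free-text keys.

read_csv_strict <- function(path, col_types, what) {
  if (!file.exists(path)) stop_schema(paste0(what, ": file not found: ", path))
  # numeric fields are parsed with base R (correctly rounded strtod) so a
  # save -> load -> save cycle is byte-identical; vroom's float parser can
  # be one ulp off
  df <- readr::read_csv(path, progress = FALSE, name_repair = "minimal",
                        col_types = readr::cols(.default = readr::col_character()))
  require_columns(df, names(col_types$cols), what)
  df <- df[names(col_types$cols)]
  for (nm in names(col_types$cols)) {
    cls <- class(col_types$cols[[nm]])[1]
    if (cls %in% c("collector_double", "collector_integer")) {
      v <- df[[nm]]
      num <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "NA" & is.na(num)
      if (any(bad)) {
        stop_schema(paste0(what, ": non-numeric value in column ", nm, ": ",
                           v[bad][1]))
      }
      df[[nm]] <- if (cls == "collector_integer") as.integer(num) else num
    }
  }
  as_tibble(df)
}

#' Food catalog: one row per food with composition and effect category
#'
#' The catalog carries, for each food, its iron and energy densities, the
#' dietary-database group used for age-sex disaggregation (token `"NONE"`
#' in the file marks foods with no such group, which fall back to energy
#' scaling), its elevated-CO2 effect category, and animal-source and
#' wild-harvest flags.
#'
#' @param path Path to a `foods.csv` file with columns
#'   `food_id,food_name,genus_group,gdd_group,eco2_category,iron_mg_per_100g,kcal_per_100g,is_animal,is_wild`.
#' @return A tibble with one validated row per food; `gdd_group` is `NA`
#'   where the file said `"NONE"`, and the flags are logical.
#' @export
load_food_catalog <- function(path) {
  ct <- readr::cols(
    food_id = readr::col_character(), food_name = readr::col_character(),
    genus_group = readr::col_character(), gdd_group = readr::col_character(),
    eco2_category = readr::col_character(),
    iron_mg_per_100g = readr::col_double(), kcal_per_100g = readr::col_double(),
    is_animal = readr::col_integer(), is_wild = readr::col_integer()
  )
  df <- read_csv_strict(path, ct, "food catalog")
  df$gdd_group[!is.na(df$gdd_group) & df$gdd_group == "NONE"] <- NA_character_
  df$is_animal <- df$is_animal != 0L
  df$is_wild <- df$is_wild != 0L
  validate_food_catalog(df)
}

#' @rdname load_food_catalog
#' @param catalog A food-catalog tibble.
#' @return `validate_food_catalog()` returns the catalog invisibly unchanged
#'   after checking all invariants, erroring otherwise.
#' @export
validate_food_catalog <- function(catalog) {
  require_columns(catalog, c("food_id", "food_name", "genus_group", "gdd_group",
                             "eco2_category", "iron_mg_per_100g",
                             "kcal_per_100g", "is_animal", "is_wild"),
                  "food catalog")
  dup <- catalog$food_id[duplicated(catalog$food_id)]
  if (length(dup) > 0) {
    stop_validation(paste0("duplicate food_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_cat <- setdiff(unique(catalog$eco2_category), eco2_categories())
  if (length(bad_cat) > 0) {
    stop_schema(paste0("unknown eco2_category: ", paste(bad_cat, collapse = ", ")))
  }
  for (col in c("iron_mg_per_100g", "kcal_per_100g")) {
    v <- catalog[[col]]
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop_validation(paste0("negative or non-finite ", col, " for food_id: ",
                             paste(catalog$food_id[bad], collapse = ", ")))
    }
  }
  mismatch <- (catalog$eco2_category == "ANIMAL") != catalog$is_animal
  if (any(mismatch)) {
    stop_validation(paste0("eco2_category ANIMAL must match is_animal flag: ",
                           paste(catalog$food_id[mismatch], collapse = ", ")))
  }
  invisible(catalog)
}

#' @rdname load_food_catalog
#' @export
save_food_catalog <- function(catalog, path) {
  validate_food_catalog(catalog)
  out <- catalog
  out$gdd_group[is.na(out$gdd_group)] <- "NONE"
  out$is_animal <- as.integer(out$is_animal)
  out$is_wild <- as.integer(out$is_wild)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Supply tables: per-capita edible food supply by country and group
#'
#' Each row gives the edible supply of one food in one country, in grams
#' per person per day, either as the national average (group token
#' `"NATIONAL"`) or for a specific age-sex group.
#'
#' @param path Path to a `supply.csv` file with columns
#'   `country,food_id,group,g_per_day`.
#' @return A validated tibble with those columns.
#' @export
load_supply_table <- function(path) {
  ct <- readr::cols(country = readr::col_character(),
                    food_id = readr::col_character(),
                    group = readr::col_character(),
                    g_per_day = readr::col_double())
  validate_supply_table(read_csv_strict(path, ct, "supply table"))
}

#' @rdname load_supply_table
#' @param table A supply tibble.
#' @export
validate_supply_table <- function(table) {
  require_columns(table, c("country", "food_id", "group", "g_per_day"),
                  "supply table")
  bad <- !is.finite(table$g_per_day) | table$g_per_day < 0
  if (any(bad)) {
    stop_validation(paste0("negative or non-finite supply for: ",
                           paste(utils::head(paste(table$country[bad], table$food_id[bad]), 5),
                                 collapse = "; ")))
  }
  key <- paste(table$country, table$food_id, table$group, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("duplicate (country, food_id, group) keys in supply table")
  }
  parse_group_token(unique(table$group))  # errors on malformed tokens
  invisible(table)
}

#' @rdname load_supply_table
#' @export
save_supply_table <- function(table, path) {
  validate_supply_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Relative-intake factors by country, food group and age-sex group
#'
#' Dimensionless multipliers of the national-average intake of a food
#' group (1.0 = eaten at the national average), with a standard deviation
#' expressing the intake model's uncertainty. Consumed as point values by
#' the disaggregation stage; the uncertainty is propagated only in the
#' Monte Carlo loss simulation.
#'
#' @param path Path to `gdd.csv` with columns
#'   `country,gdd_group,sex,age_lo,age_hi,factor,factor_sd`.
#' @return A validated tibble with those columns plus a derived `group`
#'   token column.
#' @export
load_gdd_factors <- function(path) {
  ct <- readr::cols(country = readr::col_character(),
                    gdd_group = readr::col_character(),
                    sex = readr::col_character(),
                    age_lo = readr::col_double(), age_hi = readr::col_double(),
                    factor = readr::col_double(), factor_sd = readr::col_double())
  validate_gdd_factors(read_csv_strict(path, ct, "gdd factors"))
}

#' @rdname load_gdd_factors
#' @param factors A factor tibble.
#' @export
validate_gdd_factors <- function(factors) {
  require_columns(factors, c("country", "gdd_group", "sex", "age_lo", "age_hi",
                             "factor", "factor_sd"), "gdd factors")
  if (any(!is.finite(factors$factor) | factors$factor <= 0)) {
    stop_validation("relative-intake factors must be finite and > 0")
  }
  if (any(!is.finite(factors$factor_sd) | factors$factor_sd < 0)) {
    stop_validation("factor_sd must be finite and >= 0")
  }
  factors$group <- age_sex_token(factors$sex, factors$age_lo, factors$age_hi)
  invisible(factors)
}

#' @rdname load_gdd_factors
#' @export
save_gdd_factors <- function(factors, path) {
  factors <- validate_gdd_factors(factors)
  readr::write_csv(factors[c("country", "gdd_group", "sex", "age_lo", "age_hi",
                             "factor", "factor_sd")], path, progress = FALSE)
  invisible(path)
}

#' Energy profiles: national calorie supply and group energy requirements
#'
#' One table holds, per country, the national average dietary energy
#' supply (group token `"NATIONAL"`) and the average dietary energy
#' requirement of each age-sex group, all in kcal per person per day.
#' The ratio requirement / national supply is the fallback scaling factor
#' for foods without a dietary-database group.
#'
#' @param path Path to `energy.csv` with columns `country,group,kcal_per_day`.
#' @return A validated tibble with those columns.
#' @export
load_energy_profiles <- function(path) {
  ct <- readr::cols(country = readr::col_character(),
                    group = readr::col_character(),
                    kcal_per_day = readr::col_double())
  validate_energy_profiles(read_csv_strict(path, ct, "energy profiles"))
}

#' @rdname load_energy_profiles
#' @param profiles An energy tibble.
#' @export
validate_energy_profiles <- function(profiles) {
  require_columns(profiles, c("country", "group", "kcal_per_day"),
                  "energy profiles")
  if (any(!is.finite(profiles$kcal_per_day) | profiles$kcal_per_day <= 0)) {
    stop_validation("energy values must be finite and > 0")
  }
  parse_group_token(unique(profiles$group))
  invisible(profiles)
}

#' @rdname load_energy_profiles
#' @export
save_energy_profiles <- function(profiles, path) {
  validate_energy_profiles(profiles)
  readr::write_csv(profiles, path, progress = FALSE)
  invisible(path)
}

#' Anemia prevalence by country and age-sex group
#'
#' @param path Path to `anemia.csv` with columns `country,group,anemia_pct`
#'   (percent of the group below the hemoglobin threshold, in `[0, 100]`).
#' @return A validated tibble with those columns.
#' @export
load_anemia <- function(path) {
  ct <- readr::cols(country = readr::col_character(),
                    group = readr::col_character(),
                    anemia_pct = readr::col_double())
  validate_anemia(read_csv_strict(path, ct, "anemia prevalence"))
}

#' @rdname load_anemia
#' @param anemia An anemia tibble.
#' @export
validate_anemia <- function(anemia) {
  require_columns(anemia, c("country", "group", "anemia_pct"), "anemia prevalence")
  bad <- !is.finite(anemia$anemia_pct) | anemia$anemia_pct < 0 | anemia$anemia_pct > 100
  if (any(bad)) stop_validation("anemia_pct must lie in [0, 100]")
  invisible(anemia)
}

#' @rdname load_anemia
#' @export
save_anemia <- function(anemia, path) {
  validate_anemia(anemia)
  readr::write_csv(anemia, path, progress = FALSE)
  invisible(path)
}

#' Population headcounts by country and age-sex group
#'
#' Optionally carries a `gdp_per_capita` column (constant within country)
#' used only by the descriptive income correlation.
#'
#' @param path Path to `population.csv` with columns
#'   `country,group,headcount` and optionally `gdp_per_capita`.
#' @return A validated tibble.
#' @export
load_population <- function(path) {
  first <- readr::read_csv(path, n_max = 0, col_types = readr::cols(), progress = FALSE)
  ct <- readr::cols(country = readr::col_character(),
                    group = readr::col_character(),
                    headcount = readr::col_double())
  if ("gdp_per_capita" %in% names(first)) {
    ct$cols$gdp_per_capita <- readr::col_double()
  }
  validate_population(read_csv_strict(path, ct, "population"))
}

#' @rdname load_population
#' @param population A population tibble.
#' @export
validate_population <- function(population) {
  require_columns(population, c("country", "group", "headcount"), "population")
  if (any(!is.finite(population$headcount) | population$headcount < 0)) {
    stop_validation("headcounts must be finite and >= 0")
  }
  invisible(population)
}

#' @rdname load_population
#' @export
save_population <- function(population, path) {
  validate_population(population)
  readr::write_csv(population, path, progress = FALSE)
  invisible(path)
}

#' Elevated-CO2 effect table: percentage iron changes with uncertainty
#'
#' One row per specific crop (`level = "CROP"`, keyed by `food_id`) or
#' pooled category (`level = "CATEGORY"`, keyed by category name), giving
#' the mean percentage change in iron content under elevated CO2
#' (negative = loss), the reported 95% uncertainty interval, the number
#' of analyzed samples behind the estimate, and the significance of the
#' change.
#'
#' @param path Path to `eco2_effects.csv` with columns
#'   `crop_or_category,level,mean_pct_change,ci_lo,ci_hi,n_samples,p_value`.
#' @return A validated tibble with those columns.
#' @export
load_eco2_effects <- function(path) {
  ct <- readr::cols(crop_or_category = readr::col_character(),
                    level = readr::col_character(),
                    mean_pct_change = readr::col_double(),
                    ci_lo = readr::col_double(), ci_hi = readr::col_double(),
                    n_samples = readr::col_double(),
                    p_value = readr::col_double())
  validate_eco2_effects(read_csv_strict(path, ct, "eco2 effects"))
}

#' @rdname load_eco2_effects
#' @param effects An effect tibble.
#' @export
validate_eco2_effects <- function(effects) {
  require_columns(effects, c("crop_or_category", "level", "mean_pct_change",
                             "ci_lo", "ci_hi", "n_samples", "p_value"),
                  "eco2 effects")
  bad_level <- setdiff(unique(effects$level), c("CROP", "CATEGORY"))
  if (length(bad_level) > 0) {
    stop_schema(paste0("unknown effect level: ", paste(bad_level, collapse = ", ")))
  }
  with_ci <- is.finite(effects$ci_lo) & is.finite(effects$ci_hi)
  bad <- with_ci & !(effects$ci_lo <= effects$mean_pct_change &
                       effects$mean_pct_change <= effects$ci_hi)
  if (any(bad)) {
    stop_validation(paste0("mean_pct_change outside [ci_lo, ci_hi] for: ",
                           paste(effects$crop_or_category[bad], collapse = ", ")))
  }
  if (any(!is.finite(effects$n_samples) | effects$n_samples <= 0)) {
    stop_validation("n_samples must be finite and > 0")
  }
  invisible(effects)
}

#' @rdname load_eco2_effects
#' @export
save_eco2_effects <- function(effects, path) {
  validate_eco2_effects(effects)
  readr::write_csv(effects, path, progress = FALSE)
  invisible(path)
}

#' Load or save a complete input bundle from a directory
#'
#' A bundle is a named list of the seven input tables (`foods`, `supply`,
#' `gdd`, `energy`, `anemia`, `population`, `eco2_effects`), the unit of
#' data the pipeline consumes.
#'
#' @param dir Directory holding (or to receive) `foods.csv`, `supply.csv`,
#'   `gdd.csv`, `energy.csv`, `anemia.csv`, `population.csv`,
#'   `eco2_effects.csv`.
#' @return `load_bundle()` returns the named list of tibbles;
#'   `save_bundle()` returns `dir` invisibly.
#' @export
load_bundle <- function(dir) {
  list(
    foods = load_food_catalog(file.path(dir, "foods.csv")),
    supply = load_supply_table(file.path(dir, "supply.csv")),
    gdd = load_gdd_factors(file.path(dir, "gdd.csv")),
    energy = load_energy_profiles(file.path(dir, "energy.csv")),
    anemia = load_anemia(file.path(dir, "anemia.csv")),
    population = load_population(file.path(dir, "population.csv")),
    eco2_effects = load_eco2_effects(file.path(dir, "eco2_effects.csv"))
  )
}

#' @rdname load_bundle
#' @param bundle A named list of the seven tables.
#' @export
save_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  save_food_catalog(bundle$foods, file.path(dir, "foods.csv"))
  save_supply_table(bundle$supply, file.path(dir, "supply.csv"))
  save_gdd_factors(bundle$gdd, file.path(dir, "gdd.csv"))
  save_energy_profiles(bundle$energy, file.path(dir, "energy.csv"))
  save_anemia(bundle$anemia, file.path(dir, "anemia.csv"))
  save_population(bundle$population, file.path(dir, "population.csv"))
  save_eco2_effects(bundle$eco2_effects, file.path(dir, "eco2_effects.csv"))
  invisible(dir)
}
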