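#' @importFrom rlang abort .data
#' @importFrom dplyr %>% mutate filter select arrange left_join inner_join
#'   group_by summarise ungroup bind_rows distinct across all_of n rename
#' @importFrom stats quantile rnorm runif rlnorm setNames qnorm pnorm dnorm
#'   uniroot lm coef cor median
#' @importFrom tibble tibble as_tibble
NULL

# error helpers: every user-facing failure carries a subclass so callers and
# tests can condition on the kind of violation, not on message text
stop_schema <- function(msg, ...) abort(msg, class = "ferro_schema_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "ferro_validation_error", ...)
stop_lookup <- function(msg, ...) abort(msg, class = "ferro_lookup_error", ...)
stop_domain <- function(msg, ...) abort(msg, class = "ferro_domain_error", ...)
stop_fit <- function(msg, ...) abort(msg, class = "ferro_fit_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "ferro_config_error", ...)
stop_scenario <- function(msg, ...) abort(msg, class = "ferro_scenario_error", ...)

#' Recognised elevated-CO2 effect categories
#'
#' Foods are binned by photosynthetic pathway and plant type: C3 grains,
#' legumes and maize carry measured iron declines under elevated CO2;
#' `ZERO_EFFECT` marks crops whose measured change is statistically
#' non-significant (e.g. sorghum, potato); `ANIMAL` and `OTHER_VEGETAL`
#' carry no effect.
#'
#' @return Character vector of the valid `eco2_category` values.
#' @export
eco2_categories <- function() {
  c("C3_GRAIN", "LEGUME", "MAIZE", "ZERO_EFFECT", "ANIMAL", "OTHER_VEGETAL")
}

# categories that must resolve to a measured effect distribution
affected_categories <- function() c("C3_GRAIN", "LEGUME", "MAIZE")

#' Age-sex group tokens
#'
#' Tables identify population groups with a single string token. The two
#' study groups are children aged 1-5 (both sexes) and women of childbearing
#' age (15-49); `"NATIONAL"` denotes the national per-capita average.
#'
#' @return `study_groups()` returns a tibble with columns `group`, `sex`
#'   (`"F"`, `"M"` or `"BOTH"`), `age_lo`, `age_hi`.
#' @export
study_groups <- function() {
  tibble(
    group = c("children_1_5", "women_15_49"),
    sex = c("BOTH", "F"),
    age_lo = c(1, 15),
    age_hi = c(5, 49)
  )
}

#' @rdname study_groups
#' @param sex One of `"F"`, `"M"`, `"BOTH"`.
#' @param age_lo,age_hi Age bounds in years, `age_lo <= age_hi`.
#' @return `age_sex_token()` returns the canonical token for the group.
#' @export
age_sex_token <- function(sex, age_lo, age_hi) {
  stopifnot(length(sex) == length(age_lo), length(age_lo) == length(age_hi))
  if (any(age_lo > age_hi)) stop_domain("age_lo must not exceed age_hi")
  known <- study_groups()
  out <- paste(sex, age_lo, age_hi, sep = "_")
  for (i in seq_len(nrow(known))) {
    hit <- sex == known$sex[i] & age_lo == known$age_lo[i] & age_hi == known$age_hi[i]
    out[hit] <- known$group[i]
  }
  out
}

#' @rdname study_groups
#' @param token Group token string (vectorised).
#' @return `parse_group_token()` returns a tibble with columns `group`,
#'   `sex`, `age_lo`, `age_hi`; `NATIONAL` yields `NA` fields.
#' @export
parse_group_token <- function(token) {
  known <- study_groups()
  out <- tibble(group = token, sex = NA_character_,
                age_lo = NA_real_, age_hi = NA_real_)
  for (i in seq_along(token)) {
    tok <- token[i]
    if (tok == "NATIONAL") next
    j <- match(tok, known$group)
    if (!is.na(j)) {
      out$sex[i] <- known$sex[j]
      out$age_lo[i] <- known$age_lo[j]
      out$age_hi[i] <- known$age_hi[j]
      next
    }
    parts <- strsplit(tok, "_", fixed = TRUE)[[1]]
    if (length(parts) != 3 || !parts[1] %in% c("F", "M", "BOTH")) {
      stop_validation(paste0("unrecognised group token: ", tok))
    }
    lo <- suppressWarnings(as.numeric(parts[2]))
    hi <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(lo) || is.na(hi) || lo > hi) {
      stop_validation(paste0("unrecognised group token: ", tok))
    }
    out$sex[i] <- parts[1]; out$age_lo[i] <- lo; out$age_hi[i] <- hi
  }
  out
}

# column presence check shared by all loaders
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(paste0(what, ": missing column(s) ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}
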