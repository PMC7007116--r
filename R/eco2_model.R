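# Quantifying the elevated-CO2 effect per food and propagating its
# uncertainty, together with intake-model uncertainty, to per-country
# total percentage dietary iron loss by Monte Carlo.

#' Zero out statistically non-significant effects
#'
#' Crops whose measured percentage change is not significant at `alpha`
#' (sorghum and potato in the source meta-analysis, p = 0.153 and 0.555)
#' are assigned exactly zero change with a zero-width uncertainty
#' interval; significant effects pass through unchanged.
#'
#' @param effects An effect tibble (rows as in [load_eco2_effects()]).
#' @param alpha Significance level (default 0.05).
#' @return The tibble with non-significant rows set to a degenerate zero.
#' @export
apply_zero_effect_rule <- function(effects, alpha = 0.05) {
  zero <- !is.na(effects$p_value) & effects$p_value > alpha
  effects$mean_pct_change[zero] <- 0
  effects$ci_lo[zero] <- 0
  effects$ci_hi[zero] <- 0
  effects
}

#' Pool crop-level effects into a category effect
#'
#' Sample-count-weighted average of the member crops' mean changes; the
#' interval bounds are pooled with the same weights and the sample counts
#' add.
#'
#' @param effects A non-empty effect tibble of `level == "CROP"` rows,
#'   all with `n_samples > 0`.
#' @param category Name for the pooled row.
#' @return A one-row effect tibble with `level == "CATEGORY"`.
#' @export
pool_category <- function(effects, category = "POOLED") {
  if (nrow(effects) == 0) stop_domain("cannot pool an empty effect list")
  if (any(effects$n_samples <= 0)) stop_domain("n_samples must be > 0")
  w <- effects$n_samples / sum(effects$n_samples)
  tibble(
    crop_or_category = category, level = "CATEGORY",
    mean_pct_change = sum(w * effects$mean_pct_change),
    ci_lo = sum(w * effects$ci_lo), ci_hi = sum(w * effects$ci_hi),
    n_samples = sum(effects$n_samples),
    p_value = if (nrow(effects) == 1) effects$p_value else NA_real_
  )
}

# one resolved sampling law per distinct effect entry: either a point
# mass (zero or a mean without an interval) or a fitted skew-normal
make_dist <- function(mean_pct, ci_lo, ci_hi) {
  if (!is.finite(ci_lo) || !is.finite(ci_hi) || ci_hi - ci_lo <= 0 ||
      mean_pct == 0 && ci_lo == 0 && ci_hi == 0) {
    return(list(type = "point", value = mean_pct))
  }
  c(list(type = "skewnorm"), fit_skew_normal(mean_pct, ci_lo, ci_hi))
}

dist_mean <- function(d) {
  if (d$type == "point") d$value else skewnorm_mean(d$xi, d$omega, d$alpha)
}

dist_draws <- function(d, n) {
  if (d$type == "point") rep(d$value, n) else rskewnorm(n, d$xi, d$omega, d$alpha)
}

#' Resolve the effect distribution for every food in a catalog
#'
#' A food's percentage-change law is taken from its crop-level row when
#' one exists, else from its effect category's row (C3 grains, legumes,
#' maize); animal-source foods, zero-effect crops, and other vegetal
#' foods without an entry are a point mass at zero. Foods in an affected
#' category with neither a crop nor a category row are a configuration
#' error. The zero-effect rule is applied to every entry first.
#'
#' @param catalog Food catalog tibble.
#' @param effects Effect tibble.
#' @param alpha Significance level for the zero-effect rule.
#' @return A list with `foods` (tibble `food_id, dist_id`) and `dists`
#'   (list of sampling laws; `dist_id` 0 denotes the shared zero law).
#' @export
resolve_effects <- function(catalog, effects, alpha = 0.05) {
  effects <- apply_zero_effect_rule(validate_eco2_effects(effects), alpha)
  crop_rows <- effects[effects$level == "CROP", ]
  cat_rows <- effects[effects$level == "CATEGORY", ]
  dists <- list()
  key_of <- character(0)
  dist_for_row <- function(row, key) {
    j <- match(key, key_of)
    if (!is.na(j)) return(j)
    dists[[length(dists) + 1]] <<- make_dist(row$mean_pct_change,
                                             row$ci_lo, row$ci_hi)
    key_of[length(key_of) + 1] <<- key
    length(dists)
  }
  ids <- vapply(seq_len(nrow(catalog)), function(i) {
    f <- catalog[i, ]
    if (f$eco2_category %in% c("ANIMAL", "ZERO_EFFECT")) return(0L)
    ci <- match(f$food_id, crop_rows$crop_or_category)
    if (!is.na(ci)) {
      return(as.integer(dist_for_row(crop_rows[ci, ], paste0("CROP:", f$food_id))))
    }
    ki <- match(f$eco2_category, cat_rows$crop_or_category)
    if (!is.na(ki)) {
      return(as.integer(dist_for_row(cat_rows[ki, ],
                                     paste0("CATEGORY:", f$eco2_category))))
    }
    if (f$eco2_category %in% affected_categories()) {
      stop_config(paste0("no crop or category effect for affected food: ",
                         f$food_id, " (", f$eco2_category, ")"))
    }
    0L  # OTHER_VEGETAL without any entry
  }, integer(1))
  list(foods = tibble(food_id = catalog$food_id, dist_id = ids),
       dists = dists)
}

#' Expected percentage change per food
#'
#' The analytic mean of each food's resolved effect law (zero for
#' unaffected foods); used for the deterministic expected-loss accounting
#' of the top-lost-sources table.
#'
#' @inheritParams resolve_effects
#' @return A tibble `food_id, expected_pct_change`.
#' @export
expected_effect_by_food <- function(catalog, effects, alpha = 0.05) {
  res <- resolve_effects(catalog, effects, alpha)
  means <- c(0, vapply(res$dists, dist_mean, numeric(1)))
  tibble(food_id = res$foods$food_id,
         expected_pct_change = means[res$foods$dist_id + 1L])
}

# log-normal intake perturbation with unit mean: a factor reported as
# mean `f` with sd `s` perturbs intake by exp(N(-v/2, v)) where
# v = log(1 + (s/f)^2), so E[multiplier] = 1
gdd_sdlog <- function(factor, factor_sd) {
  sqrt(log(1 + (factor_sd / factor)^2))
}

#' Monte Carlo simulation of total percentage dietary iron loss
#'
#' On each iteration, one percentage change is drawn per distinct effect
#' entry (shared across all countries and all foods mapped to that entry:
#' the effect is a property of crop biology, not geography) and one
#' multiplicative log-normal intake perturbation per relative-intake
#' factor. The country/group loss on that draw is the iron-weighted
#' average decline, reported as a positive percentage:
#' `loss = -sum(iron_f * delta_f) / sum(iron_f)`.
#'
#' @param iron Result of [iron_supply()] (or a compatible list with
#'   `by_food`).
#' @param catalog Food catalog tibble.
#' @param effects Effect tibble.
#' @param gdd Relative-intake factor tibble for intake-uncertainty
#'   propagation, or `NULL` to propagate effect uncertainty only.
#' @param n_draws Number of Monte Carlo iterations (default 1000).
#' @param seed RNG seed; identical seed gives an identical result.
#' @param alpha Significance level for the zero-effect rule.
#' @param keep_draws Keep the per-draw loss matrix and effect draws in
#'   the result (needed for diagnostic bounds; default `TRUE`).
#' @return A list of class `loss_distribution`: `summary` (tibble
#'   `country, group, mean_loss_pct, median_loss_pct, lo95, hi95`),
#'   `n_draws`, and when `keep_draws` also `draws` (matrix, one column
#'   per country/group), `units`, `effect_draws`, `food_dists`.
#' @export
simulate_losses <- function(iron, catalog, effects, gdd = NULL,
                            n_draws = 1000, seed = 1L, alpha = 0.05,
                            keep_draws = TRUE) {
  if (n_draws < 1) stop_domain("n_draws must be >= 1")
  by_food <- iron$by_food
  res <- resolve_effects(catalog, effects, alpha)
  n_dists <- length(res$dists)

  # intake-perturbation keys: one per (country, group, gdd_group) factor
  # row with positive sd that covers a food in the diet
  pert_key <- NULL
  if (!is.null(gdd)) {
    if (!"group" %in% names(gdd)) gdd <- validate_gdd_factors(gdd)
    fmap <- catalog[c("food_id", "gdd_group")]
    pert_key <- by_food %>%
      left_join(fmap, by = "food_id") %>%
      inner_join(gdd[gdd$factor_sd > 0,
                     c("country", "group", "gdd_group", "factor", "factor_sd")],
                 by = c("country", "group", "gdd_group")) %>%
      distinct(.data$country, .data$group, .data$gdd_group,
               .data$factor, .data$factor_sd)
  }

  units <- by_food %>% distinct(.data$country, .data$group)
  draws <- matrix(0, nrow = n_draws, ncol = nrow(units))
  eff_draws <- NULL

  withr::with_seed(seed, {
    eff_draws <- matrix(0, nrow = n_draws, ncol = n_dists)
    for (j in seq_len(n_dists)) eff_draws[, j] <- dist_draws(res$dists[[j]], n_draws)
    pert <- NULL
    if (!is.null(pert_key) && nrow(pert_key) > 0) {
      v <- gdd_sdlog(pert_key$factor, pert_key$factor_sd)
      pert <- matrix(rnorm(n_draws * nrow(pert_key)), nrow = n_draws)
      pert <- exp(sweep(sweep(pert, 2, v, `*`), 2, v^2 / 2, `-`))
    }
    food_dist <- setNames(res$foods$dist_id, res$foods$food_id)
    for (u in seq_len(nrow(units))) {
      rows <- by_food$country == units$country[u] & by_food$group == units$group[u]
      w0 <- by_food$iron_mg_per_day[rows]
      if (sum(w0) <= 0) {
        stop_domain(paste0("zero total iron, loss undefined for: ",
                           units$country[u], " ", units$group[u]))
      }
      fids <- by_food$food_id[rows]
      dj <- unname(food_dist[fids])
      delta <- matrix(0, nrow = n_draws, ncol = length(fids))
      pos <- dj > 0
      if (any(pos)) delta[, pos] <- eff_draws[, dj[pos], drop = FALSE]
      W <- matrix(w0, nrow = n_draws, ncol = length(fids), byrow = TRUE)
      if (!is.null(pert)) {
        fg <- catalog$gdd_group[match(fids, catalog$food_id)]
        pk <- match(paste(units$country[u], units$group[u], fg),
                    paste(pert_key$country, pert_key$group, pert_key$gdd_group))
        hit <- which(!is.na(pk))
        if (length(hit) > 0) {
          W[, hit] <- W[, hit, drop = FALSE] * pert[, pk[hit], drop = FALSE]
        }
      }
      draws[, u] <- -rowSums(W * delta) / rowSums(W)
    }
  })

  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  summary <- units %>%
    mutate(mean_loss_pct = colMeans(draws),
           median_loss_pct = qs[2, ], lo95 = qs[1, ], hi95 = qs[3, ])
  out <- list(summary = summary, n_draws = n_draws)
  if (keep_draws) {
    out$draws <- draws
    out$units <- units
    out$effect_draws <- eff_draws
    out$food_dists <- res$foods
  }
  structure(out, class = "loss_distribution")
}

#' @export
print.loss_distribution <- function(x, ...) {
  cat("Monte Carlo loss distribution:", x$n_draws, "draws,",
      nrow(x$summary), "country/group units\n")
  print(x$summary, ...)
  invisible(x)
}
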