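#' Unit-cost scaling scenario (one-way deterministic sensitivity analysis)
#'
#' Scales the unit costs of selected categories by `1 + relative_change`
#' (the analysis grid uses +/-20%, +/-30% and +/-50%) and recomputes every
#' downstream quantity.
#'
#' @param target_categories Categories whose unit costs are scaled.
#' @param relative_change Relative change, > -1 (e.g. `0.2` for +20%).
#' @return A `unit_cost_scale_scenario` object.
#' @export
unit_cost_scale_scenario <- function(target_categories, relative_change) {
  target_categories <- unique(as.character(target_categories))
  unknown <- setdiff(target_categories, cost_categories())
  if (length(unknown) > 0L) {
    stop("unknown categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(relative_change) || length(relative_change) != 1L ||
    relative_change <= -1) {
    stop("relative_change must be a scalar > -1", call. = FALSE)
  }
  structure(
    list(
      target_categories = target_categories,
      relative_change = relative_change
    ),
    class = "unit_cost_scale_scenario"
  )
}

#' Parental-hours taper scenario
#'
#' From `applies_from_year` onward, yearly parental productivity-loss hours
#' and informal-care hours (hence their costs) are reduced by `reduction`.
#' The default — a 20% reduction from year 3, when children move into school
#' age — leaves the first two modelled years at the trial-observed level.
#'
#' @param reduction Fraction in `[0, 1]`; default 0.20.
#' @param applies_from_year 1-based first affected year; default 3.
#' @param target_categories Affected categories; default both parental
#'   categories.
#' @return An `hours_taper_scenario` object.
#' @export
hours_taper_scenario <- function(reduction = 0.20, applies_from_year = 3L,
                                 target_categories = c(
                                   "parental_productivity",
                                   "parental_informal_care"
                                 )) {
  if (!is.numeric(reduction) || reduction < 0 || reduction > 1) {
    stop("reduction must lie in [0, 1]", call. = FALSE)
  }
  applies_from_year <- as.integer(applies_from_year)
  stopifnot(applies_from_year >= 1L)
  target_categories <- unique(as.character(target_categories))
  unknown <- setdiff(target_categories, cost_categories())
  if (length(unknown) > 0L) {
    stop("unknown categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      reduction = reduction, applies_from_year = applies_from_year,
      target_categories = target_categories
    ),
    class = "hours_taper_scenario"
  )
}

# Scale a unit-cost table for the targeted categories (pure).
scale_unit_costs <- function(table, categories, relative_change) {
  factor <- 1 + relative_change
  sel <- table$entries$category %in% categories
  table$entries$euro_per_unit[sel] <- table$entries$euro_per_unit[sel] * factor
  if ("parental_productivity" %in% categories) {
    table$wage_per_hour <- table$wage_per_hour * factor
  }
  if ("parental_informal_care" %in% categories) {
    table$informal_care_price_per_hour <-
      table$informal_care_price_per_hour * factor
  }
  table
}

#' Apply a unit-cost scaling scenario
#'
#' Returns the recomputed incremental costs (both horizons, all the model's
#' perspectives) under the scaled unit costs. The base model is untouched.
#' For expected-summary (aggregate-mean) models the category means scale
#' directly, which is exactly equivalent to scaling the underlying unit
#' costs since costs are linear in prices.
#'
#' @param model A [cca_model()].
#' @param scenario A [unit_cost_scale_scenario()].
#' @return Tibble `perspective`, `horizon`, `difference`.
#' @export
apply_unit_cost_scale <- function(model, scenario) {
  stopifnot(
    inherits(model, "cca_model"),
    inherits(scenario, "unit_cost_scale_scenario")
  )
  scaled <- model
  scaled$unit_costs <- scale_unit_costs(
    model$unit_costs, scenario$target_categories, scenario$relative_change
  )
  factor <- 1 + scenario$relative_change
  if (model$mode == "expected") {
    scaled$cohort <- lapply(model$cohort, function(s) {
      sel <- names(s$mean_cost_by_category) %in% scenario$target_categories
      s$mean_cost_by_category[sel] <- s$mean_cost_by_category[sel] * factor
      s
    })
  }
  if ("education_childcare" %in% scenario$target_categories &&
    !is.null(model$school_cost_map)) {
    scaled$school_cost_map <- model$school_cost_map * factor
  }
  model_incrementals(scaled)
}

#' Apply the parental-hours taper scenario
#'
#' Rebuilds the 6-year schedule, reduces the targeted categories' yearly
#' costs by `reduction` from `applies_from_year` onward (hours scale
#' one-to-one with costs at a fixed hourly price), and recomputes the
#' 6-year incrementals. The base model is untouched.
#'
#' @param model A [cca_model()].
#' @param scenario An [hours_taper_scenario()].
#' @return Tibble `perspective`, `horizon` (`"6 years"`), `difference`.
#' @export
apply_hours_taper <- function(model, scenario) {
  stopifnot(
    inherits(model, "cca_model"),
    inherits(scenario, "hours_taper_scenario")
  )
  base <- evaluate_model(model)
  schedule <- build_schedule(base$summaries_13m, model$rules, model$school_cost_map)
  sel <- schedule$category %in% scenario$target_categories &
    schedule$year >= scenario$applies_from_year
  schedule$cost[sel] <- schedule$cost[sel] * (1 - scenario$reduction)
  s6 <- project_schedule(schedule, model$discount)
  rows <- lapply(model$perspectives, function(p) {
    tibble::tibble(
      perspective = p$name, horizon = "6 years",
      difference = incremental(s6$intervention, s6$control, p,
        horizon = "6 years"
      )$difference
    )
  })
  dplyr::bind_rows(rows)
}

#' One-way sensitivity grid over unit-cost changes
#'
#' Runs [apply_unit_cost_scale()] for every (category group, relative
#' change) combination and stacks the results. Each row of the grid is
#' reproducible by the corresponding single-scenario call.
#'
#' @param model A [cca_model()].
#' @param changes Relative changes; default the +/-20/30/50% grid.
#' @param groups Named list of category vectors; default one group per
#'   societal category except delivery.
#' @return Tibble `group`, `relative_change`, `perspective`, `horizon`,
#'   `difference`.
#' @export
sa1_grid <- function(model,
                     changes = c(-0.5, -0.3, -0.2, 0.2, 0.3, 0.5),
                     groups = NULL) {
  if (is.null(groups)) {
    cats <- setdiff(societal_categories(), "pact_delivery")
    groups <- stats::setNames(as.list(cats), cats)
  }
  rows <- list()
  for (g in names(groups)) {
    for (ch in changes) {
      res <- apply_unit_cost_scale(
        model, unit_cost_scale_scenario(groups[[g]], ch)
      )
      res$group <- g
      res$relative_change <- ch
      rows[[paste(g, ch)]] <- res
    }
  }
  dplyr::bind_rows(rows)[, c(
    "group", "relative_change", "perspective", "horizon", "difference"
  )]
}

#' Out-of-pocket expense comparison
#'
#' Compares mean parental out-of-pocket expenses per child between the
#' intervention arm (trial-sourced) and an externally sourced usual-care
#' estimate — in the base analysis, Irish observational data covering
#' living costs, care and assistance, education, healthcare, travel,
#' training/support and an autism assistance dog, at 2020 prices.
#'
#' @param pact_arm_mean Mean out-of-pocket euros per child, intervention arm.
#' @param alternative_tau_mean Mean out-of-pocket euros per child from the
#'   external usual-care source. May be omitted when `breakdown` is given
#'   (its sum is used).
#' @param breakdown Optional named numeric vector of category-level euros;
#'   when both are supplied it must sum to `alternative_tau_mean`.
#' @return An `out_of_pocket_comparison` object.
#' @export
out_of_pocket_comparison <- function(pact_arm_mean, alternative_tau_mean = NULL,
                                     breakdown = NULL) {
  stopifnot(is.numeric(pact_arm_mean), pact_arm_mean >= 0)
  if (is.null(alternative_tau_mean)) {
    if (is.null(breakdown)) {
      stop("supply alternative_tau_mean or a breakdown", call. = FALSE)
    }
    alternative_tau_mean <- sum(breakdown)
  }
  stopifnot(alternative_tau_mean >= 0)
  if (!is.null(breakdown)) {
    if (any(breakdown < 0)) {
      stop("breakdown entries must be nonnegative", call. = FALSE)
    }
    if (abs(sum(breakdown) - alternative_tau_mean) > 0.5) {
      stop("breakdown must sum to alternative_tau_mean", call. = FALSE)
    }
  }
  structure(
    list(
      pact_arm_mean = as.numeric(pact_arm_mean),
      alternative_tau_mean = as.numeric(alternative_tau_mean),
      breakdown = breakdown
    ),
    class = "out_of_pocket_comparison"
  )
}

#' @rdname out_of_pocket_comparison
#' @param cmp An `out_of_pocket_comparison`.
#' @return `compare_out_of_pocket()`: list with `difference` (intervention
#'   minus usual-care, euros) and `contrast_pct` (percentage by which the
#'   usual-care mean exceeds the intervention mean, relative to usual care).
#' @export
#' @examples
#' cmp <- out_of_pocket_comparison(1696, 9599)
#' compare_out_of_pocket(cmp) # difference -7903, contrast ~82.3%
compare_out_of_pocket <- function(cmp) {
  stopifnot(inherits(cmp, "out_of_pocket_comparison"))
  if (cmp$alternative_tau_mean == 0) {
    stop("contrast undefined: alternative_tau_mean is 0", call. = FALSE)
  }
  list(
    difference = cmp$pact_arm_mean - cmp$alternative_tau_mean,
    contrast_pct = 100 * (cmp$alternative_tau_mean - cmp$pact_arm_mean) /
      cmp$alternative_tau_mean
  )
}

#' Read an out-of-pocket breakdown table
#'
#' CSV with columns `item`, `mean_cost` (euros per child, 2020 prices).
#'
#' @param path CSV file path.
#' @return Named numeric vector of category-level euros.
#' @export
read_out_of_pocket <- function(path) {
  if (!file.exists(path)) {
    stop("out-of-pocket table not found: ", path, call. = FALSE)
  }
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      item = readr::col_character(),
      mean_cost = readr::col_double()
    )
  )
  stats::setNames(tab$mean_cost, tab$item)
}
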