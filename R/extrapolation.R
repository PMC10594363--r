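#' Discounting specification
#'
#' Costs occurring in later years are down-weighted by `1/(1+r)^t` at an
#' annual rate of 3.5% by default. Under the default `start_undiscounted`
#' convention the first modelled year is undiscounted (factor 1); under
#' `end_of_year` even year 1 is discounted once.
#'
#' @param annual_rate Annual discount rate, >= 0; default 0.035.
#' @param convention `"start_undiscounted"` (default) or `"end_of_year"`.
#' @return A `discount_spec` object.
#' @export
discount_spec <- function(annual_rate = 0.035,
                          convention = c("start_undiscounted", "end_of_year")) {
  convention <- match.arg(convention)
  if (!is.numeric(annual_rate) || length(annual_rate) != 1L || annual_rate < 0) {
    stop("annual_rate must be a nonnegative scalar", call. = FALSE)
  }
  structure(
    list(annual_rate = annual_rate, convention = convention),
    class = "discount_spec"
  )
}

#' Schedule rules for the 6-year projection
#'
#' Encodes how 13-month trial costs become yearly cost streams:
#' * intervention delivery is limited to the first modelled year (which
#'   covers the 13-month delivery window) when `pact_first_period_only`;
#' * education/childcare runs at the nursery-derived yearly cost during
#'   `nursery_years` and is recosted as school time during `school_years`;
#' * every other category repeats its annualized yearly cost each year.
#'
#' `annualization_factor` converts a 13-month cost to a yearly rate; the
#' default 12/13 treats the window as 13 months of steady use.
#'
#' @param horizon_years Projection horizon in years, default 6.
#' @param pact_first_period_only Restrict delivery costs to year 1.
#' @param nursery_years,school_years 1-based year indices; together they must
#'   cover `1:horizon_years` without overlap.
#' @param annualization_factor Multiplier from 13-month cost to euros/year.
#' @return A `schedule_rules` object.
#' @export
schedule_rules <- function(horizon_years = 6L,
                           pact_first_period_only = TRUE,
                           nursery_years = 1:2,
                           school_years = 3:6,
                           annualization_factor = 12 / 13) {
  horizon_years <- as.integer(horizon_years)
  stopifnot(horizon_years >= 1L, annualization_factor > 0)
  nursery_years <- as.integer(nursery_years)
  school_years <- as.integer(school_years)
  covered <- sort(c(nursery_years, school_years))
  if (!identical(covered, seq_len(horizon_years))) {
    stop("nursery_years and school_years must partition 1:horizon_years",
      call. = FALSE
    )
  }
  structure(
    list(
      horizon_years = horizon_years,
      pact_first_period_only = isTRUE(pact_first_period_only),
      nursery_years = nursery_years,
      school_years = school_years,
      annualization_factor = annualization_factor
    ),
    class = "schedule_rules"
  )
}

#' Convert a 13-month cost to a yearly rate
#'
#' @param cost_13m Nonnegative euros over the 13-month window.
#' @param rules A [schedule_rules()].
#' @return Euros per year.
#' @export
annualize <- function(cost_13m, rules = schedule_rules()) {
  stopifnot(inherits(rules, "schedule_rules"))
  if (any(cost_13m < 0)) {
    stop("cost_13m must be nonnegative", call. = FALSE)
  }
  cost_13m * rules$annualization_factor
}

#' Build the yearly cost schedule over the projection horizon
#'
#' Applies the [schedule_rules()] to 13-month arm summaries, producing the
#' undiscounted per-year cost stream for every arm and societal category.
#'
#' @param arm_summaries Named list with elements `intervention` and
#'   `control`, each an [arm_cost_summary()] at 13 months.
#' @param rules A [schedule_rules()].
#' @param school_cost_map Named numeric `c(intervention = , control = )`:
#'   yearly euros per child for school-time education during the school
#'   years. Required when `rules$school_years` is nonempty.
#' @return A tibble `arm`, `category`, `year`, `cost` of class
#'   `yearly_cost_schedule` (attribute `discounted = FALSE`).
#' @export
build_schedule <- function(arm_summaries, rules = schedule_rules(),
                           school_cost_map = NULL) {
  stopifnot(inherits(rules, "schedule_rules"))
  if (!is.list(arm_summaries) ||
    !all(c("intervention", "control") %in% names(arm_summaries))) {
    stop("arm_summaries must be a list with 'intervention' and 'control'",
      call. = FALSE
    )
  }
  if (length(rules$school_years) > 0L) {
    if (is.null(school_cost_map) ||
      !all(c("intervention", "control") %in% names(school_cost_map))) {
      stop(
        "school_cost_map (named intervention/control, euros per year) is ",
        "required when school years are modelled",
        call. = FALSE
      )
    }
  }
  years <- seq_len(rules$horizon_years)
  rows <- list()
  for (arm in c("intervention", "control")) {
    s <- arm_summaries[[arm]]
    stopifnot(inherits(s, "arm_cost_summary"))
    for (category in societal_categories()) {
      m13 <- category_mean(s, category)
      yearly <- rep(annualize(m13, rules), rules$horizon_years)
      if (category == "pact_delivery" && rules$pact_first_period_only) {
        # the full 13-month delivery cost sits in year 1, nothing after
        yearly <- c(m13, rep(0, rules$horizon_years - 1L))
      }
      if (category == "education_childcare" && length(rules$school_years) > 0L) {
        yearly[rules$school_years] <- school_cost_map[[arm]]
      }
      rows[[paste(arm, category)]] <- tibble::tibble(
        arm = arm, category = category, year = years, cost = yearly
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "discounted") <- FALSE
  attr(out, "rules") <- rules
  attr(out, "n_children") <- c(
    intervention = arm_summaries$intervention$n_children,
    control = arm_summaries$control$n_children
  )
  class(out) <- c("yearly_cost_schedule", class(out))
  out
}

#' Discount factor for a modelled year
#'
#' @param year_index 1-based year index (vectorized), >= 1.
#' @param spec A [discount_spec()].
#' @return Dimensionless factor(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(2, discount_spec(0.035)) # 1/1.035
discount_factor <- function(year_index, spec = discount_spec()) {
  stopifnot(inherits(spec, "discount_spec"))
  if (any(year_index < 1)) {
    stop("year_index must be >= 1", call. = FALSE)
  }
  exponent <- switch(spec$convention,
    start_undiscounted = year_index - 1,
    end_of_year = year_index
  )
  (1 + spec$annual_rate)^(-exponent)
}

#' Add discounted costs to a schedule
#'
#' @param schedule A [build_schedule()] result.
#' @param spec A [discount_spec()].
#' @return The schedule with an extra `discounted_cost` column.
#' @export
discount_schedule <- function(schedule, spec = discount_spec()) {
  stopifnot(inherits(schedule, "yearly_cost_schedule"))
  schedule$discounted_cost <- schedule$cost * discount_factor(schedule$year, spec)
  schedule
}

#' Project a yearly schedule to discounted cumulative totals
#'
#' Sums each (arm, category) stream over the horizon with discounting,
#' yielding the 6-year cumulative cost summaries from which 6-year
#' incrementals and waterfalls are computed.
#'
#' @param schedule An undiscounted [build_schedule()] result.
#' @param spec A [discount_spec()].
#' @return Named list of [arm_cost_summary()] objects (`intervention`,
#'   `control`) holding discounted cumulative euros per child.
#' @export
project_schedule <- function(schedule, spec = discount_spec()) {
  stopifnot(inherits(schedule, "yearly_cost_schedule"))
  if (isTRUE(attr(schedule, "discounted"))) {
    stop("schedule is already discounted", call. = FALSE)
  }
  n_children <- attr(schedule, "n_children")
  disc <- discount_schedule(schedule, spec)
  totals <- disc |>
    dplyr::group_by(.data$arm, .data$category) |>
    dplyr::summarise(total = sum(.data$discounted_cost), .groups = "drop")
  out <- lapply(c("intervention", "control"), function(a) {
    sub <- totals[totals$arm == a, ]
    arm_cost_summary(
      a,
      if (!is.null(n_children)) n_children[[a]] else 1L,
      stats::setNames(sub$total, sub$category)
    )
  })
  stats::setNames(out, c("intervention", "control"))
}
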