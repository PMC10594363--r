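#' Assemble a cost-consequence model
#'
#' Bundles everything needed to evaluate the analysis end to end: the cohort
#' (either per-child microdata or noise-free expected arm summaries), the
#' country unit-cost table, the projection schedule rules, the discounting
#' specification and the analytic perspectives. Evaluate with
#' [evaluate_model()]; sensitivity scenarios transform a copy of the model
#' and never mutate the original.
#'
#' @param cohort Either a per-child records tibble (`child_id`, `arm`,
#'   `item_id`, `quantity`) or a named list of two [arm_cost_summary()]
#'   objects (`intervention`, `control`) for a deterministic aggregate-mean
#'   run.
#' @param unit_costs A [unit_cost_table()].
#' @param rules A [schedule_rules()].
#' @param discount A [discount_spec()].
#' @param perspectives Named list of [perspective_spec()] objects.
#' @param school_cost_map Named numeric `c(intervention=, control=)`, yearly
#'   school-time euros per child for the school years.
#' @param filter_threshold Mean-occurrence threshold for [filter_items()]
#'   (microdata cohorts only); default 0.5 events.
#' @return A `cca_model` object.
#' @export
cca_model <- function(cohort, unit_costs,
                      rules = schedule_rules(),
                      discount = discount_spec(),
                      perspectives = default_perspectives(),
                      school_cost_map = NULL,
                      filter_threshold = 0.5) {
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  mode <- if (is.data.frame(cohort)) {
    "microdata"
  } else if (is.list(cohort) &&
    all(c("intervention", "control") %in% names(cohort)) &&
    inherits(cohort$intervention, "arm_cost_summary")) {
    "expected"
  } else {
    stop("cohort must be a records tibble or a list of two arm_cost_summary objects",
      call. = FALSE
    )
  }
  structure(
    list(
      cohort = cohort, mode = mode, unit_costs = unit_costs,
      rules = rules, discount = discount, perspectives = perspectives,
      school_cost_map = school_cost_map, filter_threshold = filter_threshold
    ),
    class = "cca_model"
  )
}

#' @export
print.cca_model <- function(x, ...) {
  cat("<cca_model> ", x$unit_costs$country, ", ", x$mode, " cohort, ",
    length(x$perspectives), " perspectives, horizon ",
    x$rules$horizon_years, " years\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate a cost-consequence model
#'
#' Runs the full chain: item filtering and costing (microdata mode), arm
#' summaries at 13 months, incremental costs per perspective, the yearly
#' schedule, discounted 6-year summaries and incrementals, and waterfall
#' decompositions at both horizons.
#'
#' @param model A [cca_model()].
#' @return A list: `summaries_13m`, `summaries_6y` (lists of
#'   [arm_cost_summary()]), `incrementals` (tibble `perspective`, `horizon`,
#'   `difference`), `schedule` (discounted [build_schedule()] output),
#'   `waterfall_13m`, `waterfall_6y`, and `costs` (per-child costs, microdata
#'   mode only).
#' @export
evaluate_model <- function(model) {
  stopifnot(inherits(model, "cca_model"))
  if (model$mode == "microdata") {
    keep <- filter_items(model$cohort, model$filter_threshold)
    records <- model$cohort[model$cohort$item_id %in% keep, ]
    costs <- cost_cohort(records, model$unit_costs)
    s13 <- list(
      intervention = summarize_arm(costs, "intervention"),
      control = summarize_arm(costs, "control")
    )
  } else {
    costs <- NULL
    s13 <- model$cohort
  }
  schedule <- build_schedule(s13, model$rules, model$school_cost_map)
  s6 <- project_schedule(schedule, model$discount)

  inc_rows <- list()
  for (p in model$perspectives) {
    i13 <- incremental(s13$intervention, s13$control, p, horizon = "13 months")
    i6 <- incremental(s6$intervention, s6$control, p, horizon = "6 years")
    inc_rows[[p$name]] <- tibble::tibble(
      perspective = p$name,
      horizon = c("13 months", "6 years"),
      difference = c(i13$difference, i6$difference)
    )
  }
  list(
    summaries_13m = s13,
    summaries_6y = s6,
    incrementals = dplyr::bind_rows(inc_rows),
    schedule = discount_schedule(schedule, model$discount),
    waterfall_13m = waterfall(s13$intervention, s13$control),
    waterfall_6y = waterfall(s6$intervention, s6$control),
    costs = costs
  )
}

# Incrementals tibble for a (possibly transformed) model evaluation.
model_incrementals <- function(model) {
  evaluate_model(model)$incrementals
}
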