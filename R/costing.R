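#' Filter resource-use items by mean occurrence
#'
#' Mirrors the simplification used when adapting trial resource-use data
#' across countries: only items with a mean occurrence per child (both arms
#' pooled, zeros included) strictly greater than the threshold are retained
#' for costing.
#'
#' @param records Cohort tibble (`child_id`, `arm`, `item_id`, `quantity`).
#' @param threshold Mean events per child; default 0.5.
#' @return Character vector of retained item ids.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   child_id = c("a", "b", "c", "d"), arm = "control",
#'   item_id = "x", quantity = c(0, 1, 1, 1)
#' )
#' filter_items(rec) # mean 0.75 > 0.5: retained
filter_items <- function(records, threshold = 0.5) {
  stopifnot(nrow(records) > 0, threshold >= 0)
  n_children <- dplyr::n_distinct(records$child_id)
  means <- records |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(mean_per_child = sum(.data$quantity) / n_children, .groups = "drop")
  means$item_id[means$mean_per_child > threshold]
}

#' Cost event-denominated resource use
#'
#' Multiplies quantities by the country unit cost, summing within child and
#' category. Hour-denominated parental items are priced by
#' [productivity_cost()] / [informal_care_cost()]; use [cost_cohort()] to
#' cost a full cohort including them.
#'
#' @param records Cohort tibble of event-denominated items.
#' @param table A [unit_cost_table()].
#' @return Tibble `child_id`, `arm`, `category`, `cost` (euros, 2020).
#' @export
cost_records <- function(records, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  unknown <- setdiff(unique(records$item_id), table$entries$item_id)
  if (length(unknown) > 0L) {
    stop("no unit cost for item id: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  priced <- dplyr::inner_join(records, table$entries, by = "item_id")
  if (anyNA(priced$euro_per_unit)) {
    bad <- unique(priced$item_id[is.na(priced$euro_per_unit)])
    stop("no unit cost for item id: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  priced |>
    dplyr::group_by(.data$child_id, .data$arm, .data$category) |>
    dplyr::summarise(
      cost = sum(.data$quantity * .data$euro_per_unit),
      .groups = "drop"
    )
}

#' Value parental time off work (human-capital approach)
#'
#' Hours of work lost because of the child's condition, valued at the
#' country's national average wage.
#'
#' @param hours_off_work Nonnegative hours.
#' @param table A [unit_cost_table()].
#' @return Euros.
#' @export
productivity_cost <- function(hours_off_work, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (any(hours_off_work < 0)) {
    stop("hours_off_work must be nonnegative", call. = FALSE)
  }
  hours_off_work * table$wage_per_hour
}

#' Value informal care hours (market-price approach)
#'
#' Unpaid care hours valued at the amount that would be paid if the care
#' were provided by a formal (paid) caregiver.
#'
#' @param care_hours Nonnegative hours.
#' @param table A [unit_cost_table()].
#' @return Euros.
#' @export
informal_care_cost <- function(care_hours, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (any(care_hours < 0)) {
    stop("care_hours must be nonnegative", call. = FALSE)
  }
  care_hours * table$informal_care_price_per_hour
}

#' Inflate a cost to 2020 prices
#'
#' @param cost Nonnegative euros at the source price level.
#' @param table A [unit_cost_table()] supplying the inflation multiplier.
#' @return Euros at 2020 prices.
#' @export
inflate_to_2020 <- function(cost, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (any(cost < 0)) {
    stop("cost must be nonnegative", call. = FALSE)
  }
  cost * table$inflation_index
}

#' Cost a full cohort, including the hour-denominated family impacts
#'
#' Event-denominated items are priced from the unit-cost entries; items in
#' the parental categories are hour-denominated and priced at the wage
#' (productivity) or the formal-caregiver price (informal care). Every child
#' receives a row for every category covered by the table (zero where no
#' use), so arm summaries include true zeros.
#'
#' @inheritParams cost_records
#' @return Tibble `child_id`, `arm`, `category`, `cost`.
#' @export
cost_cohort <- function(records, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  cat_of <- stats::setNames(table$entries$category, table$entries$item_id)
  unknown <- setdiff(unique(records$item_id), names(cat_of))
  if (length(unknown) > 0L) {
    stop("no unit cost for item id: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  records$category <- unname(cat_of[records$item_id])
  prod <- records[records$category == "parental_productivity", ]
  care <- records[records$category == "parental_informal_care", ]
  event <- records[
    !records$category %in% c("parental_productivity", "parental_informal_care"),
  ]

  pieces <- list()
  if (nrow(event) > 0) {
    pieces$event <- cost_records(event[, c("child_id", "arm", "item_id", "quantity")], table)
  }
  if (nrow(prod) > 0) {
    pieces$prod <- prod |>
      dplyr::mutate(cost = productivity_cost(.data$quantity, table)) |>
      dplyr::group_by(.data$child_id, .data$arm, .data$category) |>
      dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
  }
  if (nrow(care) > 0) {
    pieces$care <- care |>
      dplyr::mutate(cost = informal_care_cost(.data$quantity, table)) |>
      dplyr::group_by(.data$child_id, .data$arm, .data$category) |>
      dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
  }
  costs <- dplyr::bind_rows(pieces)
  cats <- union(
    societal_categories(),
    unique(records$category)
  )
  costs |>
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("child_id"), !!rlang::sym("arm")),
      category = cats,
      fill = list(cost = 0)
    ) |>
    dplyr::arrange(.data$child_id, .data$category)
}

#' Arm-level cost summary
#'
#' `arm_cost_summary()` builds a summary directly from known mean costs (for
#' instance published arm totals); `summarize_arm()` computes one from
#' per-child costs, taking the arithmetic mean per category over all the
#' arm's children, zeros included.
#'
#' @param arm `"intervention"` or `"control"`.
#' @param n_children Number of children the means average over, >= 1.
#' @param mean_cost_by_category Named numeric vector of nonnegative euros per
#'   child; names are [cost_categories()].
#' @return An `arm_cost_summary` object.
#' @export
arm_cost_summary <- function(arm, n_children, mean_cost_by_category) {
  stopifnot(arm %in% c("intervention", "control"))
  n_children <- as.integer(n_children)
  if (is.na(n_children) || n_children < 1L) {
    stop("n_children must be >= 1", call. = FALSE)
  }
  m <- mean_cost_by_category
  if (is.null(names(m)) || !all(names(m) %in% cost_categories())) {
    stop("mean_cost_by_category must be named by cost categories", call. = FALSE)
  }
  if (any(m < 0)) {
    stop("mean costs must be nonnegative", call. = FALSE)
  }
  structure(
    list(arm = arm, n_children = n_children, mean_cost_by_category = m),
    class = "arm_cost_summary"
  )
}

#' @export
print.arm_cost_summary <- function(x, ...) {
  cat("<arm_cost_summary> ", x$arm, " (n = ", x$n_children, ")\n", sep = "")
  m <- x$mean_cost_by_category
  for (nm in names(m)) {
    cat(sprintf("  %-26s %12.0f EUR\n", nm, m[[nm]]))
  }
  cat(sprintf("  %-26s %12.0f EUR\n", "total", sum(m)))
  invisible(x)
}

#' @rdname arm_cost_summary
#' @param costs Per-child cost tibble from [cost_cohort()].
#' @export
summarize_arm <- function(costs, arm) {
  stopifnot(arm %in% c("intervention", "control"))
  sub <- costs[costs$arm == arm, ]
  if (nrow(sub) == 0L) {
    stop("no children in arm '", arm, "'", call. = FALSE)
  }
  n <- dplyr::n_distinct(sub$child_id)
  means <- sub |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(mean_cost = sum(.data$cost) / n, .groups = "drop")
  arm_cost_summary(arm, n, stats::setNames(means$mean_cost, means$category))
}

# Mean for a category, 0 with a warning when the summary does not carry it.
category_mean <- function(summary, category) {
  m <- summary$mean_cost_by_category
  if (!category %in% names(m)) {
    warning("category '", category, "' missing from ", summary$arm,
      " summary; treated as 0",
      call. = FALSE
    )
    return(0)
  }
  m[[category]]
}

#' Incremental cost under a perspective
#'
#' The mean per-child cost difference, intervention minus control, summed
#' over the perspective's categories. A category absent from a summary is
#' treated as zero with a warning.
#'
#' @param int_summary,ctrl_summary [arm_cost_summary()] objects for the
#'   intervention and control arms.
#' @param perspective A [perspective_spec()] or the name of a default
#'   perspective (`"healthcare_service"`, `"broader_service"`, `"societal"`).
#' @param horizon Label for the time horizon the summaries refer to.
#' @return An `incremental_cost` object with fields `perspective`, `horizon`,
#'   `difference` (euros) and `by_category` (the per-category differences).
#' @export
#' @examples
#' int <- arm_cost_summary("intervention", 74, c(pact_delivery = 6198))
#' ctl <- arm_cost_summary("control", 69, c(pact_delivery = 0))
#' incremental(int, ctl, "healthcare_service")
incremental <- function(int_summary, ctrl_summary, perspective,
                        horizon = c("13 months", "6 years")) {
  horizon <- match.arg(horizon)
  stopifnot(
    inherits(int_summary, "arm_cost_summary"),
    inherits(ctrl_summary, "arm_cost_summary"),
    int_summary$arm == "intervention", ctrl_summary$arm == "control"
  )
  perspective <- resolve_perspective(perspective)
  diffs <- vapply(perspective$categories, function(cc) {
    category_mean(int_summary, cc) - category_mean(ctrl_summary, cc)
  }, numeric(1))
  structure(
    list(
      perspective = perspective$name, horizon = horizon,
      difference = sum(diffs),
      by_category = diffs
    ),
    class = "incremental_cost"
  )
}

#' @export
print.incremental_cost <- function(x, ...) {
  cat(sprintf(
    "<incremental_cost> %s, %s: %+.0f EUR per child (intervention - control)\n",
    x$perspective, x$horizon, x$difference
  ))
  invisible(x)
}

#' Waterfall decomposition of the societal incremental cost
#'
#' Accumulates per-category cost differences (intervention minus control) in
#' the given order, starting from the intervention delivery cost, so the
#' final cumulative value equals the societal incremental cost exactly.
#'
#' @inheritParams incremental
#' @param category_order Categories in accumulation order; must start with
#'   `pact_delivery`. Categories omitted from the order must have zero
#'   difference.
#' @return Tibble `category`, `difference`, `cumulative`.
#' @export
waterfall <- function(int_summary, ctrl_summary,
                      category_order = default_waterfall_order()) {
  stopifnot(
    inherits(int_summary, "arm_cost_summary"),
    inherits(ctrl_summary, "arm_cost_summary")
  )
  category_order <- as.character(category_order)
  if (length(category_order) == 0L || category_order[1L] != "pact_delivery") {
    stop("category_order must begin with pact_delivery", call. = FALSE)
  }
  if (anyDuplicated(category_order)) {
    stop("category_order must not repeat categories", call. = FALSE)
  }
  unknown <- setdiff(category_order, societal_categories())
  if (length(unknown) > 0L) {
    stop("category_order contains non-societal categories: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  all_diffs <- vapply(societal_categories(), function(cc) {
    category_mean(int_summary, cc) - category_mean(ctrl_summary, cc)
  }, numeric(1))
  omitted <- setdiff(societal_categories(), category_order)
  nonzero_omitted <- omitted[abs(all_diffs[omitted]) > 0]
  if (length(nonzero_omitted) > 0L) {
    stop("category_order omits categories with nonzero difference: ",
      paste(nonzero_omitted, collapse = ", "),
      call. = FALSE
    )
  }
  diffs <- all_diffs[category_order]
  tibble::tibble(
    category = factor(category_order, levels = category_order),
    difference = unname(diffs),
    cumulative = cumsum(unname(diffs))
  )
}

#' Waterfall chart of incremental costs
#'
#' Floating-bar rendering of a [waterfall()] decomposition: increases in one
#' colour, savings in another, with the final societal difference marked by a
#' horizontal line.
#'
#' @param wf Tibble returned by [waterfall()].
#' @return A ggplot object.
#' @export
plot_waterfall <- function(wf) {
  wf$start <- dplyr::lag(wf$cumulative, default = 0)
  wf$direction <- ifelse(wf$difference >= 0, "cost increase", "saving")
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.integer(.data$category) - 0.4,
      xmax = as.integer(.data$category) + 0.4,
      ymin = .data$start, ymax = .data$cumulative,
      fill = .data$direction
    )) +
    ggplot2::geom_hline(
      yintercept = wf$cumulative[nrow(wf)],
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_fill_manual(
      values = c("cost increase" = "#2166ac", "saving" = "#e08214")
    ) +
    ggplot2::labs(
      x = NULL, y = "Cumulative cost difference (EUR per child)",
      fill = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
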