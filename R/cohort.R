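#' Specify a resource-use item for cohort simulation
#'
#' Usage quantities per child over the 13-month trial window are simulated
#' from a zero-inflated gamma: with probability `zero_prob` the quantity is
#' exactly zero, otherwise it is a gamma draw with the given conditional mean
#' and shape (`dispersion`). Shape 1 (the default) gives an exponential —
#' strongly right-skewed, as cost data typically are. A `fixed` item is
#' deterministic: every child in an arm uses exactly `mean_quantity` — used
#' for intervention delivery, which every intervention-arm child receives
#' once.
#'
#' `zero_prob` and `mean_quantity` may be scalars (recycled to both arms) or
#' length-2 vectors named `intervention` and `control`.
#'
#' @param item_id Unique item identifier.
#' @param category One of [cost_categories()].
#' @param unit `"event"` or `"hour"`. Hour-denominated items are priced by
#'   the wage (productivity) or the formal-caregiver price (informal care)
#'   rather than a per-event unit cost.
#' @param zero_prob Probability of zero use, in `[0, 1]`, per arm.
#' @param mean_quantity Mean quantity conditional on nonzero use
#'   (unconditional for `fixed` items), per arm; nonnegative.
#' @param dispersion Gamma shape parameter, > 0.
#' @param fixed If `TRUE` the quantity is deterministic.
#' @return An `item_spec` object.
#' @export
#' @examples
#' item_spec("slt_session", "speech_language_therapy",
#'   zero_prob = 0.3, mean_quantity = c(intervention = 12, control = 8)
#' )
item_spec <- function(item_id, category, unit = c("event", "hour"),
                      zero_prob = 0, mean_quantity = 0,
                      dispersion = 1, fixed = FALSE) {
  unit <- match.arg(unit)
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  if (!category %in% cost_categories()) {
    stop("unknown cost category: ", category, call. = FALSE)
  }
  zero_prob <- per_arm(zero_prob, "zero_prob")
  mean_quantity <- per_arm(mean_quantity, "mean_quantity")
  if (any(zero_prob < 0 | zero_prob > 1)) {
    stop("zero_prob must lie in [0, 1]", call. = FALSE)
  }
  if (any(mean_quantity < 0)) {
    stop("mean_quantity must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0) {
    stop("dispersion must be a positive scalar", call. = FALSE)
  }
  structure(
    list(
      item_id = item_id, category = category, unit = unit,
      zero_prob = zero_prob, mean_quantity = mean_quantity,
      dispersion = dispersion, fixed = isTRUE(fixed)
    ),
    class = "item_spec"
  )
}

# Recycle a scalar to both arms or validate a named length-2 vector.
per_arm <- function(x, what) {
  arms <- c("intervention", "control")
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), 2L), arms))
  }
  if (length(x) == 2L && setequal(names(x), arms)) {
    return(stats::setNames(as.numeric(x[arms]), arms))
  }
  stop(what, " must be a scalar or a vector named 'intervention' and 'control'",
    call. = FALSE
  )
}

#' Configure a synthetic trial cohort
#'
#' Defaults reproduce the trial arm sizes: 74 children receiving the
#' intervention on top of usual treatment, 69 receiving usual treatment
#' alone.
#'
#' @param items List of [item_spec()] objects with unique ids.
#' @param n_intervention,n_control Arm sizes, at least 1.
#' @param seed Integer seed. Each arm draws from its own stream derived
#'   deterministically from this seed, so changing one arm's size leaves the
#'   other arm's quantities unchanged.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(items, n_intervention = 74L, n_control = 69L, seed = 1L) {
  n_intervention <- as.integer(n_intervention)
  n_control <- as.integer(n_control)
  if (is.na(n_intervention) || n_intervention < 1L) {
    stop("n_intervention must be a positive integer", call. = FALSE)
  }
  if (is.na(n_control) || n_control < 1L) {
    stop("n_control must be a positive integer", call. = FALSE)
  }
  if (!is.list(items) || length(items) == 0L ||
    !all(vapply(items, inherits, logical(1), "item_spec"))) {
    stop("items must be a non-empty list of item_spec objects", call. = FALSE)
  }
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) {
    stop("item ids must be unique", call. = FALSE)
  }
  names(items) <- ids
  structure(
    list(
      n_intervention = n_intervention, n_control = n_control,
      items = items, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_intervention, " intervention + ",
    x$n_control, " control children, ", length(x$items), " items, seed ",
    x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a synthetic per-child resource-use cohort
#'
#' Draws one quantity per child per item from the zero-inflated gamma
#' described in [item_spec()]. Fully reproducible: the same configuration
#' (including seed) always yields the same cohort.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `child_id`, `arm`, `item_id`, `quantity`;
#'   one row per child x item.
#' @export
#' @examples
#' cfg <- cohort_config(
#'   items = list(item_spec("a", "hospital_health", mean_quantity = 2)),
#'   n_intervention = 5, n_control = 4, seed = 42
#' )
#' generate_cohort(cfg)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  # independent per-arm streams derived from the single seed
  old <- .Random.seed_exists()
  set.seed(config$seed)
  arm_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  on.exit(restore_rng(old), add = TRUE)

  dplyr::bind_rows(
    generate_arm(config, "intervention", config$n_intervention, arm_seeds[1L], "I"),
    generate_arm(config, "control", config$n_control, arm_seeds[2L], "C")
  )
}

generate_arm <- function(config, arm, n, seed, prefix) {
  set.seed(seed)
  child_id <- sprintf("%s%04d", prefix, seq_len(n))
  rows <- lapply(config$items, function(it) {
    m <- it$mean_quantity[[arm]]
    if (it$fixed) {
      q <- rep(m, n)
    } else {
      nonzero <- stats::runif(n) >= it$zero_prob[[arm]]
      draw <- if (m > 0) {
        stats::rgamma(n, shape = it$dispersion, rate = it$dispersion / m)
      } else {
        rep(0, n)
      }
      q <- ifelse(nonzero, draw, 0)
    }
    tibble::tibble(
      child_id = child_id, arm = arm, item_id = it$item_id, quantity = q
    )
  })
  dplyr::bind_rows(rows)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Expected per-child cost by arm and category
#'
#' Closed-form expectation implied by a cohort configuration and a unit-cost
#' table: for a stochastic item, (1 - zero_prob) x mean_quantity x price; for
#' a fixed item, mean_quantity x price. Hour-denominated parental items are
#' priced at the wage or the formal-care price.
#'
#' @param config A [cohort_config()].
#' @param unit_costs A [unit_cost_table()].
#' @return Tibble with columns `arm`, `category`, `mean_cost` covering every
#'   societal category (and `out_of_pocket` if the config carries such items).
#' @export
expected_costs <- function(config, unit_costs) {
  stopifnot(inherits(config, "cohort_config"))
  arms <- c("intervention", "control")
  rows <- lapply(config$items, function(it) {
    price <- item_price(unit_costs, it$item_id, it$category)
    ec <- vapply(arms, function(a) {
      if (it$fixed) {
        it$mean_quantity[[a]] * price
      } else {
        (1 - it$zero_prob[[a]]) * it$mean_quantity[[a]] * price
      }
    }, numeric(1))
    tibble::tibble(arm = arms, category = it$category, cost = ec)
  })
  cats <- union(
    societal_categories(),
    unique(vapply(config$items, `[[`, character(1), "category"))
  )
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$arm, .data$category) |>
    dplyr::summarise(mean_cost = sum(.data$cost), .groups = "drop") |>
    tidyr::complete(
      arm = arms, category = cats,
      fill = list(mean_cost = 0)
    )
}

#' Expected arm-level cost summaries for a configuration
#'
#' Convenience wrapper around [expected_costs()] returning one
#' [arm_cost_summary()] per arm — the noise-free arm means implied by the
#' configuration, used for deterministic (aggregate-mean) model runs.
#'
#' @inheritParams expected_costs
#' @return Named list with elements `intervention` and `control`.
#' @export
expected_arm_summaries <- function(config, unit_costs) {
  ec <- expected_costs(config, unit_costs)
  n <- c(intervention = config$n_intervention, control = config$n_control)
  out <- lapply(c("intervention", "control"), function(a) {
    sub <- ec[ec$arm == a, ]
    arm_cost_summary(a, n[[a]], stats::setNames(sub$mean_cost, sub$category))
  })
  stats::setNames(out, c("intervention", "control"))
}

#' Calibrate a cohort configuration to target arm-level category costs
#'
#' Rescales item mean quantities so that the expected per-child cost of each
#' (arm, category) pair — zero-inflation, conditional mean and unit price
#' combined — equals the supplied target exactly in expectation. When a
#' category holds several items the target is allocated proportionally to
#' their prior expected costs; if all prior expected costs are zero it is
#' split equally across the items that can carry cost.
#'
#' @param config A [cohort_config()] supplying the prior item structure.
#' @param targets Tibble (or data frame) with columns `arm`, `category`,
#'   `mean_cost`: the target expected euros per child.
#' @param unit_costs A [unit_cost_table()].
#' @return A new `cohort_config` whose [expected_costs()] match `targets`.
#' @export
#' @examples
#' uc <- unit_cost_table("demo",
#'   entries = tibble::tibble(
#'     item_id = "visit", category = "hospital_health", euro_per_unit = 100
#'   )
#' )
#' cfg <- cohort_config(list(item_spec("visit", "hospital_health",
#'   mean_quantity = 1
#' )))
#' tgt <- tibble::tibble(
#'   arm = "intervention", category = "hospital_health", mean_cost = 1723
#' )
#' calibrated <- calibrate_to_means(cfg, tgt, uc)
#' calibrated$items$visit$mean_quantity[["intervention"]] # 17.23
calibrate_to_means <- function(config, targets, unit_costs) {
  stopifnot(inherits(config, "cohort_config"))
  targets <- tibble::as_tibble(targets)
  need <- c("arm", "category", "mean_cost")
  if (!all(need %in% names(targets))) {
    stop("targets must have columns arm, category, mean_cost", call. = FALSE)
  }
  items <- config$items
  cats <- vapply(items, `[[`, character(1), "category")

  for (i in seq_len(nrow(targets))) {
    arm <- targets$arm[[i]]
    category <- targets$category[[i]]
    target <- targets$mean_cost[[i]]
    if (!arm %in% c("intervention", "control")) {
      stop("unknown arm in targets: ", arm, call. = FALSE)
    }
    idx <- which(cats == category)
    if (length(idx) == 0L) {
      stop("no items in category '", category, "' to calibrate", call. = FALSE)
    }
    if (target < 0) {
      stop("target mean cost must be nonnegative (", category, ")", call. = FALSE)
    }
    price <- vapply(idx, function(j) {
      item_price(unit_costs, items[[j]]$item_id, category)
    }, numeric(1))
    # euros per unit of mean_quantity, accounting for zero-inflation
    weight <- vapply(seq_along(idx), function(k) {
      it <- items[[idx[k]]]
      if (it$fixed) price[k] else (1 - it$zero_prob[[arm]]) * price[k]
    }, numeric(1))
    prior <- vapply(seq_along(idx), function(k) {
      items[[idx[k]]]$mean_quantity[[arm]] * weight[k]
    }, numeric(1))

    if (target == 0) {
      new_means <- rep(0, length(idx))
    } else if (sum(prior) > 0) {
      scale <- target / sum(prior)
      new_means <- vapply(seq_along(idx), function(k) {
        items[[idx[k]]]$mean_quantity[[arm]] * scale
      }, numeric(1))
    } else {
      carriers <- which(weight > 0)
      if (length(carriers) == 0L) {
        stop(
          "cannot calibrate category '", category, "' (arm ", arm,
          "): no item can carry cost (all unit costs zero or zero_prob 1)",
          call. = FALSE
        )
      }
      new_means <- rep(0, length(idx))
      new_means[carriers] <- (target / length(carriers)) / weight[carriers]
    }
    for (k in seq_along(idx)) {
      items[[idx[k]]]$mean_quantity[[arm]] <- new_means[k]
    }
  }
  config$items <- items
  config
}

#' Write / read a cohort as CSV
#'
#' The CSV has columns `child_id`, `arm`, `item_id`, `quantity` and
#' round-trips losslessly.
#'
#' @param records Cohort tibble as produced by [generate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the validated cohort tibble.
#' @export
write_cohort <- function(records, path) {
  stopifnot(all(c("child_id", "arm", "item_id", "quantity") %in% names(records)))
  readr::write_csv(
    records[, c("child_id", "arm", "item_id", "quantity")],
    path
  )
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      arm = readr::col_character(),
      item_id = readr::col_character(),
      quantity = readr::col_double()
    )
  )
  need <- c("child_id", "arm", "item_id", "quantity")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(is.na(records$quantity) | records$quantity < 0)
  if (length(bad) > 0L) {
    stop("invalid quantity in cohort CSV at row ", bad[1L],
      " (must be a nonnegative number)",
      call. = FALSE
    )
  }
  bad_arm <- which(!records$arm %in% c("intervention", "control"))
  if (length(bad_arm) > 0L) {
    stop("invalid arm in cohort CSV at row ", bad_arm[1L], call. = FALSE)
  }
  if (anyDuplicated(records[, c("child_id", "item_id")])) {
    dup <- which(duplicated(records[, c("child_id", "item_id")]))[1L]
    stop("duplicated (child_id, item_id) in cohort CSV at row ", dup, call. = FALSE)
  }
  records
}
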