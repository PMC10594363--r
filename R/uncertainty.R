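#' Non-parametric bootstrap of an incremental cost
#'
#' Resamples children with replacement within each arm independently and
#' recomputes the incremental cost under the given perspective. The point
#' estimate is the incremental on the original data (invariant to seed and
#' replicate count); the confidence interval is the percentile interval of
#' the bootstrap distribution.
#'
#' @param costs Per-child cost tibble from [cost_cohort()].
#' @param perspective A [perspective_spec()] or default-perspective name.
#' @param n_replicates Bootstrap replicates, >= 1. A percentile CI is
#'   reported only when `n_replicates >= 100`.
#' @param seed Optional integer seed for the resampling.
#' @param ci_level Confidence level, default 0.95.
#' @return A `bootstrap_result`: `point_estimate`, `ci_low`, `ci_high`
#'   (`NA` when no CI), `n_replicates`, `seed`, `ci_level`, and the raw
#'   `replicates` vector.
#' @export
bootstrap_incremental <- function(costs, perspective, n_replicates = 1000L,
                                  seed = NULL, ci_level = 0.95) {
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L, ci_level > 0, ci_level < 1)
  perspective <- resolve_perspective(perspective)

  totals <- costs[costs$category %in% perspective$categories, ] |>
    dplyr::group_by(.data$child_id, .data$arm) |>
    dplyr::summarise(total = sum(.data$cost), .groups = "drop")
  x_int <- totals$total[totals$arm == "intervention"]
  x_ctl <- totals$total[totals$arm == "control"]
  if (length(x_int) == 0L || length(x_ctl) == 0L) {
    stop("both arms must be present in the cost data", call. = FALSE)
  }
  point <- mean(x_int) - mean(x_ctl)

  want_ci <- n_replicates >= 100L
  if (want_ci && (length(x_int) < 2L || length(x_ctl) < 2L)) {
    stop("confidence intervals require at least 2 children per arm", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  replicates <- vapply(seq_len(n_replicates), function(i) {
    mean(sample(x_int, replace = TRUE)) - mean(sample(x_ctl, replace = TRUE))
  }, numeric(1))
  if (want_ci) {
    alpha <- 1 - ci_level
    qs <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    ci_low <- qs[1L]
    ci_high <- qs[2L]
  } else {
    ci_low <- NA_real_
    ci_high <- NA_real_
  }
  structure(
    list(
      point_estimate = point, ci_low = ci_low, ci_high = ci_high,
      n_replicates = n_replicates, seed = seed, ci_level = ci_level,
      perspective = perspective$name, replicates = replicates
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> %s incremental: %+.0f EUR",
    x$perspective, x$point_estimate
  ))
  if (!is.na(x$ci_low)) {
    cat(sprintf(
      " (%.0f%% CI %+.0f to %+.0f, %d replicates)",
      100 * x$ci_level, x$ci_low, x$ci_high, x$n_replicates
    ))
  }
  cat("\n")
  invisible(x)
}
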