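#' Cost categories of the model
#'
#' The closed set of cost categories used throughout the package. Every
#' resource-use item maps to exactly one category. `pact_delivery` is the
#' intervention-delivery cost itself; the parental categories carry the family
#' economic impacts (time off work valued by the human-capital approach,
#' unpaid care valued at the market price of a formal caregiver);
#' `out_of_pocket` holds direct family expenses and enters an analysis only
#' when a perspective explicitly includes it.
#'
#' @return Character vector of category identifiers.
#' @export
#' @examples
#' cost_categories()
cost_categories <- function() {
  c(
    "pact_delivery",
    "speech_language_therapy",
    "community_health_social",
    "hospital_health",
    "education_childcare",
    "social_care",
    "parental_productivity",
    "parental_informal_care",
    "out_of_pocket"
  )
}

#' Categories entering the societal perspective
#'
#' All categories except `out_of_pocket` (which is compared separately in the
#' out-of-pocket sensitivity analysis).
#'
#' @return Character vector.
#' @export
societal_categories <- function() {
  setdiff(cost_categories(), "out_of_pocket")
}

#' Define an analytic perspective
#'
#' A perspective is a named set of cost categories summed when computing an
#' incremental cost.
#'
#' @param name Identifier for the perspective.
#' @param categories Character vector of categories, a subset of
#'   [cost_categories()].
#' @return A `perspective_spec` object.
#' @export
#' @examples
#' perspective_spec("family", c("parental_productivity", "parental_informal_care"))
perspective_spec <- function(name, categories) {
  stopifnot(is.character(name), length(name) == 1L)
  categories <- unique(as.character(categories))
  unknown <- setdiff(categories, cost_categories())
  if (length(unknown) > 0L) {
    stop("unknown cost categories: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, categories = categories), class = "perspective_spec")
}

#' @export
print.perspective_spec <- function(x, ...) {
  cat("<perspective_spec> ", x$name, ": ",
    paste(x$categories, collapse = " + "), "\n",
    sep = ""
  )
  invisible(x)
}

#' The standard nested perspectives
#'
#' The three perspectives used in the base analysis:
#' * `healthcare_service`: intervention delivery, speech and language therapy,
#'   community health and social services, hospital-based health services;
#' * `broader_service`: healthcare plus education/childcare and social care;
#' * `societal`: broader service plus parental productivity losses and
#'   parental informal (unpaid) care.
#'
#' @param include_out_of_pocket If `TRUE`, an additional `out_of_pocket`
#'   perspective is appended (used only in the out-of-pocket sensitivity
#'   analysis).
#' @return Named list of [perspective_spec()] objects.
#' @export
#' @examples
#' names(default_perspectives())
default_perspectives <- function(include_out_of_pocket = FALSE) {
  hc <- c(
    "pact_delivery", "speech_language_therapy",
    "community_health_social", "hospital_health"
  )
  broader <- c(hc, "education_childcare", "social_care")
  societal <- c(broader, "parental_productivity", "parental_informal_care")
  ps <- list(
    healthcare_service = perspective_spec("healthcare_service", hc),
    broader_service = perspective_spec("broader_service", broader),
    societal = perspective_spec("societal", societal)
  )
  if (isTRUE(include_out_of_pocket)) {
    ps$out_of_pocket <- perspective_spec("out_of_pocket", "out_of_pocket")
  }
  ps
}

# Resolve a perspective given either a spec or the name of a default one.
resolve_perspective <- function(perspective) {
  if (inherits(perspective, "perspective_spec")) {
    return(perspective)
  }
  if (is.character(perspective) && length(perspective) == 1L) {
    ps <- default_perspectives(include_out_of_pocket = TRUE)
    if (!perspective %in% names(ps)) {
      stop("unknown perspective name: ", perspective, call. = FALSE)
    }
    return(ps[[perspective]])
  }
  stop("perspective must be a perspective_spec or the name of a default perspective",
    call. = FALSE
  )
}

#' Default waterfall category order
#'
#' The order in which category-level cost differences are accumulated in the
#' waterfall decomposition: delivery first, then health service items,
#' education and social care, and finally the family impacts.
#'
#' @return Character vector, a permutation of [societal_categories()].
#' @export
default_waterfall_order <- function() {
  c(
    "pact_delivery",
    "speech_language_therapy",
    "community_health_social",
    "hospital_health",
    "education_childcare",
    "social_care",
    "parental_productivity",
    "parental_informal_care"
  )
}
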