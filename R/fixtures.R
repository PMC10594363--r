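#' Packaged example fixtures
#'
#' The package ships illustrative fixtures for four countries (England,
#' Ireland, Italy, Spain): a unit-cost CSV, a country-parameter YAML and a
#' calibration-target CSV each. The England targets encode the published
#' 13-month arm totals exactly at the perspective level (healthcare 7,651 vs
#' 1,723 euros; societal 95,689 vs 99,308 euros; delivery difference 6,198
#' euros); the category-level split inside each perspective, all unit-cost
#' values, and the other countries' targets are synthetic illustrations —
#' the underlying trial microdata and country tariffs are not public. File
#' names carry `synthetic` where the content is invented.
#'
#' @param country One of `example_countries()`.
#' @return `example_countries()`: the country names. `example_fixture()`: a
#'   list with `country`, `unit_costs` ([unit_cost_table()]), `targets`
#'   (tibble `arm`, `category`, `mean_cost`), `school_cost_map`,
#'   `discount_rate`, and — where packaged — `oop` (out-of-pocket inputs).
#' @export
example_countries <- function() {
  c("england", "ireland", "italy", "spain")
}

#' @rdname example_countries
#' @export
example_fixture <- function(country = example_countries()) {
  country <- match.arg(country)
  extdata <- system.file("extdata", package = "costconseq")
  cfg <- read_country_config(file.path(extdata, paste0("country_", country, ".yaml")))
  targets <- readr::read_csv(
    file.path(extdata, paste0("targets_synthetic_", country, ".csv")),
    col_types = readr::cols(
      arm = readr::col_character(),
      category = readr::col_character(),
      mean_cost = readr::col_double()
    )
  )
  out <- list(
    country = country,
    unit_costs = cfg$unit_costs,
    targets = targets,
    school_cost_map = c(
      intervention = cfg$school_cost_per_year$intervention,
      control = cfg$school_cost_per_year$control
    ),
    discount_rate = cfg$discount_rate %||% 0.035
  )
  if (!is.null(cfg$out_of_pocket)) {
    oop_path <- file.path(extdata, cfg$out_of_pocket$table)
    out$oop <- list(
      pact_mean = cfg$out_of_pocket$pact_mean,
      breakdown = read_out_of_pocket(oop_path)
    )
  }
  out
}

#' Default prior item specifications
#'
#' The resource-use items behind the packaged fixtures, one stand-in item
#' per service plus two hospital items: delivery (a fixed once-per-child
#' course in the intervention arm), therapy sessions, community visits,
#' social-care contacts, hospital outpatient visits and (rare) inpatient
#' days, nursery days, parental hours off work and informal-care hours.
#' Zero-use probabilities and prior means are plausible magnitudes for a
#' preschool autism cohort; [calibrate_to_means()] rescales the means to hit
#' target arm-level category costs, so the priors mainly fix the relative
#' weight of items within a category.
#'
#' @return List of [item_spec()] objects.
#' @export
default_item_specs <- function() {
  list(
    item_spec("pact_delivery", "pact_delivery",
      mean_quantity = c(intervention = 1, control = 0), fixed = TRUE
    ),
    item_spec("slt_session", "speech_language_therapy",
      zero_prob = 0.3, mean_quantity = 10
    ),
    item_spec("gp_visit", "community_health_social",
      zero_prob = 0.2, mean_quantity = 6
    ),
    item_spec("paediatrician_visit", "community_health_social",
      zero_prob = 0.5, mean_quantity = 3
    ),
    item_spec("social_worker_visit", "social_care",
      zero_prob = 0.6, mean_quantity = 8
    ),
    item_spec("hospital_outpatient", "hospital_health",
      zero_prob = 0.5, mean_quantity = 3
    ),
    item_spec("hospital_inpatient_day", "hospital_health",
      zero_prob = 0.95, mean_quantity = 1
    ),
    item_spec("nursery_day", "education_childcare",
      zero_prob = 0.05, mean_quantity = 140, dispersion = 4
    ),
    item_spec("time_off_work", "parental_productivity",
      unit = "hour", zero_prob = 0.3, mean_quantity = 500
    ),
    item_spec("informal_care", "parental_informal_care",
      unit = "hour", zero_prob = 0.05, mean_quantity = 4500
    )
  )
}

#' Calibrated cohort configuration for a packaged country fixture
#'
#' Builds the default item list, calibrates it to the country's target
#' arm-level category means, and returns the ready [cohort_config()] with
#' the trial arm sizes (74 intervention, 69 control).
#'
#' @inheritParams example_fixture
#' @param seed Integer seed for cohort generation.
#' @return A calibrated [cohort_config()].
#' @export
example_cohort_config <- function(country = example_countries(), seed = 1L) {
  fx <- example_fixture(country)
  cfg <- cohort_config(default_item_specs(), seed = seed)
  calibrate_to_means(cfg, fx$targets, fx$unit_costs)
}

#' Assembled model for a packaged country fixture
#'
#' @inheritParams example_cohort_config
#' @param mode `"expected"` (deterministic aggregate-mean model, the default
#'   — this is how the headline results are computed) or `"microdata"`
#'   (evaluate a generated synthetic cohort).
#' @return A [cca_model()].
#' @export
example_model <- function(country = example_countries(), seed = 1L,
                          mode = c("expected", "microdata")) {
  mode <- match.arg(mode)
  fx <- example_fixture(country)
  ccfg <- example_cohort_config(country, seed = seed)
  cohort <- if (mode == "expected") {
    expected_arm_summaries(ccfg, fx$unit_costs)
  } else {
    generate_cohort(ccfg)
  }
  cca_model(
    cohort, fx$unit_costs,
    discount = discount_spec(fx$discount_rate),
    school_cost_map = fx$school_cost_map
  )
}
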