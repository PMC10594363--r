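# Shared fixtures built in code.

# Minimal unit-cost table: one event item per service category plus the
# hour-priced parental items.
toy_unit_costs <- function(wage = 20, care = 15, inflation = 1) {
  unit_cost_table(
    "toyland",
    entries = tibble::tibble(
      item_id = c(
        "delivery", "slt", "community", "hospital",
        "nursery", "social", "hours_work", "hours_care"
      ),
      category = c(
        "pact_delivery", "speech_language_therapy",
        "community_health_social", "hospital_health",
        "education_childcare", "social_care",
        "parental_productivity", "parental_informal_care"
      ),
      euro_per_unit = c(1000, 50, 40, 150, 30, 80, NA, NA)
    ),
    wage_per_hour = wage,
    informal_care_price_per_hour = care,
    inflation_index = inflation
  )
}

# Arm summaries with every societal category set (defaults zero).
toy_summary <- function(arm, n = 10, ...) {
  vals <- stats::setNames(rep(0, length(societal_categories())), societal_categories())
  override <- c(...)
  vals[names(override)] <- override
  arm_cost_summary(arm, n, vals)
}

# England fixture summaries built from the packaged calibration targets
# (which encode the published 13-month arm totals at perspective level).
england_summaries <- function() {
  fx <- example_fixture("england")
  lapply(
    stats::setNames(c("intervention", "control"), c("intervention", "control")),
    function(a) {
      sub <- fx$targets[fx$targets$arm == a, ]
      arm_cost_summary(
        a, if (a == "intervention") 74L else 69L,
        stats::setNames(sub$mean_cost, sub$category)
      )
    }
  )
}

# Tiny 5-child cohort with hand-checkable quantities.
toy_cohort <- function() {
  tibble::tibble(
    child_id = c(
      "I1", "I1", "I1", "I2", "I2", "I3",
      "C1", "C1", "C2", "C2", "C2"
    ),
    arm = c(rep("intervention", 6), rep("control", 5)),
    item_id = c(
      "delivery", "slt", "hours_care", "delivery", "hospital", "delivery",
      "slt", "hours_work", "slt", "hospital", "hours_care"
    ),
    quantity = c(1, 4, 100, 1, 2, 1, 6, 10, 2, 1, 50)
  )
}
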