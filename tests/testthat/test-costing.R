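test_that("item filtering keeps items with mean occurrence above the threshold", {
  rec <- tibble::tibble(
    child_id = rep(c("a", "b", "c", "d"), each = 2),
    arm = "control",
    item_id = rep(c("common", "rare"), 4),
    quantity = c(0, 0, 1, 1, 1, 0, 1, 0)
  )
  # common: mean 0.75 > 0.5 retained; rare: mean 0.25 dropped
  expect_equal(filter_items(rec, 0.5), "common")
  # threshold 0: anything with nonzero use retained
  expect_setequal(filter_items(rec, 0), c("common", "rare"))

  # an item used once among many children falls below the default threshold
  many <- tibble::tibble(
    child_id = sprintf("c%03d", 1:143), arm = "control",
    item_id = "once", quantity = c(1, rep(0, 142))
  )
  expect_length(filter_items(many), 0L)
})

test_that("costing multiplies quantities by unit costs and sums within category", {
  uc <- toy_unit_costs()
  rec <- tibble::tibble(
    child_id = "x", arm = "control",
    item_id = c("slt", "community", "hospital"),
    quantity = c(3, 0, 0)
  )
  out <- cost_records(rec, uc)
  expect_equal(out$cost[out$category == "speech_language_therapy"], 150)
  expect_equal(out$cost[out$category == "community_health_social"], 0)

  # two items in one category: 2 x 40 + 1 x 120-equivalent via second item
  uc2 <- unit_cost_table("demo", tibble::tibble(
    item_id = c("p", "q"), category = "community_health_social",
    euro_per_unit = c(10, 25)
  ))
  rec2 <- tibble::tibble(
    child_id = "x", arm = "control",
    item_id = c("p", "q"), quantity = c(2, 4)
  )
  expect_equal(cost_records(rec2, uc2)$cost, 120)

  expect_error(
    cost_records(
      tibble::tibble(child_id = "x", arm = "control", item_id = "??", quantity = 1),
      uc
    ),
    "\\?\\?"
  )
})

test_that("family impacts are valued at wage and formal-care price, inflated multiplicatively", {
  uc <- toy_unit_costs(wage = 20, care = 15, inflation = 1.1)
  expect_equal(productivity_cost(0, uc), 0)
  expect_equal(productivity_cost(10, uc), 200)
  uc2 <- toy_unit_costs(wage = 40)
  expect_equal(productivity_cost(10, uc2), 2 * productivity_cost(10, uc))
  expect_error(productivity_cost(-1, uc), "nonnegative")

  expect_equal(informal_care_cost(100, uc), 1500)
  expect_equal(informal_care_cost(100, toy_unit_costs(care = 0)), 0)
  expect_error(informal_care_cost(-5, uc), "nonnegative")

  expect_equal(inflate_to_2020(100, uc), 110)
  expect_equal(inflate_to_2020(100, toy_unit_costs()), 100)
  # composing inflations multiplies the indices
  a <- toy_unit_costs(inflation = 1.2)
  b <- toy_unit_costs(inflation = 1.5)
  ab <- toy_unit_costs(inflation = 1.2 * 1.5)
  expect_equal(inflate_to_2020(inflate_to_2020(100, a), b), inflate_to_2020(100, ab))
})

test_that("arm summaries are arithmetic means including zeros, invariant to child order", {
  uc <- toy_unit_costs()
  rec <- tibble::tibble(
    child_id = c("a", "b"), arm = "control",
    item_id = "hospital", quantity = c(2, 0) # 300 and 0 euros
  )
  costs <- cost_cohort(rec, uc)
  s <- summarize_arm(costs, "control")
  expect_equal(s$n_children, 2L)
  expect_equal(s$mean_cost_by_category[["hospital_health"]], 150)

  shuffled <- summarize_arm(costs[rev(seq_len(nrow(costs))), ], "control")
  expect_equal(shuffled$mean_cost_by_category, s$mean_cost_by_category)

  expect_error(summarize_arm(costs, "intervention"), "no children")
})

test_that("pipeline costing agrees exactly with a brute-force spreadsheet sum on a toy cohort", {
  uc <- toy_unit_costs(wage = 20, care = 15)
  rec <- toy_cohort()

  # independent oracle: explicit loop over rows, hand pricing
  price <- c(
    delivery = 1000, slt = 50, community = 40, hospital = 150,
    nursery = 30, social = 80, hours_work = 20, hours_care = 15
  )
  cat_of <- c(
    delivery = "pact_delivery", slt = "speech_language_therapy",
    community = "community_health_social", hospital = "hospital_health",
    nursery = "education_childcare", social = "social_care",
    hours_work = "parental_productivity", hours_care = "parental_informal_care"
  )
  oracle <- new.env()
  for (i in seq_len(nrow(rec))) {
    key <- paste(rec$child_id[i], cat_of[[rec$item_id[i]]])
    prev <- if (is.null(oracle[[key]])) 0 else oracle[[key]]
    oracle[[key]] <- prev + rec$quantity[i] * price[[rec$item_id[i]]]
  }

  costs <- cost_cohort(rec, uc)
  for (i in seq_len(nrow(costs))) {
    key <- paste(costs$child_id[i], costs$category[i])
    expected <- if (is.null(oracle[[key]])) 0 else oracle[[key]]
    expect_identical(costs$cost[i], expected)
  }

  # and the societal incremental equals the oracle's difference of arm means
  s_int <- summarize_arm(costs, "intervention")
  s_ctl <- summarize_arm(costs, "control")
  int_total <- (1 * 1000 + 4 * 50 + 100 * 15 + 1 * 1000 + 2 * 150 + 1 * 1000) / 3
  ctl_total <- (6 * 50 + 10 * 20 + 2 * 50 + 1 * 150 + 50 * 15) / 2
  inc <- incremental(s_int, s_ctl, "societal")
  expect_equal(inc$difference, int_total - ctl_total)
})

test_that("incremental costs reproduce the published 13-month England differences", {
  s <- england_summaries()
  expect_equal(incremental(s$intervention, s$control, "healthcare_service")$difference, 5928)
  expect_equal(incremental(s$intervention, s$control, "broader_service")$difference, 4510)
  expect_equal(incremental(s$intervention, s$control, "societal")$difference, -3619)
})

test_that("incremental costs are antisymmetric, additive over nested perspectives, and homogeneous", {
  s <- england_summaries()
  for (p in names(default_perspectives())) {
    fwd <- incremental(s$intervention, s$control, p)$difference
    # antisymmetry: swap the arms' cost vectors
    swapped_int <- arm_cost_summary("intervention", 69, s$control$mean_cost_by_category)
    swapped_ctl <- arm_cost_summary("control", 74, s$intervention$mean_cost_by_category)
    expect_equal(incremental(swapped_int, swapped_ctl, p)$difference, -fwd)
  }

  # additivity: societal = broader + productivity diff + informal-care diff
  soc <- incremental(s$intervention, s$control, "societal")$difference
  broad <- incremental(s$intervention, s$control, "broader_service")$difference
  fam <- incremental(
    s$intervention, s$control,
    perspective_spec("family", c("parental_productivity", "parental_informal_care"))
  )$difference
  expect_equal(soc, broad + fam)

  # homogeneity: scaling all means by lambda scales every incremental by lambda
  lambda <- 1.37
  sc_int <- arm_cost_summary("intervention", 74, lambda * s$intervention$mean_cost_by_category)
  sc_ctl <- arm_cost_summary("control", 69, lambda * s$control$mean_cost_by_category)
  for (p in names(default_perspectives())) {
    expect_equal(
      incremental(sc_int, sc_ctl, p)$difference,
      lambda * incremental(s$intervention, s$control, p)$difference
    )
  }

  # identical summaries: zero for every perspective
  same <- arm_cost_summary("control", 74, s$intervention$mean_cost_by_category)
  for (p in names(default_perspectives())) {
    expect_equal(incremental(s$intervention, same, p)$difference, 0)
  }
})

test_that("a category missing from a summary is treated as zero with a warning", {
  int <- arm_cost_summary("intervention", 74, c(pact_delivery = 6198))
  ctl <- arm_cost_summary("control", 69, c(pact_delivery = 0))
  w <- capture_warnings(inc <- incremental(int, ctl, "healthcare_service"))
  expect_true(length(w) > 0 && all(grepl("treated as 0", w)))
  expect_equal(inc$difference, 6198)
})

test_that("waterfall accumulates differences to the societal incremental, in any middle order", {
  s <- england_summaries()
  wf <- waterfall(s$intervention, s$control)
  expect_equal(as.character(wf$category)[1], "pact_delivery")
  expect_equal(wf$difference[1], 6198)
  soc <- incremental(s$intervention, s$control, "societal")$difference
  expect_equal(wf$cumulative[nrow(wf)], soc)
  expect_equal(wf$cumulative, cumsum(wf$difference))

  # brute force over permutations of a 4-category toy: intermediate values
  # change, the final cumulative never does
  int4 <- toy_summary("intervention", 74,
    pact_delivery = 1000, hospital_health = 200,
    education_childcare = 300, parental_informal_care = 50
  )
  ctl4 <- toy_summary("control", 69,
    hospital_health = 350, education_childcare = 120,
    parental_informal_care = 400
  )
  mids <- c("hospital_health", "education_childcare", "parental_informal_care")
  perms <- list(
    mids, mids[c(1, 3, 2)], mids[c(2, 1, 3)],
    mids[c(2, 3, 1)], mids[c(3, 1, 2)], mids[c(3, 2, 1)]
  )
  finals <- vapply(perms, function(p) {
    wfp <- waterfall(int4, ctl4, c("pact_delivery", p))
    wfp$cumulative[nrow(wfp)]
  }, numeric(1))
  expect_true(all(finals == finals[1]))
  expect_equal(finals[1], incremental(int4, ctl4, "societal")$difference)
})

test_that("waterfall validates its category order", {
  s <- england_summaries()
  expect_error(
    waterfall(s$intervention, s$control, c("hospital_health", "pact_delivery")),
    "begin with pact_delivery"
  )
  # omitting a category with nonzero difference is an error
  expect_error(
    waterfall(s$intervention, s$control, c("pact_delivery", "hospital_health")),
    "nonzero difference"
  )
  # omitting only zero-difference categories is fine
  int <- toy_summary("intervention", 5, pact_delivery = 100)
  ctl <- toy_summary("control", 5)
  wf <- waterfall(int, ctl, "pact_delivery")
  expect_equal(wf$cumulative, 100)
})
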