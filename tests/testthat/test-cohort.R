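test_that("generated cohorts have the configured arm sizes and full item coverage", {
  items <- list(
    item_spec("a", "hospital_health", zero_prob = 0.3, mean_quantity = 2),
    item_spec("b", "social_care", zero_prob = 0.5, mean_quantity = 5)
  )
  cfg <- cohort_config(items, n_intervention = 74, n_control = 69, seed = 7)
  rec <- generate_cohort(cfg)

  ids_int <- unique(rec$child_id[rec$arm == "intervention"])
  ids_ctl <- unique(rec$child_id[rec$arm == "control"])
  expect_length(ids_int, 74)
  expect_length(ids_ctl, 69)
  # one record per child per item
  expect_equal(nrow(rec), (74 + 69) * 2)
  expect_equal(anyDuplicated(rec[, c("child_id", "item_id")]), 0L)
  expect_true(all(rec$quantity >= 0))
})

test_that("cohort generation is deterministic and per-arm streams are independent", {
  items <- list(item_spec("a", "hospital_health", zero_prob = 0.2, mean_quantity = 3))
  cfg <- cohort_config(items, n_intervention = 20, n_control = 15, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  # growing the control arm must not perturb the intervention arm's draws
  cfg_bigger <- cohort_config(items, n_intervention = 20, n_control = 40, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg_bigger)
  expect_identical(
    a[a$arm == "intervention", ],
    b[b$arm == "intervention", ]
  )
})

test_that("degenerate and large-sample quantity distributions behave as specified", {
  # zero_prob 1: all zero
  cfg0 <- cohort_config(
    list(item_spec("a", "hospital_health", zero_prob = 1, mean_quantity = 10)),
    n_intervention = 30, n_control = 30, seed = 1
  )
  expect_true(all(generate_cohort(cfg0)$quantity == 0))

  # fixed item: exactly the configured quantity in each arm
  cfgf <- cohort_config(
    list(item_spec("d", "pact_delivery",
      mean_quantity = c(intervention = 1, control = 0), fixed = TRUE
    )),
    n_intervention = 10, n_control = 10, seed = 1
  )
  recf <- generate_cohort(cfgf)
  expect_true(all(recf$quantity[recf$arm == "intervention"] == 1))
  expect_true(all(recf$quantity[recf$arm == "control"] == 0))

  # law of large numbers: mean 10, no zero-inflation, n = 10,000 per arm
  cfg <- cohort_config(
    list(item_spec("a", "hospital_health", zero_prob = 0, mean_quantity = 10)),
    n_intervention = 10000, n_control = 10000, seed = 99
  )
  q <- generate_cohort(cfg)$quantity
  se <- stats::sd(q) / sqrt(length(q))
  expect_lt(abs(mean(q) - 10), 3 * se)
})

test_that("invalid cohort configurations are rejected", {
  it <- list(item_spec("a", "hospital_health", mean_quantity = 1))
  expect_error(cohort_config(it, n_intervention = 0), "positive integer")
  expect_error(cohort_config(it, n_control = -1), "positive integer")
  expect_error(
    cohort_config(list(it[[1]], it[[1]])),
    "unique"
  )
  expect_error(item_spec("a", "not_a_category"), "unknown cost category")
  expect_error(item_spec("a", "social_care", zero_prob = 1.2), "zero_prob")
  expect_error(item_spec("a", "social_care", mean_quantity = -1), "nonnegative")
  expect_error(item_spec("a", "social_care", dispersion = 0), "dispersion")
})

test_that("calibration matches the closed-form single-item solution", {
  uc <- unit_cost_table("demo", tibble::tibble(
    item_id = "visit", category = "hospital_health", euro_per_unit = 100
  ))
  cfg <- cohort_config(
    list(item_spec("visit", "hospital_health", zero_prob = 0, mean_quantity = 1)),
    seed = 1
  )
  tgt <- tibble::tibble(
    arm = "intervention", category = "hospital_health", mean_cost = 1723
  )
  cal <- calibrate_to_means(cfg, tgt, uc)
  # mean_quantity = target / (unit_cost * (1 - zero_prob)) = 1723 / 100
  expect_equal(cal$items$visit$mean_quantity[["intervention"]], 17.23)

  # zero target zeroes the category
  tgt0 <- tibble::tibble(arm = "control", category = "hospital_health", mean_cost = 0)
  cal0 <- calibrate_to_means(cfg, tgt0, uc)
  expect_equal(cal0$items$visit$mean_quantity[["control"]], 0)
})

test_that("calibration splits multi-item categories proportionally and errors on dead categories", {
  uc <- unit_cost_table("demo", tibble::tibble(
    item_id = c("a", "b", "dead"),
    category = c("hospital_health", "hospital_health", "social_care"),
    euro_per_unit = c(100, 50, 0)
  ))
  cfg <- cohort_config(
    list(
      item_spec("a", "hospital_health", zero_prob = 0, mean_quantity = 2), # prior 200
      item_spec("b", "hospital_health", zero_prob = 0.5, mean_quantity = 4), # prior 100
      item_spec("dead", "social_care", zero_prob = 0, mean_quantity = 1)
    ),
    seed = 1
  )
  cal <- calibrate_to_means(
    cfg,
    tibble::tibble(arm = "intervention", category = "hospital_health", mean_cost = 600),
    uc
  )
  # priors 200:100 scale by 2 -> expected costs 400 and 200
  expect_equal(cal$items$a$mean_quantity[["intervention"]], 4)
  expect_equal(cal$items$b$mean_quantity[["intervention"]], 8)

  expect_error(
    calibrate_to_means(
      cfg,
      tibble::tibble(arm = "control", category = "social_care", mean_cost = 10),
      uc
    ),
    "cannot calibrate"
  )
})

test_that("expected costs of the calibrated England fixture equal the printed arm totals", {
  fx <- example_fixture("england")
  ccfg <- example_cohort_config("england", seed = 3)
  s <- expected_arm_summaries(ccfg, fx$unit_costs)
  hc <- c(
    "pact_delivery", "speech_language_therapy",
    "community_health_social", "hospital_health"
  )
  expect_equal(sum(s$intervention$mean_cost_by_category[hc]), 7651)
  expect_equal(sum(s$control$mean_cost_by_category[hc]), 1723)
  expect_equal(sum(s$intervention$mean_cost_by_category[societal_categories()]), 95689)
  expect_equal(sum(s$control$mean_cost_by_category[societal_categories()]), 99308)
})

test_that("cohort CSV round-trips losslessly and rejects malformed input", {
  rec <- toy_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  # empty cohort: header only, reads back with zero rows
  empty <- rec[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, path2)
  expect_equal(nrow(read_cohort(path2)), 0L)

  # negative quantity names the offending row
  bad <- rec
  bad$quantity[3] <- -1
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path3)
  expect_error(read_cohort(path3), "row 3")

  # missing column
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec[, c("child_id", "arm", "item_id")], path4)
  expect_error(suppressWarnings(read_cohort(path4)), "missing|quantity")
})
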