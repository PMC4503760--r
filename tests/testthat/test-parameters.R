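test_that("baseline registry reproduces the published input values", {
  p <- bl()
  expect_identical(p$cohort_2012$new_listings, 10143)
  expect_identical(p$cohort_2012$share_no_meld, 0.094)
  expect_identical(p$cohort_2012$share_inactive, 0.129)
  expect_identical(unname(p$survival[10]), 0.63)
  expect_identical(unname(p$survival[1]), 0.90)
  expect_identical(unname(p$meld_baseline_shares),
                   c(0.036, 0.524, 0.319, 0.086, 0.035))
  expect_identical(point_estimate(p$costs$monthly_pre_lt[[">40"]]), 51085)
  expect_identical(point_estimate(p$costs$monthly_pre_lt[["<9"]]), 347)
  expect_identical(point_estimate(p$costs$organ_procurement), 73989)
  expect_identical(point_estimate(p$costs$hospital_admission), 330242)
  expect_identical(point_estimate(p$costs$physician_fees), 48562)
  expect_identical(point_estimate(p$costs$last30d_adjustment), 26469)
  expect_identical(point_estimate(p$costs$post90d_base), 139746)
  expect_identical(point_estimate(p$costs$immunosuppression_annual), 36708)
  expect_identical(point_estimate(p$rates$escalation), 0.049)
  expect_identical(point_estimate(p$rates$discount), 0.03)
  expect_identical(point_estimate(p$waiting_time_days$meld_lt10), 1776)
  expect_identical(point_estimate(p$waiting_time_days$status1), 6)
  expect_identical(point_estimate(p$pct_not_transplanted), 0.213)
  expect_identical(
    point_estimate(p$complications$superficial_skin_infection$added_cost),
    -2883)
  expect_length(p$complications, 15)
  expect_length(p$costs$admission_component_shares, 16)
  expect_length(p$costs$casemix_multipliers, 7)
  # whole-registry structural checks
  expect_lt(abs(sum(p$meld_baseline_shares) - 1), 0.001)
  expect_silent(validate_lt_parameters(p))
})

test_that("validation rejects broken parameter tables", {
  p <- bl()
  bad <- p
  bad$survival[5] <- 0.99  # breaks monotonicity
  expect_error(validate_lt_parameters(bad), "non-increasing")
  bad <- p
  bad$meld_baseline_shares[1] <- 0.2
  expect_error(validate_lt_parameters(bad), "sum to 1")
  bad <- p
  bad$cohort_2012$share_no_meld <- -0.1
  expect_error(validate_lt_parameters(bad), "domain error")
  bad <- p
  bad$waitlist_mortality[["<9"]]$prob[2] <- 0.001
  expect_error(validate_lt_parameters(bad), "non-decreasing")
})

test_that("config loading flags missing and unknown keys by name", {
  cfg <- as_config_list(bl())
  cfg$rates$unexpected_rate <- 0.5
  expect_error(load_parameters(cfg), "unknown key.*rates.*unexpected_rate")
  cfg <- as_config_list(bl())
  cfg$rates$escalation <- NULL
  expect_error(load_parameters(cfg), "missing key.*escalation")
  cfg <- as_config_list(bl())
  cfg$costs$organ_procurement <- list(kind = "triangular", base = 2,
                                      low = 5, high = 7)
  expect_error(load_parameters(cfg), "range error")
})

test_that("the baseline round-trips through YAML and JSON configs", {
  p <- bl()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p, path)
    p2 <- load_parameters(path)
    expect_equal(as_config_list(p2), as_config_list(p), tolerance = 1e-12)
  }
})

test_that("variable rows resolve to triangulars with the analogue's spread", {
  p <- resolve_variable(bl())
  sp40 <- p$costs$monthly_pre_lt[[">40"]]
  expect_identical(sp40$kind, "triangular")
  expect_identical(sp40$base, 51085)
  # MELD 30-39 spread: 20417/31644 and 42871/31644 of base
  expect_equal(sp40$low, 51085 * 20417 / 31644)
  expect_equal(sp40$high, 51085 * 42871 / 31644)
  # share-change rows whose base matches an analogue adopt its exact bounds
  sc <- p$growth$meld_share_annual_change
  expect_equal(sc[["<9"]]$low, -0.04)
  expect_equal(sc[["<9"]]$high, -0.006)
  expect_equal(sc[["20-29"]]$low, 0.002)
  expect_equal(sc[[">40"]]$high, 0.205)
  for (cat in names(sc)) {
    expect_identical(sc[[cat]]$kind, "triangular")
    expect_lte(sc[[cat]]$low, sc[[cat]]$base)
    expect_gte(sc[[cat]]$high, sc[[cat]]$base)
  }
})

test_that("the registry export is a complete flat audit table", {
  reg <- parameter_registry(bl())
  expect_true(all(c("name", "kind", "base", "low", "high", "units",
                    "source") %in% names(reg)))
  expect_gt(nrow(reg), 120)  # every scalar input appears
  expect_true("rates.escalation" %in% reg$name)
  expect_identical(reg$base[reg$name == "rates.escalation"], 0.049)
  path <- withr::local_tempfile(fileext = ".csv")
  parameter_registry(bl(), path)
  expect_true(file.exists(path))
  expect_identical(nrow(utils::read.csv(path)), nrow(reg))
})
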