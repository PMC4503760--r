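test_that("the net escalation factor behaves like a compound real rate", {
  expect_identical(escalation_factor(list(r = 0.049, d = 0.03), 0), 1)
  for (yrs in c(1, 5, 19))
    expect_equal(escalation_factor(list(r = 0.04, d = 0.04), yrs), 1)
  expect_equal(escalation_factor(bl(), 19), (1.049 / 1.03)^19)
  expect_equal(escalation_factor(bl(), 19), 1.41522, tolerance = 1e-5)
  expect_error(escalation_factor(bl(), -1), ">= 0")
})

test_that("severe-illness pre-transplant costs are 12 months at listing prices", {
  p <- bl()
  expect_identical(pre_lt_cost(p, ">40", 1), 12 * 51085)
  expect_equal(pre_lt_cost(p, ">40", 20), 613020 * (1.049 / 1.03)^19)
  expect_lt(abs(pre_lt_cost(p, ">40", 20) / 867564 - 1), 0.001)
  expect_lt(abs(pre_lt_cost(p, "30-39", 20) / 537402 - 1), 0.001)
  expect_identical(pre_lt_cost(p, "20-29", 1), 12 * 19602)
  expect_error(pre_lt_cost(p, "41+", 1), "unknown MELD")
  # scaling law: severe categories scale exactly by the net factor
  for (cat in c("20-29", "30-39", ">40"))
    for (t in c(2, 11, 20))
      expect_equal(pre_lt_cost(p, cat, t),
                   pre_lt_cost(p, cat, 1) * escalation_factor(p, t - 1))
})

test_that("waitlist accrual matches a month-by-month ledger", {
  # brute-force oracle: whole months, each escalated at the net monthly
  # rate, plus the last-30-days adjustment at the transplant date
  p <- bl()
  months <- 48
  p$waiting_time_days$meld_lt10 <- dist_spec("fixed", months * 365 / 12)
  p$time_to_transplant_annual_change <- dist_spec("fixed", 0)
  f <- (1.049 / 1.03)^(1 / 12)
  ledger <- sum(347 * f^(0:(months - 1))) + 26469 * f^months
  expect_equal(pre_lt_cost(p, "<9", 1), ledger, tolerance = 1e-9)
  expect_equal(pre_lt_cost(p, "<9", 5), ledger * (1.049 / 1.03)^4,
               tolerance = 1e-9)
  # published Year-20 low-MELD values are convention-dependent; agree to 20%
  pb <- bl()
  expect_lt(abs(pre_lt_cost(pb, "<9", 20) / 71621 - 1), 0.20)
  expect_lt(abs(pre_lt_cost(pb, "<9", 1) / 49407 - 1), 0.20)
})

test_that("the MELD-weighted pre-transplant cost tracks the published average", {
  p <- bl()
  expect_lt(abs(weighted_pre_lt_cost(p, 1) / 168386 - 1), 0.03)
  expect_lt(abs(weighted_pre_lt_cost(p, 20) / 307610 - 1), 0.05)
  # degenerate weights recover the single-category cost
  w <- stats::setNames(c(0, 0, 0, 0, 1), meld_categories())
  expect_equal(weighted_pre_lt_cost(p, 1, shares = w),
               pre_lt_cost(p, ">40", 1))
  expect_error(weighted_pre_lt_cost(p, 1, shares = w * 2), "sum to 1")
})

test_that("admission cost composes components, case mix and escalation", {
  p <- bl()
  expect_equal(casemix_uplift(p), 0.3674)
  # with no case-mix uplift the component sum is procurement + hospital + fees
  p0 <- p
  p0$admission_casemix[names(p0$costs$casemix_multipliers)] <- 0
  expect_equal(admission_cost(p0, 1), 73989 + 330242 + 48562)
  expect_lt(abs(admission_cost(p, 1) / 588580 - 1), 0.07)
  for (t in c(5, 20))
    expect_equal(admission_cost(p, t),
                 admission_cost(p, 1) * escalation_factor(p, t - 1))
})

test_that("post-transplant cost sums base, complications and immunosuppression", {
  p <- bl()
  expect_lt(abs(complication_addon(p) - 131995), 5)
  expect_lt(abs(post_lt_cost(p, 1) / 670839 - 1), 0.05)
  expect_lt(abs(post_lt_cost(p, 20) / 949391 - 1), 0.05)
  # Year-20 / Year-1 ratio equals the net factor exactly
  expect_equal(post_lt_cost(p, 20) / post_lt_cost(p, 1),
               escalation_factor(p, 19))
  # a negative complication cost reduces the total by exactly freq * |cost|
  pz <- p
  pz$complications$superficial_skin_infection$frequency <-
    dist_spec("fixed", 0)
  expect_equal(post_lt_cost(pz, 1) - post_lt_cost(p, 1), 0.16 * 2883)
})

test_that("phase totals are exactly additive and match published sums", {
  p <- bl()
  pc <- phase_costs(p, years = c(1, 10, 20))
  expect_identical(pc$total,
                   pc$pre_lt_weighted + pc$admission + pc$post_lt)
  # published Year-1 and Year-20 phase components sum to the printed totals
  expect_identical(168386 + 588580 + 670839, 1427805)
  expect_identical(307610 + 836788 + 949391, 2093789)
  tol1 <- 0.03 * 168386 + 0.07 * 588580 + 0.05 * 670839
  expect_lt(abs(pc$total[1] - 1427805), tol1)
})

test_that("national expenditure scales as the product of cost and demand", {
  expect_equal(national_expenditure(1427805, 10367), 14802054435)
  expect_identical(round(national_expenditure(1427805, 10367) / 1e8) / 10,
                   14.8)
  expect_identical(round(national_expenditure(2093789, 12763) / 1e8) / 10,
                   26.7)
  expect_identical(national_expenditure(2093789, 0), 0)
  expect_error(national_expenditure(-1, 10), ">= 0")
  fe <- forecast_expenditure(bl(), years = c(1, 20))
  expect_lt(abs(fe$total_usd[1] / 14.8e9 - 1), 0.05)
  expect_lt(abs(fe$total_usd[2] / 26.7e9 - 1), 0.05)
})

test_that("discounting and escalation move every phase cost monotonically", {
  p <- bl()
  costs_at <- function(params) c(pre_lt_cost(params, "<9", 10),
                                 pre_lt_cost(params, ">40", 10),
                                 admission_cost(params, 10),
                                 post_lt_cost(params, 10))
  base <- costs_at(p)
  hi_d <- p
  hi_d$rates$discount <- dist_spec("fixed", 0.06)
  expect_true(all(costs_at(hi_d) < base))
  hi_r <- p
  hi_r$rates$escalation <- dist_spec("fixed", 0.08)
  expect_true(all(costs_at(hi_r) > base))
})
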