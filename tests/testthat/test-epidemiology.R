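test_that("new-listing forecasts compound from the 2012 registry count", {
  p <- bl()
  expect_identical(round(project_new_listings(p, 1)), 10367)
  expect_identical(round(project_new_listings(p, 20)), 12763)
  expect_error(project_new_listings(p, 21), "out of range")
  expect_error(project_new_listings(p, 0), "out of range")
  # zero growth: the 2012 count persists
  p0 <- set_base(p$growth, "listings_annual_change", 0)
  pz <- p; pz$growth <- p0
  for (t in c(1, 7, 20))
    expect_equal(project_new_listings(pz, t), 10143)
  # strictly increasing demand under positive growth
  n <- vapply(1:20, project_new_listings, numeric(1), params = p)
  expect_true(all(diff(n) > 0))
})

test_that("MELD share evolution renormalizes and shifts mix to sicker patients", {
  p <- bl()
  s2012 <- evolve_meld_shares(p, 2012)
  expect_equal(unname(s2012), unname(p$meld_baseline_shares /
                                       sum(p$meld_baseline_shares)))
  s2014 <- evolve_meld_shares(p, 2014)
  expect_identical(names(which.max(s2014)), "10-19")
  expect_identical(round(100 * unname(s2014["10-19"])), 51)
  s2033 <- evolve_meld_shares(p, 2033)
  expect_identical(names(which.max(s2033)), "20-29")
  expect_identical(round(100 * unname(s2033["20-29"])), 39)
  # renormalization property across scenarios and years
  for (seed in 1:5) {
    sc <- random_scenario(seed, 0.2)
    for (yr in c(2012, 2020, 2033))
      expect_equal(sum(evolve_meld_shares(sc$params, yr)), 1)
  }
})

test_that("with-MELD listings honour anchors and track computed shares", {
  p <- bl()
  expect_identical(project_with_meld_listings(p, 1, "anchored"), 7934)
  expect_identical(project_with_meld_listings(p, 7, "anchored"), 8006)
  expect_identical(project_with_meld_listings(p, 20, "anchored"), 7600)
  expect_error(project_with_meld_listings(p, 2, "anchored"), "no published")
  computed <- project_with_meld_listings(p, 1, "computed")
  expect_lt(abs(computed / 7934 - 1), 0.01)
  # auto prefers the anchor where one exists
  expect_identical(project_with_meld_listings(p, 1, "auto"), 7934)
  expect_identical(project_with_meld_listings(p, 2, "auto"),
                   project_with_meld_listings(p, 2, "computed"))
})

test_that("per-category counts reproduce the published 20-year changes", {
  p <- bl()
  c2014 <- meld_category_counts(evolve_meld_shares(p, 2014), 7934)
  c2033 <- meld_category_counts(evolve_meld_shares(p, 2033), 7600)
  chg <- round(100 * (c2033 / c2014 - 1))
  expect_identical(unname(chg["<9"]), -55)
  expect_identical(unname(chg[">40"]), 76)
  expect_lte(abs(chg[["10-19"]] - -27), 3)
  expect_lte(abs(chg[["20-29"]] - 15), 3)
  expect_lte(abs(chg[["30-39"]] - 42), 3)
  expect_equal(unname(meld_category_counts(
    stats::setNames(rep(0.2, 5), meld_categories()), 100)), rep(20, 5))
  expect_error(meld_category_counts(evolve_meld_shares(p, 2014), -1),
               "negative")
})

test_that("waitlist mortality interpolates linearly and caps at the horizon", {
  p <- bl()
  sched40 <- p$waitlist_mortality[[">40"]]
  # 20-day wait scales the 3-month cumulative rate through the origin
  expect_equal(ltecon:::interp_mortality(sched40, 20 / 365),
               0.793 * (20 / 365) / 0.25)
  # beyond the longest printed horizon the schedule holds flat
  expect_equal(ltecon:::interp_mortality(sched40, 2), 0.793)
  sched9 <- p$waitlist_mortality[["<9"]]
  expect_equal(ltecon:::interp_mortality(sched9, 4.5),
               0.076 + 0.5 * (0.084 - 0.076))
  expect_error(ltecon:::interp_mortality(sched9, -1), "negative")
})

test_that("attrition partitions each cohort and zero rates transplant everyone", {
  p <- bl()
  for (t in c(1, 10, 20)) {
    att <- waitlist_attrition(p, t)
    tot <- att[att$meld == "total", ]
    expect_lt(abs(tot$died_or_severe + tot$not_transplanted +
                    tot$transplanted - tot$listed), 0.5)
  }
  # zero mortality and zero refusal: everyone listed is transplanted
  pz <- bl()
  for (cat in meld_categories())
    pz$waitlist_mortality[[cat]]$prob[] <- 0
  pz$pct_not_transplanted <- dist_spec("fixed", 0)
  att <- waitlist_attrition(pz, 1)
  tot <- att[att$meld == "total", ]
  expect_equal(tot$transplanted, tot$listed)
})

test_that("admission outcomes and survivor chains follow the fixed rates", {
  p <- bl()
  expect_equal(admission_outcomes(p, 100)$died, 6)
  expect_equal(admission_outcomes(p, 5000)$retransplanted, 150)
  expect_equal(admission_outcomes(p, 0)$died, 0)
  expect_equal(unname(survivors_at_year(p, 1000, 10)), 630)
  expect_equal(unname(survivors_at_year(p, 1000, 1)), 900)
  expect_equal(unname(survivors_at_year(p, 0, 5)), 0)
  expect_error(survivors_at_year(p, 100, 11), "out of range")
  surv <- vapply(1:10, function(k) survivors_at_year(p, 1000, k), numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("mean listing age rises from about 58 to about 62 years", {
  p <- bl()
  expect_lt(abs(mean_age_at_listing(p, 2014) - 57.7), 1.5)
  expect_lt(abs(mean_age_at_listing(p, 2033) - 62), 1.5)
  # all weight in one group returns that group's midpoint
  p1 <- p
  p1$cohort_2012$age_shares[] <- c(0, 0, 1, 0)
  p1$growth$age_group_annual_change[] <- 0
  expect_equal(mean_age_at_listing(p1, 2020), 57)
})

test_that("cohort forecast matches a spreadsheet-style recomputation", {
  # independent oracle: plain year-by-year arithmetic for a 3-year horizon
  p <- bl()
  fc <- forecast_cohorts(p, years = 1:3)
  g <- 0.011; ttc <- 0.017
  for (t in 1:3) {
    cy <- 2014 + t - 1
    n <- 10143 * 1.011^(cy - 2012)
    expect_equal(fc$new_listings[t], n, tolerance = 1e-9)
    nm <- 0.094 * 1.076^(cy - 2012)
    ia <- 0.129 * 0.995^(cy - 2012)
    wm <- n * (1 - nm - ia)
    expect_equal(fc$with_meld[t], wm, tolerance = 1e-9)
    raw <- c(0.036 * 0.973^(cy - 2012), 0.524 * 0.997^(cy - 2012),
             0.319 * 1.022^(cy - 2012), 0.086 * 1.034^(cy - 2012),
             0.035 * 1.045^(cy - 2012))
    shares <- raw / sum(raw)
    waits <- c(1776, 639, 106, 20, 20) * (1 + ttc)^(t - 1) / 365
    mort <- numeric(5)
    sched <- p$waitlist_mortality
    for (i in 1:5) {
      s <- sched[[i]]
      mort[i] <- stats::approx(c(0, s$years), c(0, s$prob), waits[i],
                               rule = 2)$y
    }
    listed <- shares * wm
    died <- sum(listed * mort)
    tx <- sum((listed - listed * mort) * (1 - 0.213))
    expect_equal(fc$died_or_severe[t], died, tolerance = 1e-9)
    expect_equal(fc$transplanted[t], tx, tolerance = 1e-9)
    expect_equal(fc$died_admission[t], 0.06 * tx, tolerance = 1e-9)
    expect_equal(fc$survivors_10yr[t], 0.63 * tx, tolerance = 1e-9)
  }
})
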