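#' Calendar year of a model listing year
#'
#' Year 1 of the simulation corresponds to calendar 2014; growth from the
#' 2012 registry data year therefore compounds over `calendar_year - 2012`
#' years.
#'
#' @param params An `lt_parameters` object.
#' @param model_year Listing year index (Year 1 = first model year).
#' @return Calendar year.
#' @export
calendar_year <- function(params, model_year) {
  params$clock$first_model_year + model_year - 1
}

check_model_year <- function(params, model_year) {
  if (any(model_year < 1 | model_year > params$clock$horizon_years))
    stop(sprintf("model_year out of range 1..%d", params$clock$horizon_years),
         call. = FALSE)
  invisible(model_year)
}

#' Forecast new waitlist listings for a model year
#'
#' Compounds the 2012 registry count of new listings at the annual listings
#' growth rate over the years elapsed since the data year:
#' `N(t) = N_2012 * (1 + g)^(calendar_year - 2012)`.
#'
#' @inheritParams calendar_year
#' @param rounded Round to whole patients for reporting (default `FALSE`:
#'   fractional patients are carried unrounded through the pipeline).
#' @return Forecast count of new listings (possibly fractional).
#' @examples
#' p <- load_parameters()
#' round(project_new_listings(p, 1))   # 10367 (2014)
#' round(project_new_listings(p, 20))  # 12763 (2033)
#' @export
project_new_listings <- function(params, model_year, rounded = FALSE) {
  check_model_year(params, model_year)
  g <- point_estimate(params$growth$listings_annual_change)
  yrs <- calendar_year(params, model_year) - params$clock$base_data_year
  n <- params$cohort_2012$new_listings * (1 + g)^yrs
  if (rounded) round(n) else n
}

compound_shares <- function(shares, changes, elapsed) {
  s <- shares * (1 + changes)^elapsed
  s / sum(s)
}

#' Evolve the MELD category mix of new listings
#'
#' Each baseline MELD share is compounded by its per-category annual change
#' over the years elapsed since 2012, then the five shares are renormalized
#' to sum to one.
#'
#' @param params An `lt_parameters` object.
#' @param year Calendar year (>= base data year).
#' @return Named fraction vector over the five MELD categories, summing to 1.
#' @examples
#' p <- load_parameters()
#' round(100 * evolve_meld_shares(p, 2014))  # 10-19 largest at 51%
#' round(100 * evolve_meld_shares(p, 2033))  # 20-29 largest at 39%
#' @export
evolve_meld_shares <- function(params, year) {
  if (year < params$clock$base_data_year)
    stop("year precedes the base data year", call. = FALSE)
  deltas <- vapply(params$growth$meld_share_annual_change, point_estimate,
                   numeric(1))
  compound_shares(params$meld_baseline_shares, deltas,
                  year - params$clock$base_data_year)
}

#' Forecast new listings carrying a MELD score
#'
#' Newly listed patients with no reported MELD score or inactive status are
#' excluded from the MELD-stratified cohort. In `"computed"` mode the two
#' exclusion shares are compounded at their annual changes from 2012 and
#' subtracted from total listings. `"anchored"` mode returns the published
#' projection for years where one exists (2014, 2020, 2033); `"auto"` uses
#' the anchor when available and the computed value otherwise.
#'
#' @inheritParams calendar_year
#' @param mode `"computed"`, `"anchored"` or `"auto"`.
#' @return Count of new with-MELD listings.
#' @export
project_with_meld_listings <- function(params, model_year,
                                       mode = c("auto", "computed", "anchored")) {
  mode <- match.arg(mode)
  check_model_year(params, model_year)
  cy <- calendar_year(params, model_year)
  anchor <- params$anchors$with_meld[as.character(cy)]
  if (mode == "anchored" || (mode == "auto" && !is.na(anchor))) {
    if (is.na(anchor))
      stop(sprintf("no published with-MELD anchor for calendar year %d", cy),
           call. = FALSE)
    return(unname(anchor))
  }
  elapsed <- cy - params$clock$base_data_year
  no_meld <- params$cohort_2012$share_no_meld *
    (1 + point_estimate(params$growth$no_meld_annual_change))^elapsed
  inactive <- params$cohort_2012$share_inactive *
    (1 + point_estimate(params$growth$inactive_annual_change))^elapsed
  project_new_listings(params, model_year) * (1 - no_meld - inactive)
}

#' Split a with-MELD cohort into per-category counts
#'
#' @param shares Named fraction vector over MELD categories (must sum to 1).
#' @param with_meld_total Total with-MELD listings (>= 0).
#' @return Named count vector (fractional persons retained).
#' @export
meld_category_counts <- function(shares, with_meld_total) {
  if (with_meld_total < 0) stop("negative cohort total", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-6)
    stop("shares must sum to 1", call. = FALSE)
  shares * with_meld_total
}

# Cumulative death/severe-illness probability after `years` on the list:
# linear interpolation on the printed schedule, through the origin, held
# flat beyond the longest printed horizon.
interp_mortality <- function(schedule, years) {
  if (any(years < 0)) stop("waiting duration negative", call. = FALSE)
  stats::approx(c(0, schedule$years), c(0, schedule$prob),
                xout = years, rule = 2)$y
}

#' Waiting time on the list by MELD category
#'
#' Maps each MELD category to the median waiting time of its waiting-time
#' band (days), grown by the annual change in time-to-transplant over the
#' years elapsed since Year 1.
#'
#' @inheritParams calendar_year
#' @param status1_for_top Use the status-1 waiting time (6 days) for MELD
#'   >40 rather than the >=25 band (20 days).
#' @return Named vector of waiting times in days per MELD category.
#' @export
waiting_time_by_meld <- function(params, model_year = 1,
                                 status1_for_top = FALSE) {
  check_model_year(params, model_year)
  bands <- meld_wait_band(status1_for_top)
  base_days <- vapply(params$waiting_time_days[bands], point_estimate,
                      numeric(1))
  names(base_days) <- names(bands)
  ttc <- point_estimate(params$time_to_transplant_annual_change)
  base_days * (1 + ttc)^(model_year - 1)
}

#' Waitlist attrition for one listing cohort
#'
#' For each MELD category, applies the cumulative death/severe-illness
#' schedule over that category's waiting duration, removes the fraction of
#' surviving eligible patients who do not proceed to transplant, and counts
#' the remainder as transplanted. The three outcomes partition the cohort.
#'
#' @inheritParams calendar_year
#' @param with_meld_mode Passed to [project_with_meld_listings()].
#' @return A `data.frame` with one row per MELD category plus a `total`
#'   row: `listed`, `died_or_severe`, `not_transplanted`, `transplanted`.
#' @export
waitlist_attrition <- function(params, model_year,
                               with_meld_mode = "computed") {
  check_model_year(params, model_year)
  cy <- calendar_year(params, model_year)
  shares <- evolve_meld_shares(params, cy)
  total <- project_with_meld_listings(params, model_year, with_meld_mode)
  listed <- meld_category_counts(shares, total)
  wait_years <- waiting_time_by_meld(params, model_year) / 365
  mort <- vapply(meld_categories(), function(cat)
    interp_mortality(params$waitlist_mortality[[cat]], wait_years[[cat]]),
    numeric(1))
  died <- listed * mort
  eligible <- listed - died
  not_tx <- eligible * point_estimate(params$pct_not_transplanted)
  tx <- eligible - not_tx
  out <- data.frame(
    meld = c(meld_categories(), "total"),
    listed = c(listed, sum(listed)),
    died_or_severe = c(died, sum(died)),
    not_transplanted = c(not_tx, sum(not_tx)),
    transplanted = c(tx, sum(tx)),
    row.names = NULL)
  out
}

#' Index-hospitalization outcomes among transplanted patients
#'
#' @param params An `lt_parameters` object.
#' @param transplanted Count of transplanted patients (>= 0).
#' @return List with `died` (6% of operated) and `retransplanted` (3%).
#' @export
admission_outcomes <- function(params, transplanted) {
  if (transplanted < 0) stop("transplanted must be >= 0", call. = FALSE)
  cm <- params$admission_casemix
  list(died = cm[["died"]] * transplanted,
       retransplanted = cm[["retransplant"]] * transplanted)
}

#' Post-transplant survivors k years after operation
#'
#' @param params An `lt_parameters` object.
#' @param operated Count of operated patients.
#' @param k Post-transplant year, 1..10.
#' @return `operated * S(k)` where `S` is the cumulative survival schedule.
#' @export
survivors_at_year <- function(params, operated, k) {
  if (any(k < 1 | k > length(params$survival)))
    stop(sprintf("k out of range 1..%d", length(params$survival)),
         call. = FALSE)
  operated * params$survival[k]
}

#' Mean age at listing for a calendar year
#'
#' Age-group shares are compounded at their annual changes from 2012,
#' renormalized, and combined with fixed group midpoints (18-34: 26;
#' 35-49: 42; 50-64: 57; >65: 72).
#'
#' @param params An `lt_parameters` object.
#' @param year Calendar year.
#' @param midpoints Age assigned to each group.
#' @return Mean age in years.
#' @export
mean_age_at_listing <- function(params, year,
                                midpoints = c("18-34" = 26, "35-49" = 42,
                                              "50-64" = 57, ">65" = 72)) {
  if (year < params$clock$base_data_year)
    stop("year precedes the base data year", call. = FALSE)
  s <- compound_shares(params$cohort_2012$age_shares,
                       params$growth$age_group_annual_change,
                       year - params$clock$base_data_year)
  sum(s * midpoints[names(s)])
}

#' Full cohort forecast over the simulation horizon
#'
#' Runs the epidemiology model for every listing year: new listings,
#' with-MELD listings, MELD shares and counts, mean age, and waitlist
#' attrition splits. Counts are carried unrounded; round at report time.
#'
#' @param params An `lt_parameters` object.
#' @param years Model year indices (default the full horizon).
#' @param with_meld_mode Passed to [project_with_meld_listings()].
#' @return A `data.frame` of class `lt_cohort_forecast`, one row per year.
#' @examples
#' fc <- forecast_cohorts(load_parameters())
#' round(fc$new_listings[c(1, 20)])  # 10367, 12763
#' @export
forecast_cohorts <- function(params, years = seq_len(params$clock$horizon_years),
                             with_meld_mode = "computed") {
  check_model_year(params, years)
  mc <- meld_categories()
  rows <- lapply(years, function(t) {
    cy <- calendar_year(params, t)
    shares <- evolve_meld_shares(params, cy)
    att <- waitlist_attrition(params, t, with_meld_mode)
    tot <- att[att$meld == "total", ]
    counts <- meld_category_counts(shares, tot$listed)
    tx <- tot$transplanted
    adm <- admission_outcomes(params, tx)
    operated <- tx  # retransplants re-enter the OR but are not new listings
    row <- data.frame(
      model_year = t, calendar_year = cy,
      new_listings = project_new_listings(params, t),
      with_meld = tot$listed,
      mean_age = mean_age_at_listing(params, cy),
      died_or_severe = tot$died_or_severe,
      not_transplanted = tot$not_transplanted,
      transplanted = tx,
      died_admission = adm$died,
      retransplanted = adm$retransplanted,
      survivors_10yr = survivors_at_year(params, operated, 10))
    for (cat in mc) {
      row[[paste0("share_", cat)]] <- shares[[cat]]
      row[[paste0("count_", cat)]] <- counts[[cat]]
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lt_cohort_forecast", "data.frame")
  out
}

#' Aggregate attrition over all simulated cohorts
#'
#' Pools the listing cohorts of the whole simulation period and reports the
#' fractions transplanted, dying or becoming too ill on the list, and not
#' proceeding to transplant, plus admission deaths and 10-year survivors as
#' fractions of operated patients.
#'
#' @param forecast Output of [forecast_cohorts()].
#' @return Named list of pooled counts and fractions.
#' @export
attrition_summary <- function(forecast) {
  listed <- sum(forecast$with_meld)
  tx <- sum(forecast$transplanted)
  list(
    listed = listed,
    transplanted = tx,
    frac_transplanted = tx / listed,
    frac_died_or_severe = sum(forecast$died_or_severe) / listed,
    frac_not_transplanted = sum(forecast$not_transplanted) / listed,
    frac_died_admission = sum(forecast$died_admission) / tx,
    frac_survive_10yr = sum(forecast$survivors_10yr) / tx)
}
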