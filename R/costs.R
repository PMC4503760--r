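#' Net escalation-and-discount factor
#'
#' Treatment prices escalate at an annual rate `r` while future costs are
#' discounted to present value at rate `d`; a Year-1 price carried to a
#' listing `years` later is multiplied by the single net factor
#' `((1 + r) / (1 + d))^years`.
#'
#' @param rates An `lt_parameters` object, or a list with numeric elements
#'   `r` (escalation) and `d` (discount).
#' @param years Elapsed years (>= 0, may be fractional).
#' @return The multiplier.
#' @examples
#' escalation_factor(list(r = 0.049, d = 0.03), 19)  # ~1.415
#' @export
escalation_factor <- function(rates, years) {
  if (any(years < 0)) stop("years must be >= 0", call. = FALSE)
  rd <- base_rates(rates)
  net_factor(rd$r, rd$d)^years
}

base_rates <- function(rates) {
  if (inherits(rates, "lt_parameters"))
    list(r = point_estimate(rates$rates$escalation),
         d = point_estimate(rates$rates$discount))
  else {
    stopifnot(is.numeric(rates$r), is.numeric(rates$d))
    if (rates$r <= -1 || rates$d <= -1)
      stop("rates must exceed -1", call. = FALSE)
    rates
  }
}

net_factor <- function(r, d) (1 + r) / (1 + d)

# geometric sum f^1 + f^2 + ... + f^n, stable at f == 1; vectorized over f
geom_sum <- function(f, n) {
  out <- ifelse(abs(f - 1) < 1e-12, n, f * (f^n - 1) / (f - 1))
  out
}

# geometric sum 1 + f + ... + f^(m-1) with fractional m: (f^m - 1)/(f - 1)
geom_sum_frac <- function(f, m) {
  ifelse(abs(f - 1) < 1e-12, m, (f^m - 1) / (f - 1))
}

DAYS_PER_MONTH <- 365 / 12

# ---- vectorized cost kernels ------------------------------------------------
# Each kernel accepts scalar or draw-vector inputs; the deterministic API
# calls them with base values so the Monte Carlo and base cases share one
# code path.

kernel_pre_lt_severe <- function(monthly, r, d, listing_year) {
  12 * monthly * net_factor(r, d)^(listing_year - 1)
}

kernel_pre_lt_wait <- function(monthly, last30, wait_days, ttc, r, d,
                               listing_year) {
  f <- net_factor(r, d)
  months <- wait_days * (1 + ttc)^(listing_year - 1) / DAYS_PER_MONTH
  g <- f^(1 / 12)
  accrual <- monthly * geom_sum_frac(g, months)
  (accrual + last30 * g^months) * f^(listing_year - 1)
}

kernel_admission <- function(procurement, physician, hospital, uplift,
                             r, d, listing_year) {
  (procurement + physician + hospital * (1 + uplift)) *
    net_factor(r, d)^(listing_year - 1)
}

kernel_post_lt <- function(post90, complication_addon, immuno_annual,
                           r, d, listing_year, horizon = 10) {
  f <- net_factor(r, d)
  (post90 + complication_addon + immuno_annual * geom_sum(f, horizon)) *
    f^(listing_year - 1)
}

# ---- deterministic per-phase costs ------------------------------------------

severe_category <- function(params, meld) {
  wt <- point_estimate(params$waiting_time_days[[meld_wait_band()[[meld]]]])
  wt <= 365
}

#' Discounted pre-transplant cost per to-be-transplanted patient
#'
#' Severely ill categories (waiting time under one year: MELD 20-29, 30-39,
#' >40) are costed as the 12 months preceding transplant at the category's
#' monthly spending. Less ill categories (MELD <9, 10-19) accrue monthly
#' spending over the full waiting duration (grown by the annual change in
#' time-to-transplant for later cohorts, each month's cost escalated at the
#' net rate from the listing date), plus the last-30-days cost adjustment
#' escalated to the transplant date. All values are expressed at the
#' listing-year price level via [escalation_factor()].
#'
#' @param params An `lt_parameters` object.
#' @param meld A MELD category label (see [meld_categories()]).
#' @param listing_year Model listing year, 1..horizon.
#' @return Discounted cost in USD.
#' @examples
#' p <- load_parameters()
#' pre_lt_cost(p, ">40", 1)  # 613020 = 12 x 51085
#' @export
pre_lt_cost <- function(params, meld, listing_year) {
  if (!meld %in% meld_categories())
    stop(sprintf("unknown MELD category '%s'", meld), call. = FALSE)
  check_model_year(params, listing_year)
  rd <- base_rates(params)
  monthly <- point_estimate(params$costs$monthly_pre_lt[[meld]])
  if (severe_category(params, meld)) {
    kernel_pre_lt_severe(monthly, rd$r, rd$d, listing_year)
  } else {
    kernel_pre_lt_wait(
      monthly,
      point_estimate(params$costs$last30d_adjustment),
      point_estimate(params$waiting_time_days[[meld_wait_band()[[meld]]]]),
      point_estimate(params$time_to_transplant_annual_change),
      rd$r, rd$d, listing_year)
  }
}

#' MELD-mix-weighted pre-transplant cost
#'
#' Weighted average of [pre_lt_cost()] across the five MELD categories,
#' weighted by the listing year's evolved MELD shares (or a supplied share
#' vector).
#'
#' @inheritParams pre_lt_cost
#' @param shares Optional named share vector summing to 1; defaults to
#'   [evolve_meld_shares()] at the listing calendar year.
#' @return Discounted cost in USD.
#' @export
weighted_pre_lt_cost <- function(params, listing_year, shares = NULL) {
  if (is.null(shares))
    shares <- evolve_meld_shares(params, calendar_year(params, listing_year))
  if (abs(sum(shares) - 1) > 1e-6)
    stop("shares must sum to 1", call. = FALSE)
  costs <- vapply(meld_categories(), pre_lt_cost, numeric(1),
                  params = params, listing_year = listing_year)
  sum(shares[meld_categories()] * costs)
}

#' Expected case-mix uplift on the hospital-admission component
#'
#' Dot product of the seven patient/donor characteristic frequencies with
#' their percentage cost uplifts (re-transplantation, ward and ICU status,
#' donor and recipient age 60+, alcoholic liver disease, Child-Pugh C).
#'
#' @param params An `lt_parameters` object.
#' @return The expected fractional uplift (about 0.367 at baseline).
#' @export
casemix_uplift <- function(params) {
  mult <- vapply(params$costs$casemix_multipliers, point_estimate, numeric(1))
  freq <- params$admission_casemix[names(mult)]
  sum(freq * mult)
}

#' Discounted transplant-admission cost per operated patient
#'
#' Organ procurement plus physician fees plus the hospital admission
#' component uplifted by the expected case mix ([casemix_uplift()]), priced
#' at the listing year via [escalation_factor()].
#'
#' @inheritParams pre_lt_cost
#' @return Discounted cost in USD.
#' @export
admission_cost <- function(params, listing_year) {
  check_model_year(params, listing_year)
  rd <- base_rates(params)
  kernel_admission(
    point_estimate(params$costs$organ_procurement),
    point_estimate(params$costs$physician_fees),
    point_estimate(params$costs$hospital_admission),
    casemix_uplift(params),
    rd$r, rd$d, listing_year)
}

#' Expected complication cost add-on in the first 90 post-operative days
#'
#' Sum over complications of frequency times added cost (the superficial
#' skin-infection row carries a negative added cost and reduces the total).
#'
#' @param params An `lt_parameters` object.
#' @return Expected added cost in USD (about $131,993 at baseline).
#' @export
complication_addon <- function(params) {
  sum(vapply(params$complications, function(cp)
    point_estimate(cp$frequency) * point_estimate(cp$added_cost), numeric(1)))
}

#' Discounted 10-year post-transplant cost per surviving patient
#'
#' First-90-days base cost plus the expected complication add-on plus ten
#' years of immunosuppression (each year escalated at the net rate), priced
#' at the listing year. The metric is conditional on 10-year survival, so
#' no survival weighting is applied.
#'
#' @inheritParams pre_lt_cost
#' @return Discounted cost in USD.
#' @export
post_lt_cost <- function(params, listing_year) {
  check_model_year(params, listing_year)
  rd <- base_rates(params)
  kernel_post_lt(
    point_estimate(params$costs$post90d_base),
    complication_addon(params),
    point_estimate(params$costs$immunosuppression_annual),
    rd$r, rd$d, listing_year)
}

#' Per-patient phase costs across listing years
#'
#' Computes, for each listing year, the discounted pre-transplant cost per
#' MELD category, the MELD-mix-weighted pre-transplant cost, the admission
#' and 10-year post-transplant costs, and their exact sum.
#'
#' @param params An `lt_parameters` object.
#' @param years Model listing years (default the full horizon).
#' @return A `data.frame` of class `lt_phase_costs`.
#' @examples
#' pc <- phase_costs(load_parameters(), years = c(1, 20))
#' round(pc$total)
#' @export
phase_costs <- function(params, years = seq_len(params$clock$horizon_years)) {
  check_model_year(params, years)
  mc <- meld_categories()
  rows <- lapply(years, function(t) {
    pre <- vapply(mc, pre_lt_cost, numeric(1), params = params,
                  listing_year = t)
    row <- data.frame(model_year = t,
                      calendar_year = calendar_year(params, t))
    for (cat in mc) row[[paste0("pre_lt_", cat)]] <- pre[[cat]]
    row$pre_lt_weighted <- weighted_pre_lt_cost(params, t)
    row$admission <- admission_cost(params, t)
    row$post_lt <- post_lt_cost(params, t)
    row$total <- row$pre_lt_weighted + row$admission + row$post_lt
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lt_phase_costs", "data.frame")
  out
}

#' National expenditure from per-patient cost and demand
#'
#' @param per_patient Total discounted per-patient cost (USD).
#' @param demand Forecast demand (patients).
#' @return Total USD.
#' @export
national_expenditure <- function(per_patient, demand) {
  if (any(per_patient < 0) || any(demand < 0))
    stop("per_patient and demand must be >= 0", call. = FALSE)
  per_patient * demand
}

#' National demand and expenditure forecast
#'
#' Potential total cost of liver transplantation per listing year, assuming
#' every newly listed patient completes all three treatment phases: the
#' per-patient total phase cost times forecast new listings.
#'
#' @param params An `lt_parameters` object.
#' @param years Model listing years.
#' @return A `data.frame`: `model_year`, `calendar_year`, `demand`,
#'   `per_patient`, `total_usd`.
#' @export
forecast_expenditure <- function(params,
                                 years = seq_len(params$clock$horizon_years)) {
  pc <- phase_costs(params, years)
  demand <- vapply(years, project_new_listings, numeric(1), params = params)
  data.frame(model_year = years,
             calendar_year = pc$calendar_year,
             demand = demand,
             per_patient = pc$total,
             total_usd = national_expenditure(pc$total, demand))
}
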