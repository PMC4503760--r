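#' MELD score categories used throughout the model
#'
#' The waitlist population is stratified into five MELD (Model for End-Stage
#' Liver Disease) categories, ordered from least to most severe.
#'
#' @return Character vector of the five category labels.
#' @export
meld_categories <- function() c("<9", "10-19", "20-29", "30-39", ">40")

#' @rdname meld_categories
#' @export
age_groups <- function() c("18-34", "35-49", "50-64", ">65")

# Mapping from MELD category to the waiting-time band whose median waiting
# time it uses. The published waiting-time bands (<10, 11-18, 19-24, >=25,
# status 1) straddle the MELD cost categories; this monotone mapping uses
# each band once, with status 1 available as an override for MELD >40.
meld_wait_band <- function(status1_for_top = FALSE) {
  m <- c("<9" = "meld_lt10", "10-19" = "meld_11_18", "20-29" = "meld_19_24",
         "30-39" = "meld_ge25", ">40" = "meld_ge25")
  if (status1_for_top) m[">40"] <- "status1"
  m
}

#' Baseline parameter table: 2012 U.S. liver-transplant registry inputs
#'
#' Constructs the packaged baseline parameter table: the 2012 OPTN/SRTR
#' cohort size and composition, per-MELD share trajectories (Wiesner et al.
#' waitlist mix), waitlist mortality/severe-illness schedules, waiting
#' times, admission case mix (Showstack et al.), the 10-year
#' post-transplant survival schedule, phase costs in 2014 USD (Axelrod et
#' al., Milliman, Ammori et al., CPMC) and the cost escalation/discount
#' rates, each with its uncertainty distribution. This is the single source
#' of truth consumed by the epidemiology, cost and uncertainty modules.
#'
#' @return A validated object of class `lt_parameters`.
#' @seealso [load_parameters()], [parameter_registry()]
#' @export
lt_baseline_parameters <- function() {
  tri <- function(base, low, high) dist_spec("triangular", base, low, high)
  fx  <- function(base) dist_spec("fixed", base)
  vr  <- function(base) dist_spec("variable", base)
  mc  <- meld_categories()

  p <- list(
    clock = list(base_data_year = 2012, first_model_year = 2014,
                 horizon_years = 20),
    cohort_2012 = list(
      new_listings = 10143,
      share_no_meld = 0.094,
      share_inactive = 0.129,
      age_shares = c("18-34" = 0.042, "35-49" = 0.147,
                     "50-64" = 0.627, ">65" = 0.184)),
    growth = list(
      listings_annual_change = tri(0.011, -0.014, 0.079),
      no_meld_annual_change = tri(0.076, 0.049, 0.094),
      inactive_annual_change = tri(-0.005, -0.068, 0.051),
      meld_share_annual_change = list(
        "<9" = vr(-0.027), "10-19" = vr(-0.003), "20-29" = vr(0.022),
        "30-39" = vr(0.034), ">40" = vr(0.045)),
      # registry-wide share-change rows (MELD 6-14 / 15-34 / >35); used as
      # spread analogues when resolving the "variable" rows above
      share_change_analogues = list(
        "6-14" = tri(-0.027, -0.04, -0.006),
        "15-34" = tri(0.022, 0.002, 0.046),
        ">35" = tri(0.045, -0.021, 0.205)),
      age_group_annual_change = c("18-34" = -0.022, "35-49" = -0.068,
                                  "50-64" = 0.025, ">65" = 0.047)),
    meld_baseline_shares = c("<9" = 0.036, "10-19" = 0.524, "20-29" = 0.319,
                             "30-39" = 0.086, ">40" = 0.035),
    # cumulative probability of death or severe illness on the waitlist, by
    # time since listing (years); 3 months = 0.25 yr
    waitlist_mortality = list(
      "<9" = list(years = c(0.25, 1:10),
                  prob = c(0.029, 0.051, 0.062, 0.069, 0.076, 0.084,
                           0.092, 0.102, 0.112, 0.124, 0.137)),
      "10-19" = list(years = c(0.25, 1:5),
                     prob = c(0.077, 0.135, 0.165, 0.182, 0.201, 0.222)),
      "20-29" = list(years = 0.25, prob = 0.235),
      "30-39" = list(years = 0.25, prob = 0.602),
      ">40" = list(years = 0.25, prob = 0.793)),
    waiting_time_days = list(
      meld_lt10 = tri(1776, 1538, 2125),
      meld_11_18 = tri(639, 592, 698),
      meld_19_24 = tri(106, 93, 116),
      meld_ge25 = tri(20, 18, 22),
      status1 = tri(6, 5, 7)),
    time_to_transplant_annual_change = tri(0.017, -0.017, 0.051),
    pct_not_transplanted = dist_spec("uniform", 0.213, 0.204, 0.222),
    admission_casemix = c(retransplant = 0.03, died = 0.06,
                          hosp_not_icu = 0.24, icu = 0.09, donor_60plus = 0.07,
                          recipient_60plus = 0.19, ald = 0.20,
                          child_pugh_c = 0.35),
    survival = c(0.90, 0.85, 0.79, 0.76, 0.74, 0.71, 0.69, 0.67, 0.65, 0.63),
    complications = list(
      acute_cellular_rejection = list(frequency = tri(0.11, 0.11, 0.60),
                                      added_cost = tri(21317, 10659, 31976)),
      biliary_complications = list(frequency = tri(0.33, 0.10, 0.33),
                                   added_cost = tri(40457, 20229, 60686)),
      hepatic_artery_thrombosis = list(frequency = tri(0.03, 0.03, 0.12),
                                       added_cost = tri(83085, 41543, 124628)),
      superficial_skin_infection = list(frequency = tri(0.16, 0.12, 0.20),
                                        added_cost = tri(-2883, -4325, -1442)),
      pneumonia = list(frequency = tri(0.16, 0.12, 0.20),
                       added_cost = tri(59122, 29561, 88683)),
      bloodstream_infection = list(frequency = tri(0.16, 0.12, 0.20),
                                   added_cost = tri(75616, 37808, 113424)),
      peritonitis = list(frequency = tri(0.17, 0.13, 0.21),
                         added_cost = tri(88187, 44094, 132281)),
      urinary_tract_infection = list(frequency = tri(0.17, 0.13, 0.21),
                                     added_cost = tri(50609, 25305, 75914)),
      c_difficile_colitis = list(frequency = tri(0.10, 0.08, 0.13),
                                 added_cost = tri(33939, 16970, 50909)),
      other_infections = list(frequency = tri(0.55, 0.41, 0.69),
                              added_cost = tri(50118, 25059, 75177)),
      venous_thromboembolism = list(frequency = tri(0.07, 0.05, 0.09),
                                    added_cost = tri(39148, 19574, 58722)),
      reoperation = list(frequency = tri(0.23, 0.17, 0.29),
                         added_cost = tri(82231, 41116, 123347)),
      primary_non_function = list(frequency = tri(0.03, 0.02, 0.04),
                                  added_cost = tri(78812, 39406, 118218)),
      hepatic_vein_stenosis = list(frequency = tri(0.07, 0.05, 0.09),
                                   added_cost = tri(54370, 27185, 81555)),
      acute_renal_failure = list(frequency = tri(0.17, 0.13, 0.21),
                                 added_cost = tri(60766, 30383, 91149))),
    costs = list(
      monthly_pre_lt = list(
        "<9" = tri(347, 35, 658),
        "10-19" = tri(1578, 1097, 2058),
        "20-29" = tri(19602, 13060, 26143),
        "30-39" = tri(31644, 20417, 42871),
        ">40" = vr(51085)),
      last30d_adjustment = tri(26469, 13235, 39704),
      organ_procurement = tri(73989, 36995, 110984),
      hospital_admission = fx(330242),
      admission_component_shares = list(
        immunosuppressive = tri(0.081, 0.041, 0.121),
        anti_infective = tri(0.050, 0.025, 0.075),
        other_medications = tri(0.011, 0.005, 0.016),
        blood_products = tri(0.120, 0.060, 0.180),
        operating_room = tri(0.088, 0.044, 0.132),
        respiratory_services = tri(0.041, 0.021, 0.062),
        special_care = tri(0.140, 0.070, 0.210),
        other_room_and_care = tri(0.162, 0.081, 0.243),
        immunosuppressive_monitoring = tri(0.010, 0.005, 0.014),
        other_laboratory = tri(0.145, 0.073, 0.218),
        chest_radiography = tri(0.011, 0.006, 0.017),
        ultrasound = tri(0.006, 0.003, 0.009),
        other_imaging = tri(0.020, 0.010, 0.030),
        pathology = tri(0.007, 0.004, 0.011),
        material_services = tri(0.089, 0.045, 0.134),
        miscellaneous = tri(0.018, 0.009, 0.027)),
      physician_fees = tri(48562, 24281, 72843),
      casemix_multipliers = list(
        retransplant = tri(1.54, 0.77, 2.31),
        hosp_not_icu = tri(0.15, 0.08, 0.23),
        icu = tri(0.42, 0.21, 0.63),
        donor_60plus = tri(0.28, 0.14, 0.42),
        recipient_60plus = tri(0.17, 0.09, 0.26),
        ald = tri(0.26, 0.13, 0.39),
        child_pugh_c = tri(0.41, 0.21, 0.62)),
      post90d_base = tri(139746, 50610, 228882),
      immunosuppression_annual = fx(36708)),
    rates = list(
      escalation = tri(0.049, 0.0258, 0.0604),
      discount = tri(0.03, 0.015, 0.045)),
    # new with-MELD listing totals printed for specific calendar years;
    # used by the anchored projection mode
    anchors = list(with_meld = c("2014" = 7934, "2020" = 8006,
                                 "2033" = 7600)))
  names(p$survival) <- as.character(1:10)
  class(p) <- "lt_parameters"
  validate_lt_parameters(p)
}

#' @export
print.lt_parameters <- function(x, ...) {
  cat("<lt_parameters>\n")
  cat(sprintf("  base data year %d; model years %d-%d (Year 1-%d)\n",
              x$clock$base_data_year, x$clock$first_model_year,
              x$clock$first_model_year + x$clock$horizon_years - 1,
              x$clock$horizon_years))
  cat(sprintf("  2012 cohort: %s new listings (%.1f%% no MELD, %.1f%% inactive)\n",
              format(x$cohort_2012$new_listings, big.mark = ","),
              100 * x$cohort_2012$share_no_meld,
              100 * x$cohort_2012$share_inactive))
  cat(sprintf("  %d parameters in registry\n", nrow(parameter_registry(x))))
  invisible(x)
}

#' Validate a parameter table
#'
#' Checks every structural invariant: distribution ranges, fractions in
#' \[0, 1\], MELD baseline shares summing to 1 (within 0.001), a
#' non-increasing survival schedule, non-decreasing cumulative waitlist
#' mortality schedules, and non-negative monetary bases (complication added
#' costs excepted: prophylactic line items may be negative).
#'
#' @param params An `lt_parameters` object.
#' @return `params`, invisibly restored to full class, or an error.
#' @export
validate_lt_parameters <- function(params) {
  fail <- function(...) stop(sprintf(...), call. = FALSE)
  mc <- meld_categories()

  frac_ok <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      fail("domain error: %s must be fractions in [0, 1]", what)
  }
  frac_ok(params$cohort_2012$share_no_meld, "share_no_meld")
  frac_ok(params$cohort_2012$share_inactive, "share_inactive")
  frac_ok(params$cohort_2012$age_shares, "age_shares")
  frac_ok(params$meld_baseline_shares, "meld_baseline_shares")
  frac_ok(params$admission_casemix, "admission_casemix")
  frac_ok(params$survival, "survival")

  if (abs(sum(params$meld_baseline_shares) - 1) > 0.001)
    fail("meld_baseline_shares must sum to 1 within 0.001 (got %.4f)",
         sum(params$meld_baseline_shares))
  if (!identical(names(params$meld_baseline_shares), mc))
    fail("meld_baseline_shares must be named by the five MELD categories")

  s <- params$survival
  if (length(s) != 10 || any(s <= 0) || any(diff(s) > 0))
    fail("survival must be 10 values in (0, 1], non-increasing")

  for (cat in mc) {
    sched <- params$waitlist_mortality[[cat]]
    if (is.null(sched)) fail("missing waitlist mortality schedule for MELD %s", cat)
    if (any(diff(sched$prob) < 0) || any(diff(sched$years) <= 0))
      fail("waitlist mortality schedule for MELD %s must be non-decreasing", cat)
    frac_ok(sched$prob, sprintf("waitlist mortality (MELD %s)", cat))
  }

  for (nm in names(params$costs)) {
    item <- params$costs[[nm]]
    specs <- if (is_dist_spec(item)) list(item) else item
    for (sp in specs) {
      validate_dist_spec(sp)
      if (nm %in% c("monthly_pre_lt", "last30d_adjustment",
                    "organ_procurement", "hospital_admission",
                    "physician_fees", "post90d_base",
                    "immunosuppression_annual") && sp$base < 0)
        fail("domain error: monetary base for %s must be >= 0", nm)
    }
  }
  for (cp in params$complications) {
    validate_dist_spec(cp$frequency)
    validate_dist_spec(cp$added_cost)
    frac_ok(cp$frequency$base, "complication frequency")
  }
  for (sp in params$waiting_time_days) validate_dist_spec(sp)
  validate_dist_spec(params$rates$escalation)
  validate_dist_spec(params$rates$discount)
  if (params$rates$escalation$base <= -1 || params$rates$discount$base <= -1)
    fail("escalation and discount rates must exceed -1")
  if (params$clock$horizon_years < 1 ||
      params$clock$first_model_year <= params$clock$base_data_year)
    fail("clock: need horizon_years >= 1 and first_model_year > base_data_year")
  invisible(params)
}

#' Resolve "variable" distribution rows to triangular distributions
#'
#' Inputs whose published uncertainty bounds are marked "variable" (the
#' per-MELD share annual changes and the MELD >40 monthly spending) are
#' given triangular bounds with the same relative low/high spread as their
#' nearest fully specified analogue: MELD 30-39 monthly spending for the
#' MELD >40 spending row, and the nearest (by base value) of the
#' registry-wide share-change rows for the share-change rows. Deterministic
#' runs are unaffected (the base is unchanged); only Monte Carlo sampling
#' uses the resolved bounds.
#'
#' @param params An `lt_parameters` object.
#' @return The same object with every `"variable"` spec replaced by a
#'   `"triangular"` spec.
#' @export
resolve_variable <- function(params) {
  rel_tri <- function(base, analogue) {
    lo <- base * analogue$low / analogue$base
    hi <- base * analogue$high / analogue$base
    dist_spec("triangular", base, min(lo, base), max(hi, base))
  }
  sp40 <- params$costs$monthly_pre_lt[[">40"]]
  if (sp40$kind == "variable")
    params$costs$monthly_pre_lt[[">40"]] <-
      rel_tri(sp40$base, params$costs$monthly_pre_lt[["30-39"]])
  analogues <- params$growth$share_change_analogues
  abase <- vapply(analogues, point_estimate, numeric(1))
  for (cat in names(params$growth$meld_share_annual_change)) {
    sp <- params$growth$meld_share_annual_change[[cat]]
    if (sp$kind == "variable") {
      nearest <- analogues[[which.min(abs(abase - sp$base))]]
      params$growth$meld_share_annual_change[[cat]] <- rel_tri(sp$base, nearest)
    }
  }
  params
}

# ---- configuration (YAML/JSON) serialization --------------------------------

as_plain <- function(x) {
  if (is_dist_spec(x)) {
    out <- list(kind = x$kind, base = x$base)
    if (!is.null(x$low)) out$low <- x$low
    if (!is.null(x$high)) out$high <- x$high
    out
  } else if (is.list(x)) {
    lapply(x, as_plain)
  } else if (is.numeric(x) && !is.null(names(x))) {
    as.list(x)
  } else x
}

#' Serialize a parameter table to a plain configuration list
#'
#' The inverse of [load_parameters()]: produces a nested list (suitable for
#' `yaml::write_yaml()` or `jsonlite::write_json()`) mirroring the
#' parameter-table structure, with each distribution spec flattened to
#' `kind`/`base`/`low`/`high` fields.
#'
#' @param params An `lt_parameters` object.
#' @return A nested plain list.
#' @export
as_config_list <- function(params) {
  out <- as_plain(unclass(params))
  out
}

#' Write a parameter table to a YAML or JSON configuration file
#'
#' @param params An `lt_parameters` object.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  cfg <- as_config_list(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 12)
  }
  invisible(path)
}

num_vec <- function(x, path) {
  v <- unlist(x)
  if (!is.numeric(v))
    stop(sprintf("validation error at '%s': expected numeric values", path),
         call. = FALSE)
  v
}

spec_from_cfg <- function(cfg, path) {
  if (is_dist_spec(cfg)) return(cfg)
  known <- c("kind", "base", "low", "high")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("unknown key(s) at '%s': %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  if (is.null(cfg$kind) || is.null(cfg$base))
    stop(sprintf("missing key at '%s': distribution specs need 'kind' and 'base'",
                 path), call. = FALSE)
  dist_spec(cfg$kind, cfg$base, cfg$low, cfg$high)
}

build_from_template <- function(template, cfg, path = "") {
  if (is_dist_spec(template)) return(spec_from_cfg(cfg, path))
  if (is.list(template)) {
    extra <- setdiff(names(cfg), names(template))
    if (length(extra))
      stop(sprintf("unknown key(s) at '%s': %s",
                   if (nzchar(path)) path else "<root>",
                   paste(extra, collapse = ", ")), call. = FALSE)
    missing <- setdiff(names(template), names(cfg))
    if (length(missing))
      stop(sprintf("missing key(s) at '%s': %s",
                   if (nzchar(path)) path else "<root>",
                   paste(missing, collapse = ", ")), call. = FALSE)
    out <- lapply(names(template), function(nm)
      build_from_template(template[[nm]], cfg[[nm]],
                          if (nzchar(path)) paste(path, nm, sep = ".") else nm))
    names(out) <- names(template)
    return(out)
  }
  v <- num_vec(cfg, path)
  if (length(v) != length(template) ||
      (!is.null(names(template)) && !setequal(names(v), names(template))))
    stop(sprintf("validation error at '%s': expected %d value(s) named %s",
                 path, length(template),
                 paste(names(template), collapse = ", ")), call. = FALSE)
  if (!is.null(names(template))) v <- v[names(template)]
  v
}

#' Load and validate a parameter table
#'
#' Accepts the packaged baseline by name (`"table1_baseline"`), a path to a
#' YAML or JSON configuration document mirroring the parameter-table
#' structure, or such a document already parsed into a list. The document
#' must supply every required key; unknown keys are an error (silent typos
#' corrupt forecasts), as are range violations (`low > high`) and negative
#' fractions.
#'
#' @param source `"table1_baseline"`, a file path, or a nested list.
#' @return A validated `lt_parameters` object.
#' @examples
#' p <- load_parameters("table1_baseline")
#' p$cohort_2012$new_listings  # 10143
#' @export
load_parameters <- function(source = "table1_baseline") {
  if (inherits(source, "lt_parameters")) return(validate_lt_parameters(source))
  if (is.character(source) && length(source) == 1) {
    if (source == "table1_baseline") return(lt_baseline_parameters())
    if (!file.exists(source))
      stop(sprintf("config not found: '%s' (use 'table1_baseline' for the packaged baseline)",
                   source), call. = FALSE)
    cfg <- if (grepl("\\.json$", source, ignore.case = TRUE))
      jsonlite::fromJSON(source, simplifyVector = FALSE)
    else yaml::read_yaml(source)
  } else if (is.list(source)) {
    cfg <- source
  } else stop("load_parameters: source must be a name, path or list",
              call. = FALSE)
  template <- unclass(lt_baseline_parameters())
  p <- build_from_template(template, cfg)
  class(p) <- "lt_parameters"
  validate_lt_parameters(p)
}

# ---- registry export --------------------------------------------------------

registry_units <- function(name) {
  if (grepl("waiting_time|_days", name)) return("days")
  if (grepl("new_listings", name)) return("patients")
  if (grepl("annual_change|escalation|discount", name)) return("fraction/yr")
  if (grepl("monthly_pre_lt", name)) return("USD/month")
  if (grepl("immunosuppression_annual", name)) return("USD/yr")
  if (grepl("added_cost|last30d|procurement|hospital_admission|physician_fees|post90d",
            name)) return("USD")
  if (grepl("casemix_multipliers", name)) return("fractional uplift")
  "fraction"
}

registry_source <- function(name) {
  if (grepl("^cohort_2012|^growth\\.(listings|no_meld|inactive|age)", name))
    return("OPTN/SRTR registry (2012)")
  if (grepl("^meld_baseline_shares|^growth\\.meld|^growth\\.share_change", name))
    return("OPTN/SRTR registry; Wiesner et al.")
  if (grepl("^waitlist_mortality", name)) return("Wiesner et al.; OPTN/SRTR")
  if (grepl("^waiting_time", name)) return("OPTN registry")
  if (grepl("^admission_casemix|casemix_multipliers|admission_component_shares",
            name)) return("Showstack et al.")
  if (grepl("^survival", name)) return("Washburn et al.; Milliman; Longworth et al.")
  if (grepl("^complications|post90d", name)) return("Ammori et al.")
  if (grepl("monthly_pre_lt", name)) return("Axelrod et al.")
  if (grepl("last30d|procurement|hospital_admission|physician_fees", name))
    return("Milliman research report")
  if (grepl("immunosuppression_annual", name)) return("CPMC")
  if (grepl("^rates\\.escalation", name)) return("WHO global health expenditure")
  if (grepl("^rates\\.discount", name)) return("Yen et al.; Torgerson & Raftery")
  if (grepl("^pct_not_transplanted|time_to_transplant", name))
    return("OPTN/SRTR registry")
  "model convention"
}

flatten_registry <- function(x, prefix = "") {
  rows <- list()
  add <- function(name, kind, base, low, high) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, base = base,
      low = ifelse(is.null(low), NA_real_, low),
      high = ifelse(is.null(high), NA_real_, high),
      stringsAsFactors = FALSE)
  }
  walk <- function(x, prefix) {
    if (is_dist_spec(x)) {
      add(prefix, x$kind, x$base, x$low, x$high)
    } else if (is.list(x)) {
      for (nm in names(x))
        walk(x[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm)
    } else if (is.numeric(x)) {
      if (length(x) == 1 && is.null(names(x))) add(prefix, "fixed", x, NULL, NULL)
      else for (i in seq_along(x))
        add(paste(prefix, if (is.null(names(x))) i else names(x)[i], sep = "."),
            "fixed", x[[i]], NULL, NULL)
    }
  }
  walk(x, prefix)
  do.call(rbind, rows)
}

#' Export the full parameter registry as a flat table
#'
#' One row per scalar parameter: dotted name, distribution kind, base, low,
#' high, units and data source. Useful as a CSV audit trail of every input
#' driving a forecast.
#'
#' @param params An `lt_parameters` object.
#' @param path Optional CSV path; if supplied the table is also written.
#' @return A `data.frame` (invisibly if `path` is given).
#' @export
parameter_registry <- function(params, path = NULL) {
  reg <- flatten_registry(unclass(params))
  reg <- reg[!grepl("^anchors|^clock", reg$name), ]
  reg$units <- vapply(reg$name, registry_units, character(1))
  reg$source <- vapply(reg$name, registry_source, character(1))
  rownames(reg) <- NULL
  if (!is.null(path)) {
    utils::write.csv(reg, path, row.names = FALSE)
    return(invisible(reg))
  }
  reg
}
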