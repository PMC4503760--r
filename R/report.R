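#' Run manifest written alongside every report
#'
#' Records the command, configuration source, seed, draw count, output
#' directory, package version and timestamp so every output set is fully
#' reproducible.
#'
#' @param command Command name.
#' @param config Config path or baseline name.
#' @param out_dir Output directory.
#' @param seed,n_draws Optional Monte Carlo settings.
#' @return Path of the written manifest JSON, invisibly.
#' @keywords internal
write_manifest <- function(command, config, out_dir, seed = NULL,
                           n_draws = NULL) {
  manifest <- list(
    command = command, config = config, seed = seed, n_draws = n_draws,
    out_dir = out_dir,
    package_version = as.character(utils::packageVersion("ltecon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       path, auto_unbox = TRUE)
  invisible(path)
}

resolve_config <- function(config) {
  if (inherits(config, "lt_parameters")) return(config)
  load_parameters(config)
}

config_label <- function(config) {
  if (is.character(config)) config else "<in-memory parameters>"
}

write_outputs <- function(df, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, file.path(out_dir, paste0(stem, ".json")),
                       dataframe = "rows", digits = NA)
  invisible(csv)
}

#' Cohort forecast command
#'
#' Runs the epidemiology model end-to-end and writes the per-year cohort
#' table (CSV + JSON) with a run manifest. Monetary/count columns are
#' written unrounded; round at display time (nearest patient).
#'
#' @param config `"table1_baseline"`, a config path, or an `lt_parameters`
#'   object.
#' @param years Model year indices; must be non-empty.
#' @param out_dir Output directory.
#' @param with_meld_mode Passed to [forecast_cohorts()].
#' @return The forecast data frame, invisibly.
#' @export
cmd_forecast <- function(config = "table1_baseline", years = 1:20,
                         out_dir = ".", with_meld_mode = "computed") {
  if (!length(years)) stop("usage error: empty forecast horizon", call. = FALSE)
  params <- resolve_config(config)
  fc <- forecast_cohorts(params, years, with_meld_mode)
  write_outputs(fc, out_dir, "cohort_forecast")
  write_manifest("forecast", config_label(config), out_dir)
  invisible(fc)
}

#' Phase-cost forecast command
#'
#' Writes the per-listing-year phase-cost table (pre-transplant per MELD
#' and weighted, admission, post-transplant, total) plus national demand
#' and expenditure.
#'
#' @inheritParams cmd_forecast
#' @return The phase-cost data frame (with national totals), invisibly.
#' @export
cmd_costs <- function(config = "table1_baseline", years = 1:20,
                      out_dir = ".") {
  if (!length(years)) stop("usage error: empty forecast horizon", call. = FALSE)
  params <- resolve_config(config)
  pc <- phase_costs(params, years)
  nat <- forecast_expenditure(params, years)
  pc$demand <- nat$demand
  pc$national_total <- nat$total_usd
  write_outputs(pc, out_dir, "phase_costs")
  write_manifest("costs", config_label(config), out_dir)
  invisible(pc)
}

#' Probabilistic sensitivity analysis command
#'
#' Runs the Monte Carlo uncertainty analysis on the Year-20 cost metrics
#' and writes an uncertainty-shaped table (metric, base, certainty, mean,
#' median, p10, p90) and a sensitivity-shaped table (metric, input, index),
#' in CSV and JSON.
#'
#' @inheritParams cmd_forecast
#' @param n_draws Monte Carlo iterations.
#' @param seed Integer seed.
#' @return List with `uncertainty` and `sensitivity` data frames, invisibly.
#' @export
cmd_psa <- function(config = "table1_baseline", n_draws = 30000,
                    seed = 20140101, out_dir = ".") {
  params <- resolve_config(config)
  mc <- run_monte_carlo(params, n_draws = n_draws, seed = seed,
                        keep_draws = TRUE)
  write_outputs(mc$summary, out_dir, "uncertainty")
  if (n_draws >= 100) {
    sens <- sensitivity_report(mc)
    sens_df <- do.call(rbind, lapply(names(sens), function(m)
      cbind(metric = m, sens[[m]])))
  } else {
    warning("too few draws for sensitivity indices; writing empty table",
            call. = FALSE)
    sens_df <- data.frame(metric = character(), input = character(),
                          rho = numeric(), index = numeric(),
                          rank = integer())
  }
  write_outputs(sens_df, out_dir, "sensitivity")
  write_manifest("psa", config_label(config), out_dir, seed = seed,
                 n_draws = n_draws)
  invisible(list(uncertainty = mc$summary, sensitivity = sens_df))
}

#' Bioengineered-liver ledger command
#'
#' Writes the catalog-price cost ledger for building `fraction` of a liver
#' from a price list (CSV path or list of [cell_line()] objects).
#'
#' @param pricelist Price-list CSV path or list of cell lines (default the
#'   packaged catalog baseline).
#' @param fraction Fraction of a whole liver in (0, 1].
#' @param reprogramming Reprogramming cost (USD).
#' @param out_dir Output directory.
#' @return The `liver_cost_breakdown`, invisibly.
#' @export
cmd_bioliver <- function(pricelist = NULL, fraction = 1,
                         reprogramming = 15000, out_dir = ".") {
  if (fraction <= 0 || fraction > 1)
    stop("usage error: --fraction must be in (0, 1]", call. = FALSE)
  lines <- if (is.null(pricelist)) baseline_cell_lines()
    else if (is.character(pricelist)) read_price_list(pricelist)
    else pricelist
  bc <- build_cost(lines, fraction = fraction, reprogramming = reprogramming)
  ledger <- rbind(
    data.frame(line = "reprogramming", cells = NA_real_, vials = NA_real_,
               cost = bc$reprogramming),
    bc$lines,
    data.frame(line = "total", cells = NA_real_, vials = NA_real_,
               cost = bc$total))
  write_outputs(ledger, out_dir, "bioliver_ledger")
  write_manifest("bioliver", config_label(
    if (is.character(pricelist)) pricelist else "catalog_baseline"), out_dir)
  invisible(bc)
}

#' Run every report
#'
#' Convenience wrapper running [cmd_forecast()], [cmd_costs()], [cmd_psa()]
#' and [cmd_bioliver()] into one output directory.
#'
#' @inheritParams cmd_psa
#' @inheritParams cmd_bioliver
#' @return `out_dir`, invisibly.
#' @export
cmd_report_all <- function(config = "table1_baseline", n_draws = 30000,
                           seed = 20140101, fraction = 1, out_dir = ".") {
  cmd_forecast(config, out_dir = out_dir)
  cmd_costs(config, out_dir = out_dir)
  cmd_psa(config, n_draws = n_draws, seed = seed, out_dir = out_dir)
  cmd_bioliver(fraction = fraction, out_dir = out_dir)
  invisible(out_dir)
}
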