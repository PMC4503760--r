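#' Cost metrics available for uncertainty analysis
#'
#' The seven Year-20 per-patient cost metrics assessed by the probabilistic
#' sensitivity analysis: the discounted pre-transplant cost for each MELD
#' category, the transplant-admission cost, and the 10-year post-transplant
#' cost.
#'
#' @return Character vector of metric names.
#' @export
mc_metrics <- function() {
  c(paste0("pre_lt_", meld_categories()), "admission", "post_lt")
}

# Draw all varied inputs for one metric and return the input matrix plus an
# evaluator mapping those draws to the metric value. Epidemiology growth
# parameters are held at base: these metrics are per-patient costs, not
# national totals.
sample_metric <- function(params, metric, n, listing_year) {
  draw <- function(spec) sample_dist(spec, n)
  inputs <- list(
    annual_cost_increase = draw(params$rates$escalation),
    cost_discount_rate = draw(params$rates$discount))
  r <- inputs$annual_cost_increase
  d <- inputs$cost_discount_rate

  if (grepl("^pre_lt_", metric)) {
    cat <- sub("^pre_lt_", "", metric)
    if (!cat %in% meld_categories())
      stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
    monthly <- draw(params$costs$monthly_pre_lt[[cat]])
    inputs[[paste0("monthly_pre_lt_", cat)]] <- monthly
    if (severe_category(params, cat)) {
      out <- kernel_pre_lt_severe(monthly, r, d, listing_year)
    } else {
      last30 <- draw(params$costs$last30d_adjustment)
      wt <- draw(params$waiting_time_days[[meld_wait_band()[[cat]]]])
      ttc <- draw(params$time_to_transplant_annual_change)
      inputs$last30d_adjustment <- last30
      inputs$waiting_time_days <- wt
      inputs$time_to_transplant_change <- ttc
      out <- kernel_pre_lt_wait(monthly, last30, wt, ttc, r, d, listing_year)
    }
  } else if (metric == "admission") {
    inputs$organ_procurement <- draw(params$costs$organ_procurement)
    inputs$physician_fees <- draw(params$costs$physician_fees)
    shares <- params$costs$admission_component_shares
    share_draws <- matrix(0, n, length(shares),
                          dimnames = list(NULL, names(shares)))
    for (nm in names(shares)) {
      share_draws[, nm] <- draw(shares[[nm]])
      inputs[[paste0("component_share_", nm)]] <- share_draws[, nm]
    }
    base_share_sum <- sum(vapply(shares, point_estimate, numeric(1)))
    hospital <- point_estimate(params$costs$hospital_admission) *
      rowSums(share_draws) / base_share_sum
    mult <- params$costs$casemix_multipliers
    uplift_terms <- matrix(0, n, length(mult))
    for (j in seq_along(mult)) {
      nm <- names(mult)[j]
      m <- draw(mult[[nm]])
      inputs[[paste0("casemix_multiplier_", nm)]] <- m
      uplift_terms[, j] <- params$admission_casemix[[nm]] * m
    }
    uplift <- rowSums(uplift_terms)
    out <- kernel_admission(inputs$organ_procurement, inputs$physician_fees,
                            hospital, uplift, r, d, listing_year)
  } else if (metric == "post_lt") {
    inputs$post90d_base <- draw(params$costs$post90d_base)
    addon_terms <- matrix(0, n, length(params$complications))
    for (j in seq_along(params$complications)) {
      nm <- names(params$complications)[j]
      fq <- draw(params$complications[[nm]]$frequency)
      cs <- draw(params$complications[[nm]]$added_cost)
      inputs[[paste0("frequency_", nm)]] <- fq
      inputs[[paste0("added_cost_", nm)]] <- cs
      addon_terms[, j] <- fq * cs
    }
    addon <- rowSums(addon_terms)
    out <- kernel_post_lt(inputs$post90d_base, addon,
                          point_estimate(params$costs$immunosuppression_annual),
                          r, d, listing_year)
  } else stop(sprintf("unknown metric '%s'", metric), call. = FALSE)

  if (anyNA(out) || any(!is.finite(out))) {
    bad <- which(!is.finite(out))[1]
    stop(sprintf("metric '%s' evaluation failed at draw %d", metric, bad),
         call. = FALSE)
  }
  list(inputs = do.call(cbind, inputs), output = out)
}

metric_base_case <- function(params, metric, listing_year) {
  if (grepl("^pre_lt_", metric))
    pre_lt_cost(params, sub("^pre_lt_", "", metric), listing_year)
  else if (metric == "admission") admission_cost(params, listing_year)
  else post_lt_cost(params, listing_year)
}

#' Monte Carlo uncertainty analysis of the cost metrics
#'
#' Samples every uncertain input of each cost metric from its distribution
#' (triangular by inverse CDF with mode at base; uniform on its bounds;
#' "variable" rows resolved via [resolve_variable()]; fixed inputs held at
#' base), evaluates the metric on each draw, and summarizes: the certainty
#' of reaching or exceeding the deterministic base case, the mean, median
#' and 10th/90th percentiles. Inputs are sampled independently.
#'
#' @param params An `lt_parameters` object.
#' @param metrics Metric names (see [mc_metrics()]).
#' @param n_draws Number of Monte Carlo iterations (default 30,000).
#' @param seed Integer seed; identical seed and `n_draws` give bit-identical
#'   results.
#' @param listing_year Listing year at which metrics are evaluated
#'   (default 20, the last simulated cohort).
#' @param keep_draws Retain the sampled input matrix and outputs per metric
#'   (required for [sensitivity_indices()] via [sensitivity_report()]).
#' @return An `lt_monte_carlo` object: `summary` data frame (metric, base
#'   case, certainty, mean, median, p10, p90), plus draws if requested.
#' @examples
#' mc <- run_monte_carlo(load_parameters(), metrics = "admission",
#'                       n_draws = 2000, seed = 1)
#' mc$summary
#' @export
run_monte_carlo <- function(params, metrics = mc_metrics(), n_draws = 30000,
                            seed = 20140101, listing_year = NULL,
                            keep_draws = FALSE) {
  stopifnot(n_draws >= 1)
  if (is.null(listing_year)) listing_year <- params$clock$horizon_years
  check_model_year(params, listing_year)
  if (n_draws < 30)
    warning("degenerate summary: fewer than 30 draws", call. = FALSE)
  sampled <- resolve_variable(params)
  set.seed(seed)
  draws <- list()
  rows <- lapply(metrics, function(m) {
    s <- sample_metric(sampled, m, n_draws, listing_year)
    if (keep_draws) draws[[m]] <<- s
    base <- metric_base_case(params, m, listing_year)
    q <- stats::quantile(s$output, c(0.10, 0.50, 0.90), names = FALSE,
                         type = 7)
    data.frame(metric = m, base_case = base,
               certainty = mean(s$output >= base),
               mean = mean(s$output), median = q[2], p10 = q[1], p90 = q[3],
               mean_vs_base = mean(s$output) / base - 1)
  })
  out <- list(summary = do.call(rbind, rows), n_draws = n_draws, seed = seed,
              listing_year = listing_year,
              draws = if (keep_draws) draws)
  class(out) <- "lt_monte_carlo"
  out
}

#' @export
print.lt_monte_carlo <- function(x, ...) {
  cat(sprintf("<lt_monte_carlo: %d draws, seed %d, Year-%d metrics>\n",
              x$n_draws, x$seed, x$listing_year))
  s <- x$summary
  s$base_case <- round(s$base_case)
  s$certainty <- sprintf("%.0f%%", 100 * s$certainty)
  s$mean <- round(s$mean); s$median <- round(s$median)
  s$p10 <- round(s$p10); s$p90 <- round(s$p90)
  s$mean_vs_base <- sprintf("%+.1f%%", 100 * s$mean_vs_base)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Contribution-to-variance sensitivity indices
#'
#' Signed, normalized squared Spearman rank correlation of each varied
#' input with the output: `index_i = sign(rho_i) * rho_i^2 / sum_j rho_j^2`.
#' This is the rank contribution-to-variance convention of spreadsheet PSA
#' tools, so reported indices sum to about +/-100% in absolute value.
#'
#' @param inputs Matrix or data frame of sampled inputs (one column per
#'   input, one row per draw). Constant columns are dropped.
#' @param output Numeric vector of metric values per draw.
#' @return A `data.frame` (`input`, `rho`, `index`, `rank`) sorted by
#'   decreasing absolute index; all-`NA` indices if the output is constant.
#' @export
sensitivity_indices <- function(inputs, output) {
  inputs <- as.matrix(inputs)
  stopifnot(nrow(inputs) == length(output))
  if (nrow(inputs) < 100)
    stop("sensitivity_indices requires at least 100 draws", call. = FALSE)
  varied <- apply(inputs, 2, function(v) stats::sd(v) > 0)
  inputs <- inputs[, varied, drop = FALSE]
  if (stats::sd(output) == 0) {
    warning("constant output: sensitivity indices undefined", call. = FALSE)
    return(data.frame(input = colnames(inputs), rho = NA_real_,
                      index = NA_real_, rank = NA_integer_))
  }
  rho <- apply(inputs, 2, function(v)
    stats::cor(rank(v), rank(output)))
  idx <- sign(rho) * rho^2 / sum(rho^2)
  out <- data.frame(input = colnames(inputs), rho = rho, index = idx,
                    row.names = NULL)
  out <- out[order(-abs(out$index)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Sensitivity report for a Monte Carlo run
#'
#' Applies [sensitivity_indices()] to the retained draws of each metric of
#' a [run_monte_carlo()] result (run with `keep_draws = TRUE`).
#'
#' @param mc An `lt_monte_carlo` object with retained draws.
#' @param metrics Metrics to report (default: all retained).
#' @return Named list of sensitivity-index data frames.
#' @export
sensitivity_report <- function(mc, metrics = names(mc$draws)) {
  if (is.null(mc$draws))
    stop("run_monte_carlo must be called with keep_draws = TRUE",
         call. = FALSE)
  out <- lapply(metrics, function(m)
    sensitivity_indices(mc$draws[[m]]$inputs, mc$draws[[m]]$output))
  names(out) <- metrics
  out
}
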