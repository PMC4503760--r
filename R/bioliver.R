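#' Cell-line specification for the bioengineered-liver cost ledger
#'
#' @param name Cell line name.
#' @param cells_per_liver Cells required to populate a whole liver.
#' @param cells_per_vial Cells supplied per cryovial.
#' @param price_per_vial Catalog list price per vial (USD).
#' @return An object of class `cell_line`.
#' @export
cell_line <- function(name, cells_per_liver, cells_per_vial, price_per_vial) {
  if (any(c(cells_per_liver, cells_per_vial, price_per_vial) <= 0))
    stop("cell_line: all quantities must be positive", call. = FALSE)
  structure(list(name = name, cells_per_liver = cells_per_liver,
                 cells_per_vial = cells_per_vial,
                 price_per_vial = price_per_vial),
            class = "cell_line")
}

#' Baseline iPSC-derived cell lines at catalog list pricing
#'
#' Hepatocytes (1.5e11 cells per liver), endothelial cells (40% of the
#' hepatocyte count) and fibroblasts (10%), priced per cryovial at current
#' vendor catalog list prices.
#'
#' @return List of [cell_line()] objects.
#' @export
baseline_cell_lines <- function() {
  list(
    hepatocytes = cell_line("hepatocytes", 1.5e11, 9.0e6, 1500),
    endothelial_cells = cell_line("endothelial_cells", 6.0e10, 3.2e7, 800),
    fibroblasts = cell_line("fibroblasts", 1.5e10, 1.0e7, 800))
}

check_fraction <- function(fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  fraction
}

#' Vials required for a (partial) liver
#'
#' Fractional vials are allowed: the published ledger costs imply exact
#' proportional pricing, not whole-vial purchasing.
#'
#' @param line A [cell_line()].
#' @param fraction Fraction of a whole liver in (0, 1].
#' @return Number of vials (real-valued).
#' @examples
#' vials_required(baseline_cell_lines()$hepatocytes)  # 16666.67 (1.67e4)
#' @export
vials_required <- function(line, fraction = 1) {
  check_fraction(fraction)
  fraction * line$cells_per_liver / line$cells_per_vial
}

#' Catalog-price cost ledger for a bioengineered liver
#'
#' Sums the somatic-cell reprogramming cost (fraction-independent) and each
#' cell line's vial cost, the latter scaling linearly with the fraction of
#' liver built.
#'
#' @param lines List of [cell_line()] objects.
#' @param fraction Fraction of a whole liver in (0, 1].
#' @param reprogramming Reprogramming cost (USD; non-GMP list price).
#' @return An object of class `liver_cost_breakdown`: per-line vials and
#'   costs, the reprogramming cost and the exact total.
#' @examples
#' build_cost(baseline_cell_lines())$total             # 27,715,000
#' build_cost(baseline_cell_lines(), fraction = 0.35)$total  # 9,710,000
#' @export
build_cost <- function(lines, fraction = 1, reprogramming = 15000) {
  if (!length(lines)) stop("need at least one cell line", call. = FALSE)
  check_fraction(fraction)
  if (reprogramming < 0) stop("reprogramming cost must be >= 0", call. = FALSE)
  vials <- vapply(lines, vials_required, numeric(1), fraction = fraction)
  costs <- vials * vapply(lines, function(l) l$price_per_vial, numeric(1))
  ledger <- data.frame(
    line = vapply(lines, function(l) l$name, character(1)),
    cells = fraction * vapply(lines, function(l) l$cells_per_liver, numeric(1)),
    vials = vials, cost = costs, row.names = NULL)
  structure(list(fraction = fraction, reprogramming = reprogramming,
                 lines = ledger, cell_cost = sum(costs),
                 total = reprogramming + sum(costs)),
            class = "liver_cost_breakdown")
}

#' @export
print.liver_cost_breakdown <- function(x, ...) {
  cat(sprintf("<bioengineered liver cost ledger: %.0f%% of liver>\n",
              100 * x$fraction))
  df <- x$lines
  df$vials <- formatC(df$vials, format = "e", digits = 2)
  df$cost <- sprintf("$%s", format(round(df$cost), big.mark = ","))
  print(df, row.names = FALSE)
  cat(sprintf("  reprogramming: $%s\n",
              format(x$reprogramming, big.mark = ",")))
  cat(sprintf("  total:         $%s\n",
              format(round(x$total), big.mark = ",")))
  invisible(x)
}

#' Re-price the ledger under per-line price multipliers
#'
#' Scales each cell line's vial price (for example to explore economies of
#' scale in cell manufacturing) and rebuilds the ledger.
#'
#' @param lines List of [cell_line()] objects.
#' @param multipliers Named (by line) or unnamed positive multipliers,
#'   recycled across lines.
#' @inheritParams build_cost
#' @return A `liver_cost_breakdown`.
#' @export
price_decline_scenario <- function(lines, multipliers, fraction = 1,
                                   reprogramming = 15000) {
  if (any(multipliers < 0)) stop("multipliers must be >= 0", call. = FALSE)
  mult <- if (!is.null(names(multipliers))) {
    missing <- setdiff(names(lines), names(multipliers))
    if (length(missing))
      stop(sprintf("no multiplier for line(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    multipliers[names(lines)]
  } else rep_len(multipliers, length(lines))
  repriced <- Map(function(l, m) {
    l$price_per_vial <- l$price_per_vial * m
    l
  }, lines, mult)
  build_cost(repriced, fraction = fraction, reprogramming = reprogramming)
}

#' Read a cell-line price list from CSV
#'
#' Expected columns: `line`, `cells_per_liver`, `cells_per_vial`,
#' `price_per_vial`.
#'
#' @param path CSV path.
#' @return List of [cell_line()] objects named by line.
#' @export
read_price_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "cells_per_liver", "cells_per_vial", "price_per_vial")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("price list missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lines <- lapply(seq_len(nrow(df)), function(i)
    cell_line(df$line[i], df$cells_per_liver[i], df$cells_per_vial[i],
              df$price_per_vial[i]))
  names(lines) <- df$line
  lines
}
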