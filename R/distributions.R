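#' Distribution specification for an uncertain model input
#'
#' Every model input carries a `dist_spec` describing how it is treated in
#' deterministic runs (always at `base`) and in Monte Carlo runs (sampled
#' from the stated distribution). Four kinds are supported:
#'
#' * `"fixed"` — never varied; `low`/`high` absent (or equal to `base`).
#' * `"triangular"` — bounded, with `base` interpreted as the mode.
#' * `"uniform"` — sampled on `[low, high]`; `base` is reported but does not
#'   enter sampling.
#' * `"variable"` — a placeholder for inputs whose bounds are not published;
#'   resolved to a triangular before sampling (see [resolve_variable()]).
#'
#' @param kind One of `"fixed"`, `"triangular"`, `"uniform"`, `"variable"`.
#' @param base Base (deterministic) value. For triangular kinds this is the
#'   mode of the distribution.
#' @param low,high Lower and upper bounds; required for `"triangular"` and
#'   `"uniform"`, must satisfy `low <= base <= high`.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("triangular", 0.049, 0.0258, 0.0604)
#' dist_spec("fixed", 0.06)
#' @export
dist_spec <- function(kind, base, low = NULL, high = NULL) {
  kind <- match.arg(kind, c("fixed", "triangular", "uniform", "variable"))
  spec <- structure(
    list(kind = kind, base = as.numeric(base),
         low = if (!is.null(low)) as.numeric(low),
         high = if (!is.null(high)) as.numeric(high)),
    class = "dist_spec")
  validate_dist_spec(spec)
  spec
}

#' @export
print.dist_spec <- function(x, ...) {
  rng <- if (x$kind %in% c("triangular", "uniform"))
    sprintf(" [%g, %g]", x$low, x$high) else ""
  cat(sprintf("<dist_spec %s: base %g%s>\n", x$kind, x$base, rng))
  invisible(x)
}

validate_dist_spec <- function(spec) {
  if (!is.finite(spec$base))
    stop("dist_spec: 'base' must be a finite number", call. = FALSE)
  if (spec$kind == "fixed") {
    for (b in c(spec$low, spec$high))
      if (!isTRUE(all.equal(b, spec$base)))
        stop("dist_spec: fixed kind requires low/high absent or equal to base",
             call. = FALSE)
  } else if (spec$kind %in% c("triangular", "uniform")) {
    if (is.null(spec$low) || is.null(spec$high))
      stop(sprintf("dist_spec: %s kind requires both 'low' and 'high'",
                   spec$kind), call. = FALSE)
    if (spec$low > spec$base || spec$base > spec$high)
      stop(sprintf(
        "dist_spec: range error, need low <= base <= high (got %g, %g, %g)",
        spec$low, spec$base, spec$high), call. = FALSE)
  }
  # "variable": only base is required; bounds supplied by resolve_variable()
  invisible(spec)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Deterministic base-case value of a distribution spec
#'
#' Returns the `base` value regardless of kind; this is how every
#' deterministic forecast in the package evaluates its inputs.
#'
#' @param spec A [dist_spec()].
#' @return The base value, a length-1 numeric.
#' @export
point_estimate <- function(spec) {
  stopifnot(is_dist_spec(spec))
  spec$base
}

#' Sample from a distribution spec
#'
#' Draws `n` values. Fixed specs return the base unchanged; uniform specs
#' draw from `U(low, high)`; triangular specs use the inverse-CDF transform
#' with mode = `base`. `"variable"` specs must be resolved to triangular
#' first (see [resolve_variable()]); sampling one directly is an error.
#'
#' Uses R's global random-number stream: call `set.seed()` beforehand for
#' reproducible draws.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1L) {
  stopifnot(is_dist_spec(spec), n >= 0)
  switch(spec$kind,
    fixed = rep(spec$base, n),
    uniform = stats::runif(n, spec$low, spec$high),
    triangular = rtriangular(n, spec$low, spec$base, spec$high),
    variable = stop(
      "sample_dist: 'variable' specs must be resolved to triangular first",
      call. = FALSE))
}

# Inverse-CDF triangular sampler, mode = b. Degenerate ranges collapse to
# point masses so fixed-equivalent specs sample deterministically.
rtriangular <- function(n, a, b, c) {
  if (c <= a) return(rep(b, n))
  u <- stats::runif(n)
  fb <- (b - a) / (c - a)
  x <- ifelse(u < fb,
              a + sqrt(u * (c - a) * (b - a)),
              c - sqrt((1 - u) * (c - a) * (c - b)))
  # guard the fb boundary when b == a or b == c
  x[!is.finite(x)] <- b
  x
}
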