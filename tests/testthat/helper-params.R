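# Shared fixtures: the packaged baseline (loaded once) and small helpers
# for deriving modified parameter sets in tests.

bl <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_parameters("table1_baseline")
    cached
  }
})

# Replace every distribution spec by a fixed spec at its base value,
# collapsing all sampling to the deterministic base case.
collapse_to_fixed <- function(x) {
  if (inherits(x, "dist_spec")) return(dist_spec("fixed", x$base))
  if (is.list(x)) {
    cls <- class(x)
    x <- lapply(x, collapse_to_fixed)
    class(x) <- cls
    return(x)
  }
  x
}

# Set the base (and bounds, for fixed kinds) of one spec inside a params
# object; `path` is a character vector of list names.
set_base <- function(params, path, base, low = NULL, high = NULL) {
  sp <- params[[path]]
  stopifnot(inherits(sp, "dist_spec"))
  params[[path]] <- dist_spec(sp$kind, base,
                              if (is.null(low)) sp$low else low,
                              if (is.null(high)) sp$high else high)
  params
}
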