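# Deterministic sensitivity analysis: one-way sweeps, tornado ranking, and
# threshold (break-even) search. The incremental cost is affine in every
# single parameter (the tree expectation is multilinear), so thresholds
# found by bisection must agree with a two-point linear solve.

#' One-way parameter sweep
#'
#' Evaluates the incremental cost (MSU minus ST) over a grid of values of a
#' single parameter, holding every other parameter at baseline. Probability
#' grids are clipped to \[0, 1\].
#'
#' @inheritParams build_strategy_trees
#' @param name Parameter to vary (a row of the parameter set).
#' @param grid Numeric vector of values to evaluate at.
#' @return A data.frame with columns `value` and `incremental_cost`.
#' @export
one_way_sweep <- function(params, name, grid, options = model_options()) {
  i <- match(name, params$name)
  if (is.na(i)) {
    stop(sprintf("unknown parameter '%s'; valid names: %s", name,
                 paste(params$name, collapse = ", ")), call. = FALSE)
  }
  if (params$kind[i] == "probability") grid <- pmin(pmax(grid, 0), 1)
  inc <- vapply(grid, function(v) {
    evaluate(set_baseline(params, name, v), options)$incremental_cost
  }, numeric(1))
  data.frame(value = grid, incremental_cost = inc)
}

#' Tornado analysis
#'
#' Evaluates the incremental cost at every parameter's low and high range
#' bound (others at baseline) and ranks parameters by swing, the absolute
#' difference between the two incremental costs. Parameters with a collapsed
#' range (low = high) are kept with swing 0.
#'
#' @inheritParams build_strategy_trees
#' @return A data.frame sorted by decreasing swing with columns `parameter`,
#'   `label`, `low`, `high`, `incremental_at_low`, `incremental_at_high`,
#'   `swing`, `rank`.
#' @export
tornado <- function(params, options = model_options()) {
  stop_if_invalid_params(params)
  rows <- lapply(seq_len(nrow(params)), function(i) {
    name <- params$name[i]
    at <- one_way_sweep(params, name, c(params$low[i], params$high[i]), options)
    data.frame(parameter = name,
               label = unname(PARAM_LABELS[name]),
               low = params$low[i], high = params$high[i],
               incremental_at_low = at$incremental_cost[1],
               incremental_at_high = at$incremental_cost[2],
               swing = abs(at$incremental_cost[2] - at$incremental_cost[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold (break-even) search for one parameter
#'
#' Finds the parameter value at which the lower-cost strategy switches
#' (incremental cost crosses zero), all other parameters at baseline. The
#' root is bracketed by bisection to a relative tolerance of 1e-6 and
#' finished with one linear-interpolation step inside the final bracket;
#' because the incremental cost is affine in any one parameter, this lands
#' the root to machine precision and coincides with the closed-form linear
#' solve over the original bounds. If the
#' incremental cost has the same sign at both bounds there is no threshold
#' (`direction = "none"`). A bound where the incremental cost is exactly 0
#' is returned as the threshold itself.
#'
#' @inheritParams build_strategy_trees
#' @param name Parameter to search over.
#' @param bounds Numeric length-2 search interval `(low, high)`.
#' @param tol Relative bisection tolerance.
#' @return A list of class `threshold_result` with `parameter`,
#'   `threshold`, `direction` (`"msu_optimal_above"`, `"msu_optimal_below"`
#'   or `"none"`), and `bounds`.
#' @export
#' @examples
#' find_threshold(default_parameters(), "n_census", c(100, 1000))
find_threshold <- function(params, name, bounds, options = model_options(),
                           tol = 1e-6) {
  if (length(bounds) != 2L || !is.numeric(bounds) || bounds[1] >= bounds[2]) {
    stop("bounds must be a numeric pair with low < high", call. = FALSE)
  }
  f <- function(v) {
    evaluate(set_baseline(params, name, v), options)$incremental_cost
  }
  lo <- bounds[1]; hi <- bounds[2]
  flo <- f(lo); fhi <- f(hi)

  result <- function(threshold, direction) {
    structure(list(parameter = name, threshold = threshold,
                   direction = direction, bounds = bounds),
              class = "threshold_result")
  }
  # MSU is optimal where the incremental cost is negative
  dir_from_slope <- function() if (fhi < flo) "msu_optimal_above" else "msu_optimal_below"

  if (flo == 0) return(result(lo, dir_from_slope()))
  if (fhi == 0) return(result(hi, dir_from_slope()))
  if (sign(flo) == sign(fhi)) return(result(NA_real_, "none"))

  while ((hi - lo) > tol * max(abs(lo), abs(hi), 1)) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    if (fmid == 0) return(result(mid, dir_from_slope()))
    if (sign(fmid) == sign(flo)) { lo <- mid; flo <- fmid } else { hi <- mid; fhi <- fmid }
  }
  # the incremental cost is affine in a single parameter, so one linear
  # interpolation inside the final bracket lands the root to machine precision
  result(lo - flo * (hi - lo) / (fhi - flo), dir_from_slope())
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("No break-even for '%s' on (%g, %g): one strategy is cheaper throughout\n",
                x$parameter, x$bounds[1], x$bounds[2]))
  } else {
    cat(sprintf("Break-even for '%s': %.6g (%s)\n", x$parameter, x$threshold,
                sub("_", " ", x$direction)))
  }
  invisible(x)
}
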