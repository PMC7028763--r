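# Probabilistic sensitivity analysis: second-order uncertainty propagated by
# seeded Monte Carlo. Probabilities get beta distributions and costs gamma
# distributions, moment-matched so the mean is the baseline value and the
# sd is (high - low)/3.92 (the range read as a central 95% interval); the
# annual census is drawn uniformly over its integer range.

#' Assign sampling distributions to every parameter
#'
#' Moment matching per parameter kind: probabilities get a beta distribution
#' with mean = baseline and sd = (high - low)/3.92; costs get a gamma
#' distribution with the same moments (right-skewed, which suits the
#' MSU-operations cost whose reported range is skewed toward its lower end);
#' the census gets a discrete uniform over `low:high`. A collapsed range
#' (low = high) yields a point mass. If the requested beta variance is
#' infeasible (sd^2 >= mean(1-mean)) the parameter falls back to a
#' continuous uniform over (low, high) and the fallback is recorded.
#'
#' @inheritParams build_strategy_trees
#' @return A data.frame with one row per parameter: `parameter`, `family`
#'   (`"beta"`, `"gamma"`, `"uniform_integer"`, `"uniform"`, `"point"`),
#'   `shape1`, `shape2` (family-specific), `mean`, `sd`, `note`.
#' @export
assign_distributions <- function(params) {
  stop_if_invalid_params(params)
  rows <- lapply(seq_len(nrow(params)), function(i) {
    name <- params$name[i]; kind <- params$kind[i]
    m <- params$baseline[i]
    s <- (params$high[i] - params$low[i]) / 3.92
    row <- function(family, shape1, shape2, mean, sd, note = "") {
      data.frame(parameter = name, family = family, shape1 = shape1,
                 shape2 = shape2, mean = mean, sd = sd, note = note,
                 stringsAsFactors = FALSE)
    }
    if (s == 0) return(row("point", m, m, m, 0))
    if (kind == "count") {
      lo <- params$low[i]; hi <- params$high[i]
      mu <- (lo + hi) / 2
      return(row("uniform_integer", lo, hi, mu, sqrt(((hi - lo + 1)^2 - 1) / 12)))
    }
    v <- s^2
    if (kind == "probability") {
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        return(row("uniform", params$low[i], params$high[i],
                   (params$low[i] + params$high[i]) / 2,
                   (params$high[i] - params$low[i]) / sqrt(12),
                   "beta moment matching infeasible; uniform fallback"))
      }
      nu <- m * (1 - m) / v - 1
      return(row("beta", m * nu, (1 - m) * nu, m, s))
    }
    # cost: gamma, shape/rate parameterization
    if (m <= 0) {
      return(row("uniform", params$low[i], params$high[i],
                 (params$low[i] + params$high[i]) / 2,
                 (params$high[i] - params$low[i]) / sqrt(12),
                 "gamma moment matching infeasible; uniform fallback"))
    }
    row("gamma", m^2 / v, m / v, m, s)
  })
  do.call(rbind, rows)
}

sample_one <- function(spec) {
  switch(spec$family,
         point = spec$mean,
         beta = stats::rbeta(1, spec$shape1, spec$shape2),
         gamma = stats::rgamma(1, shape = spec$shape1, rate = spec$shape2),
         uniform = stats::runif(1, spec$shape1, spec$shape2),
         uniform_integer = sample(seq(spec$shape1, spec$shape2), 1),
         stop("unknown distribution family: ", spec$family))
}

#' Run the probabilistic sensitivity analysis
#'
#' For each iteration every parameter is drawn independently from its
#' assigned distribution and both strategies are evaluated through the
#' strategy trees at the sampled values. The stroke-type mixture constraint
#' (`p_is + p_mimic <= 1` for each arm) is enforced by rejection resampling
#' of the (p_is_msu, p_is_st, p_mimic) triple, with a clip after 1,000
#' failed attempts. Identical seeds reproduce the run bitwise.
#'
#' @inheritParams build_strategy_trees
#' @param n_iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed for the random-number stream.
#' @return A list of class `psa_result`: `n_iterations`, `seed`, `specs`
#'   (the distribution table), `draws` (one row per iteration of sampled
#'   parameter values), `costs` (columns `cost_msu`, `cost_st`,
#'   `incremental`), and `preference` (named proportions, ties counted
#'   toward ST).
#' @export
run_psa <- function(params, options = model_options(), n_iterations = 10000,
                    seed = 20140701) {
  stopifnot(n_iterations >= 1)
  stop_if_invalid_params(params)
  specs <- assign_distributions(params)
  spec_list <- split(specs, seq_len(nrow(specs)))
  names(spec_list) <- specs$parameter
  mix_names <- c("p_is_msu", "p_is_st", "p_mimic")

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_iterations, ncol = nrow(specs),
                  dimnames = list(NULL, specs$parameter))
  cost_msu <- cost_st <- numeric(n_iterations)

  base <- params
  for (it in seq_len(n_iterations)) {
    x <- vapply(spec_list, sample_one, numeric(1))
    # mixture constraint: derived hemorrhagic share must stay non-negative
    tries <- 0L
    while ((x["p_is_msu"] + x["p_mimic"] > 1 || x["p_is_st"] + x["p_mimic"] > 1) &&
           tries < 1000L) {
      for (nm in mix_names) x[nm] <- sample_one(spec_list[[nm]])
      tries <- tries + 1L
    }
    if (x["p_is_msu"] + x["p_mimic"] > 1 || x["p_is_st"] + x["p_mimic"] > 1) {
      x["p_mimic"] <- min(1 - x["p_is_msu"], 1 - x["p_is_st"])
    }
    draws[it, ] <- x
    base$baseline <- unname(x[base$name])
    trees <- build_strategy_trees(base, options)
    n <- x["n_census"]
    cost_st[it] <- n * expected_cost(trees$st, validate = FALSE)
    cost_msu[it] <- x["c_msu_annual"] + n * expected_cost(trees$msu, validate = FALSE) +
      if (options$ed_scenario) n * x["c_ed_is"] else 0
  }

  incremental <- cost_msu - cost_st
  structure(list(
    n_iterations = n_iterations,
    seed = seed,
    options = options,
    specs = specs,
    draws = as.data.frame(draws),
    costs = data.frame(cost_msu = cost_msu, cost_st = cost_st,
                       incremental = incremental),
    preference = c(msu = mean(incremental < 0), st = mean(incremental >= 0))
  ), class = "psa_result")
}

#' Summarize a PSA run
#'
#' Summary statistics per cost column, mirroring the usual Monte Carlo
#' report: mean, median, standard deviation, standard error
#' (sqrt(variance/size)), minimum, 10th and 90th percentiles, maximum.
#'
#' @param psa A [run_psa()] result.
#' @return A data.frame with a `statistic` column and one column per cost
#'   series (`cost_msu`, `cost_st`, `incremental`).
#' @export
psa_summary <- function(psa) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$costs) >= 1)
  stat_rows <- list(
    mean = mean, median = stats::median,
    sd = function(x) if (length(x) > 1) stats::sd(x) else 0,
    se = function(x) if (length(x) > 1) sqrt(stats::var(x) / length(x)) else 0,
    min = min,
    p10 = function(x) unname(stats::quantile(x, 0.10)),
    p90 = function(x) unname(stats::quantile(x, 0.90)),
    max = max
  )
  out <- data.frame(statistic = names(stat_rows), stringsAsFactors = FALSE)
  for (col in names(psa$costs)) {
    out[[col]] <- vapply(stat_rows, function(f) f(psa$costs[[col]]), numeric(1))
  }
  out
}

#' Cost acceptability curve
#'
#' Empirical cumulative proportion of iterations whose incremental cost
#' (MSU minus ST) does not exceed each grid level: the probability the MSU
#' is acceptable if the decision maker tolerates paying up to `x` more.
#' At `x = 0` the curve equals the MSU preference probability.
#'
#' @param psa A [run_psa()] result.
#' @param x_grid Numeric vector of cost-difference levels; by default an
#'   even grid spanning the observed incremental costs plus zero.
#' @return A data.frame with columns `x` and `proportion` (non-decreasing,
#'   reaching 0 below the minimum and 1 above the maximum).
#' @export
acceptability_curve <- function(psa, x_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$costs) >= 1)
  inc <- psa$costs$incremental
  if (is.null(x_grid)) {
    x_grid <- sort(unique(c(0, seq(min(inc), max(inc), length.out = 101))))
  }
  data.frame(x = x_grid,
             proportion = vapply(x_grid, function(x) mean(inc <= x), numeric(1)))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iterations, x$seed))
  cat(sprintf("  ST cheaper in  %.1f%% of iterations\n", 100 * x$preference["st"]))
  cat(sprintf("  MSU cheaper in %.1f%% of iterations\n", 100 * x$preference["msu"]))
  s <- psa_summary(x)
  cat(sprintf("  Mean incremental cost: $%s (sd $%s)\n",
              format(round(s$incremental[s$statistic == "mean"]), big.mark = ","),
              format(round(s$incremental[s$statistic == "sd"]), big.mark = ",")))
  invisible(x)
}
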