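# Model parameters: probabilities (with baseline/low/high), unit costs
# (2017 USD), and the annual transport census. A parameter set is a
# data.frame (class msu_parameters) with one row per parameter.

PARAM_DEFS <- list(
  # name            baseline   low      high     kind
  list("n_census",     355,     100,     600,    "count"),
  list("p_is_msu",     0.53,    0.43,    0.63,   "probability"),
  list("p_is_st",      0.53,    0.43,    0.63,   "probability"),
  list("p_mimic",      0.27,    0.02,    0.31,   "probability"),
  list("p_elig_msu",   0.82,    0.72,    0.92,   "probability"),
  list("p_elig_st",    0.75,    0.65,    0.85,   "probability"),
  list("p_recv_msu",   0.95,    0.89,    0.98,   "probability"),
  list("p_recv_st",    0.95,    0.90,    0.99,   "probability"),
  list("p_csc",        0.42,    0.36,    0.56,   "probability"),
  list("p_tx_is",      0.41,    0.13,    0.68,   "probability"),
  list("p_tx_hem",     0.80,    0.60,    0.90,   "probability"),
  list("p_tx_mimic",   0.10,    0.01,    0.19,   "probability"),
  list("p_air_is",     0.50,    0.40,    0.60,   "probability"),
  list("p_air_hem",    0.98,    0.95,    0.99,   "probability"),
  list("p_air_ok",     0.95,    0.80,    0.99,   "probability"),
  list("c_ct",         253,     190,     316,    "cost"),
  list("c_tpa",        188,     141,     235,    "cost"),
  list("c_obs",        71,      53,      89,     "cost"),
  list("c_ed_is",      749,     563,     964,    "cost"),
  list("c_ed_hem",     749,     563,     964,    "cost"),
  list("c_tele",       28,      21,      35,     "cost"),
  list("c_air",        7412,    5559,    9265,   "cost"),
  list("c_ground",     723,     542,     904,    "cost"),
  list("c_msu_annual", 600000,  500000,  1200000, "cost")
)

# Human-readable labels used in reports and the tornado output.
PARAM_LABELS <- c(
  n_census     = "Number of stroke patients (annual census)",
  p_is_msu     = "Probability of ischemic stroke, MSU",
  p_is_st      = "Probability of ischemic stroke, ST",
  p_mimic      = "Probability of stroke mimic",
  p_elig_msu   = "Probability tPA eligible, MSU",
  p_elig_st    = "Probability tPA eligible, ST",
  p_recv_msu   = "Probability tPA received, MSU",
  p_recv_st    = "Probability tPA received, ED (ST)",
  p_csc        = "Probability initial receiving hospital is a CSC",
  p_tx_is      = "Probability of requiring transfer to CSC, ischemic",
  p_tx_hem     = "Probability of requiring transfer to CSC, hemorrhagic",
  p_tx_mimic   = "Probability of requiring transfer to CSC, mimic",
  p_air_is     = "Probability of transfer by air, ischemic",
  p_air_hem    = "Probability of transfer by air, hemorrhagic",
  p_air_ok     = "Probability air transfer feasible",
  c_ct         = "Cost of CT scan",
  c_tpa        = "Cost of tPA administration",
  c_obs        = "Cost of observation after tPA",
  c_ed_is      = "Cost of ED visit, ischemic",
  c_ed_hem     = "Cost of ED visit, hemorrhagic",
  c_tele       = "Cost of telehealth consultation",
  c_air        = "Cost of interhospital air transfer",
  c_ground     = "Cost of interhospital ground transfer",
  c_msu_annual = "Annual cost of MSU operations"
)

#' Default model parameters
#'
#' Returns the shipped parameter set: every probability and unit cost of the
#' MSU/ST model with its baseline value and low/high range (2017 USD), plus
#' the annual suspected-stroke transport census. The hemorrhagic-stroke
#' probability is not a free parameter; it is derived per arm as
#' `1 - p_is - p_mimic` (baseline 0.20).
#'
#' @return A data.frame of class `msu_parameters` with columns `name`,
#'   `baseline`, `low`, `high`, `kind` (one of `"probability"`, `"cost"`,
#'   `"count"`).
#' @seealso [load_parameters()], [param_value()], [set_baseline()]
#' @export
default_parameters <- function() {
  df <- do.call(rbind, lapply(PARAM_DEFS, function(d) {
    data.frame(name = d[[1]], baseline = d[[2]], low = d[[3]], high = d[[4]],
               kind = d[[5]], stringsAsFactors = FALSE)
  }))
  class(df) <- c("msu_parameters", "data.frame")
  df
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a parameter set and returns every
#' violation found (empty character vector when valid): known fields present,
#' `low <= baseline <= high`, probabilities within \[0, 1\], costs
#' non-negative, census at least 1, and the mixture constraint
#' `p_is + p_mimic <= 1` for each arm.
#'
#' @param params An `msu_parameters` data.frame.
#' @return Character vector of violation messages.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  need <- vapply(PARAM_DEFS, `[[`, character(1), 1)
  missing <- setdiff(need, params$name)
  if (length(missing)) {
    return(sprintf("missing parameter '%s'", missing))
  }
  for (i in seq_len(nrow(params))) {
    r <- params[i, ]
    vals <- c(baseline = r$baseline, low = r$low, high = r$high)
    if (anyNA(vals)) {
      v <- c(v, sprintf("parameter '%s' has missing values", r$name))
      next
    }
    if (!(r$low <= r$baseline && r$baseline <= r$high)) {
      v <- c(v, sprintf("parameter '%s': low <= baseline <= high violated (%g, %g, %g)",
                        r$name, r$low, r$baseline, r$high))
    }
    if (r$kind == "probability" && any(vals < 0 | vals > 1)) {
      v <- c(v, sprintf("parameter '%s': probability outside [0,1] (%g, %g, %g)",
                        r$name, r$low, r$baseline, r$high))
    }
    if (r$kind == "cost" && any(vals < 0)) {
      v <- c(v, sprintf("parameter '%s': negative cost", r$name))
    }
    if (r$name == "n_census" && r$baseline < 1) {
      v <- c(v, "parameter 'n_census': census must be >= 1")
    }
  }
  for (arm in c("p_is_msu", "p_is_st")) {
    if (all(c(arm, "p_mimic") %in% params$name)) {
      s <- param_value(params, arm) + param_value(params, "p_mimic")
      if (!is.na(s) && s > 1 + 1e-9) {
        v <- c(v, sprintf("mixture constraint violated: %s + p_mimic = %g > 1", arm, s))
      }
    }
  }
  v
}

stop_if_invalid_params <- function(params) {
  v <- validate_parameters(params)
  if (length(v)) {
    stop("invalid parameters:\n", paste("  -", v, collapse = "\n"), call. = FALSE)
  }
  invisible(params)
}

# Evaluation-time checks only: baselines must be admissible model inputs.
# (Sensitivity sweeps and PSA draws may move a baseline outside its
# low/high reporting range; that is legitimate for evaluation.)
check_eval_params <- function(params) {
  v <- character(0)
  need <- vapply(PARAM_DEFS, `[[`, character(1), 1)
  missing <- setdiff(need, params$name)
  if (length(missing)) v <- c(v, sprintf("missing parameter '%s'", missing))
  if (!length(missing)) {
    b <- stats::setNames(params$baseline, params$name)
    prob <- params$name[params$kind == "probability"]
    bad <- prob[b[prob] < 0 | b[prob] > 1]
    if (length(bad)) v <- c(v, sprintf("parameter '%s': probability outside [0,1]", bad))
    cost <- params$name[params$kind == "cost"]
    neg <- cost[b[cost] < 0]
    if (length(neg)) v <- c(v, sprintf("parameter '%s': negative cost", neg))
    if (b["n_census"] < 1) v <- c(v, "parameter 'n_census': census must be >= 1")
  }
  if (length(v)) {
    stop("invalid parameters:\n", paste("  -", v, collapse = "\n"), call. = FALSE)
  }
  invisible(params)
}

#' Read or modify a parameter's baseline value
#'
#' @param params An `msu_parameters` data.frame.
#' @param name Parameter name.
#' @param value New baseline value (for `set_baseline`).
#' @return `param_value` returns the baseline value; `set_baseline` returns
#'   the modified parameter set.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) {
    stop(sprintf("unknown parameter '%s'; valid names: %s", name,
                 paste(params$name, collapse = ", ")), call. = FALSE)
  }
  params$baseline[i]
}

#' @rdname param_value
#' @export
set_baseline <- function(params, name, value) {
  i <- match(name, params$name)
  if (is.na(i)) {
    stop(sprintf("unknown parameter '%s'; valid names: %s", name,
                 paste(params$name, collapse = ", ")), call. = FALSE)
  }
  params$baseline[i] <- as.numeric(value)
  params
}

# Baselines as a named list, with the derived hemorrhagic probabilities.
param_list <- function(params) {
  p <- as.list(stats::setNames(params$baseline, params$name))
  p$p_hem_msu <- 1 - p$p_is_msu - p$p_mimic
  p$p_hem_st <- 1 - p$p_is_st - p$p_mimic
  p
}
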