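# Synthetic patient cohort: one row per suspected-stroke transport, drawn
# from the conditional Bernoulli/categorical structure of the ST tree.
# Fields that only exist conditionally (e.g. tPA eligibility for
# non-ischemic patients) are NA, which is distinct from FALSE.

#' Simulate a synthetic transport cohort
#'
#' Draws `n` patient records emulating the registry cohort the model
#' parameters were abstracted from: stroke type (ischemic / hemorrhagic /
#' mimic with the ST-arm mixture), tPA eligibility and receipt for ischemic
#' patients, whether the initial receiving hospital is a CSC, and — for
#' non-CSC patients — transfer need, air/ground mode and air feasibility.
#' Mimic transfers are ground-only. Identical seeds reproduce the cohort
#' bitwise.
#'
#' @inheritParams build_strategy_trees
#' @param n Number of patients (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `patient_id`, `stroke_type`,
#'   `tpa_eligible`, `tpa_received`, `initial_csc`, `needs_transfer`,
#'   `transfer_air_indicated`, `air_feasible`; conditional columns are NA
#'   where their condition does not hold.
#' @export
simulate_cohort <- function(params, n, seed = 20140701) {
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    stop("n must be a non-negative count", call. = FALSE)
  }
  check_eval_params(params)
  p <- param_list(params)
  if (p$p_hem_st < 0) {
    stop("derived hemorrhagic probability is negative (p_is_st + p_mimic > 1)",
         call. = FALSE)
  }
  n <- as.integer(n)
  set.seed(seed)
  if (n == 0L) {
    return(data.frame(patient_id = character(0), stroke_type = character(0),
                      tpa_eligible = logical(0), tpa_received = logical(0),
                      initial_csc = logical(0), needs_transfer = logical(0),
                      transfer_air_indicated = logical(0),
                      air_feasible = logical(0), stringsAsFactors = FALSE))
  }

  type <- sample(c("ischemic", "hemorrhagic", "mimic"), n, replace = TRUE,
                 prob = c(p$p_is_st, p$p_hem_st, p$p_mimic))
  is_is <- type == "ischemic"

  tpa_eligible <- rep(NA, n)
  tpa_eligible[is_is] <- stats::runif(sum(is_is)) < p$p_elig_st
  tpa_received <- rep(NA, n)
  elig <- !is.na(tpa_eligible) & tpa_eligible
  tpa_received[elig] <- stats::runif(sum(elig)) < p$p_recv_st

  initial_csc <- stats::runif(n) < p$p_csc

  needs_transfer <- rep(NA, n)
  noncsc <- !initial_csc
  p_tx <- c(ischemic = p$p_tx_is, hemorrhagic = p$p_tx_hem, mimic = p$p_tx_mimic)
  needs_transfer[noncsc] <- stats::runif(sum(noncsc)) < p_tx[type[noncsc]]

  transfer_air_indicated <- rep(NA, n)
  tx <- !is.na(needs_transfer) & needs_transfer
  p_air <- c(ischemic = p$p_air_is, hemorrhagic = p$p_air_hem, mimic = 0)
  transfer_air_indicated[tx] <- stats::runif(sum(tx)) < p_air[type[tx]]

  air_feasible <- rep(NA, n)
  air <- !is.na(transfer_air_indicated) & transfer_air_indicated
  air_feasible[air] <- stats::runif(sum(air)) < p$p_air_ok

  data.frame(patient_id = sprintf("pt%05d", seq_len(n)),
             stroke_type = type,
             tpa_eligible = tpa_eligible,
             tpa_received = tpa_received,
             initial_csc = initial_csc,
             needs_transfer = needs_transfer,
             transfer_air_indicated = transfer_air_indicated,
             air_feasible = air_feasible,
             stringsAsFactors = FALSE)
}

# Wilson 95% score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # degenerate proportions: the score bound collapses to the boundary exactly
  c(lower = if (x == 0) 0 else max(0, center - half),
    upper = if (x == n) 1 else min(1, center + half))
}

#' Estimate model probabilities from a cohort
#'
#' Inverts the simulation: every conditional probability of the ST-arm model
#' is estimated as the conditional sample proportion with a Wilson 95% score
#' interval. Conditionals with an empty denominator are reported as
#' not-estimable (NA estimate and interval).
#'
#' @param cohort A data.frame as returned by [simulate_cohort()].
#' @return A data.frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `successes`, `denominator`.
#' @export
estimate_parameters <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  }
  n <- nrow(cohort)
  type <- cohort$stroke_type
  noncsc <- !cohort$initial_csc
  tx <- !is.na(cohort$needs_transfer) & cohort$needs_transfer

  counts <- list(
    p_is_st    = c(sum(type == "ischemic"), n),
    p_mimic    = c(sum(type == "mimic"), n),
    p_elig_st  = c(sum(cohort$tpa_eligible, na.rm = TRUE),
                   sum(!is.na(cohort$tpa_eligible))),
    p_recv_st  = c(sum(cohort$tpa_received, na.rm = TRUE),
                   sum(!is.na(cohort$tpa_received))),
    p_csc      = c(sum(cohort$initial_csc), n),
    p_tx_is    = c(sum(tx & type == "ischemic"), sum(noncsc & type == "ischemic")),
    p_tx_hem   = c(sum(tx & type == "hemorrhagic"), sum(noncsc & type == "hemorrhagic")),
    p_tx_mimic = c(sum(tx & type == "mimic"), sum(noncsc & type == "mimic")),
    p_air_is   = c(sum(cohort$transfer_air_indicated & type == "ischemic", na.rm = TRUE),
                   sum(tx & type == "ischemic")),
    p_air_hem  = c(sum(cohort$transfer_air_indicated & type == "hemorrhagic", na.rm = TRUE),
                   sum(tx & type == "hemorrhagic")),
    p_air_ok   = c(sum(cohort$air_feasible, na.rm = TRUE),
                   sum(!is.na(cohort$air_feasible)))
  )
  rows <- lapply(names(counts), function(nm) {
    x <- counts[[nm]][1]; d <- counts[[nm]][2]
    if (d == 0) {
      data.frame(parameter = nm, estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, successes = 0, denominator = 0,
                 stringsAsFactors = FALSE)
    } else {
      ci <- wilson_interval(x, d)
      data.frame(parameter = nm, estimate = x / d, lower = ci["lower"],
                 upper = ci["upper"], successes = x, denominator = d,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Patient-level costing of a cohort under the ST rules
#'
#' Applies the standard-transport cost rules to each record's realized path
#' (ED visit + CT for everyone, tPA + observation where received, air or
#' ground transfer charge where realized) and counts realized secondary
#' transfers under the configured consequence scope. This is the
#' patient-level oracle for the ST tree's expected cost.
#'
#' @param cohort A data.frame as returned by [simulate_cohort()].
#' @inheritParams build_strategy_trees
#' @return A list with `total_st_cost`, `transfer_count`, and `per_patient`
#'   (the per-record cost vector).
#' @export
micro_cost <- function(cohort, params, options = model_options()) {
  check_eval_params(params)
  p <- param_list(params)
  n <- nrow(cohort)
  cost <- rep(p$c_ct, n)
  cost <- cost + ifelse(cohort$stroke_type == "hemorrhagic", p$c_ed_hem, p$c_ed_is)
  recv <- !is.na(cohort$tpa_received) & cohort$tpa_received
  cost[recv] <- cost[recv] + p$c_tpa + p$c_obs

  tx <- !is.na(cohort$needs_transfer) & cohort$needs_transfer
  by_air <- tx & !is.na(cohort$air_feasible) & cohort$air_feasible
  by_ground <- tx & !by_air
  cost[by_air] <- cost[by_air] + p$c_air
  cost[by_ground] <- cost[by_ground] + p$c_ground

  in_scope <- if (options$consequence_scope == "stroke_only") {
    cohort$stroke_type %in% c("ischemic", "hemorrhagic")
  } else rep(TRUE, n)

  list(total_st_cost = sum(cost),
       transfer_count = sum(tx & in_scope),
       per_patient = cost)
}
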