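# MSU vs standard-transport strategy model: builds the per-patient decision
# trees from the parameter set, evaluates annual totals and the incremental
# cost, and counts the secondary transfers / ED encounters averted.
#
# Branch sequence (fixed by the conditional structure of the parameters):
# stroke type -> tPA cascade (ischemic only) -> initial hospital CSC? ->
# transfer needed? -> air or ground -> air feasible?. The MSU arm has no
# transfer subtree: the unit triages to the appropriate center directly.

#' Analysis options for the strategy model
#'
#' @param msu_ed_policy How MSU patients are admitted at the receiving
#'   hospital: `"non_ischemic"` (default) — ischemic patients are admitted
#'   directly to the stroke unit while hemorrhagic and mimic patients are
#'   evaluated through the receiving ED; `"none"` — every MSU patient
#'   bypasses the ED; `"all"` — every MSU patient incurs an ED visit.
#' @param ed_scenario Secondary analysis switch: when `TRUE`, one additional
#'   ED visit cost is added per MSU patient on top of the baseline policy
#'   (no direct-admit anywhere), leaving the ST arm unchanged.
#' @param consequence_scope Which averted transfers are counted:
#'   `"stroke_only"` (default) restricts the averted-transfer and averted-ED
#'   counts to confirmed-stroke (ischemic + hemorrhagic) pathways;
#'   `"all_types"` includes mimic transfers. Mimic transfers are always
#'   costed; the scope only affects the consequence counts.
#' @return A list of class `model_options`.
#' @export
model_options <- function(msu_ed_policy = c("non_ischemic", "none", "all"),
                          ed_scenario = FALSE,
                          consequence_scope = c("stroke_only", "all_types")) {
  structure(list(
    msu_ed_policy = match.arg(msu_ed_policy),
    ed_scenario = isTRUE(ed_scenario),
    consequence_scope = match.arg(consequence_scope),
    mimic_transfer_mode = "ground_only"
  ), class = "model_options")
}

# Transfer subtree appended under every ST resolution: initial hospital is a
# CSC (no transfer possible) or not; if not, transfer may be needed; needed
# transfers go by air (subject to feasibility) or ground. `base` carries the
# treatment cost items and flags accumulated upstream of the transfer stage.
st_transfer_subtree <- function(type, base_costs, base_flags, p) {
  p_tx <- switch(type, ischemic = p$p_tx_is, hemorrhagic = p$p_tx_hem,
                 mimic = p$p_tx_mimic)
  leaf <- function(suffix, extra_costs = numeric(0), extra_flags = character(0)) {
    terminal_leaf(paste0(type, "_", suffix),
                  c(base_costs, extra_costs), c(base_flags, extra_flags))
  }
  ground_leaf <- leaf("ground_transfer", c(transfer_ground = p$c_ground),
                      "ground_transfer")
  mode_node <- if (type == "mimic") {
    # no air probability is defined for mimics: ground only
    ground_leaf
  } else {
    p_air <- if (type == "ischemic") p$p_air_is else p$p_air_hem
    chance_node(paste0(type, "_transfer_mode"), list(
      branch("air_indicated", p_air, chance_node(
        paste0(type, "_air_feasibility"), list(
          branch("air_feasible", p$p_air_ok,
                 leaf("air_transfer", c(transfer_air = p$c_air), "air_transfer")),
          branch("air_infeasible", 1 - p$p_air_ok, ground_leaf)
        ))),
      branch("ground_indicated", 1 - p_air, ground_leaf)
    ))
  }
  chance_node(paste0(type, "_initial_hospital"), list(
    branch("csc", p$p_csc, leaf("csc_no_transfer")),
    branch("non_csc", 1 - p$p_csc, chance_node(
      paste0(type, "_transfer_need"), list(
        branch("transfer_needed", p_tx, mode_node),
        branch("no_transfer", 1 - p_tx, leaf("no_transfer_needed"))
      )))
  ))
}

#' Build the per-patient MSU and ST strategy trees
#'
#' Constructs both decision trees at the parameter set's baseline values.
#' In the ST arm every patient incurs one ED visit and one CT at the initial
#' hospital; eligible ischemic patients who receive tPA add the drug and
#' post-tPA observation costs; every pathway then resolves the secondary
#' transfer stage. In the MSU arm every patient incurs the on-board CT and
#' telehealth consultation; the tPA cascade uses MSU probabilities; ED costs
#' follow `msu_ed_policy`; there is no secondary transfer stage.
#'
#' @param params An `msu_parameters` data.frame (see [default_parameters()]).
#' @param options A [model_options()] list.
#' @return A list with elements `msu` and `st`, each a `chance_node`
#'   representing the per-patient tree.
#' @export
build_strategy_trees <- function(params, options = model_options()) {
  check_eval_params(params)
  p <- param_list(params)
  if (p$p_hem_st < 0 || p$p_hem_msu < 0) {
    stop("derived hemorrhagic probability is negative (p_is + p_mimic > 1)",
         call. = FALSE)
  }

  # --- ST arm ---------------------------------------------------------------
  st_is_base <- c(ed_visit = p$c_ed_is, ct = p$c_ct)
  st_is <- chance_node("ischemic_tpa_eligibility", list(
    branch("tpa_eligible", p$p_elig_st, chance_node("ischemic_tpa_receipt", list(
      branch("tpa_received", p$p_recv_st,
             st_transfer_subtree("ischemic",
                                 c(st_is_base, tpa = p$c_tpa, observation = p$c_obs),
                                 c("ed_encounter", "tpa_given"), p)),
      branch("tpa_not_received", 1 - p$p_recv_st,
             st_transfer_subtree("ischemic", st_is_base, "ed_encounter", p))
    ))),
    branch("tpa_not_eligible", 1 - p$p_elig_st,
           st_transfer_subtree("ischemic", st_is_base, "ed_encounter", p))
  ))
  st <- chance_node("st_stroke_type", list(
    branch("ischemic", p$p_is_st, st_is),
    branch("hemorrhagic", p$p_hem_st,
           st_transfer_subtree("hemorrhagic",
                               c(ed_visit = p$c_ed_hem, ct = p$c_ct),
                               "ed_encounter", p)),
    branch("mimic", p$p_mimic,
           st_transfer_subtree("mimic",
                               c(ed_visit = p$c_ed_is, ct = p$c_ct),
                               "ed_encounter", p))
  ))

  # --- MSU arm --------------------------------------------------------------
  msu_base <- c(ct = p$c_ct, telehealth = p$c_tele)
  ed_for <- function(type) {
    # mimic ED visits are costed at the ischemic ED rate (no mimic-specific cost)
    want <- switch(options$msu_ed_policy,
                   none = FALSE,
                   non_ischemic = type %in% c("hemorrhagic", "mimic"),
                   all = TRUE)
    if (!want) return(list(costs = numeric(0), flags = character(0)))
    amount <- if (type == "hemorrhagic") p$c_ed_hem else p$c_ed_is
    list(costs = c(ed_visit = amount), flags = "ed_encounter")
  }
  msu_leaf <- function(type, suffix, extra_costs = numeric(0),
                       extra_flags = character(0)) {
    ed <- ed_for(type)
    terminal_leaf(paste0(type, "_", suffix),
                  c(msu_base, extra_costs, ed$costs),
                  c(extra_flags, ed$flags))
  }
  msu_is <- chance_node("ischemic_tpa_eligibility", list(
    branch("tpa_eligible", p$p_elig_msu, chance_node("ischemic_tpa_receipt", list(
      branch("tpa_received", p$p_recv_msu,
             msu_leaf("ischemic", "tpa_received",
                      c(tpa = p$c_tpa, observation = p$c_obs), "tpa_given")),
      branch("tpa_not_received", 1 - p$p_recv_msu,
             msu_leaf("ischemic", "tpa_not_received"))
    ))),
    branch("tpa_not_eligible", 1 - p$p_elig_msu,
           msu_leaf("ischemic", "tpa_not_eligible"))
  ))
  msu <- chance_node("msu_stroke_type", list(
    branch("ischemic", p$p_is_msu, msu_is),
    branch("hemorrhagic", p$p_hem_msu, msu_leaf("hemorrhagic", "admitted")),
    branch("mimic", p$p_mimic, msu_leaf("mimic", "admitted"))
  ))

  list(msu = msu, st = st)
}

#' Evaluate the strategy model
#'
#' Computes annual expected totals for both strategies, the incremental cost
#' (MSU minus ST), per-patient costs, and the expected consequence counts.
#' The ST total is `n_census` times the per-patient ST tree expectation; the
#' MSU total adds the annual MSU operating cost to `n_census` times the
#' per-patient MSU tree expectation, plus one ED visit per patient when
#' `ed_scenario` is on.
#'
#' @inheritParams build_strategy_trees
#' @return A list of class `msu_evaluation` with elements `cost_st_total`,
#'   `cost_msu_total`, `incremental_cost`, `transfers_averted`,
#'   `transfers_averted_air`, `transfers_averted_ground`,
#'   `ed_encounters_averted`, `per_patient_cost_st`,
#'   `per_patient_cost_msu_variable`, `n_census`, and `options`.
#' @export
#' @examples
#' res <- evaluate(default_parameters())
#' round(res$incremental_cost)
evaluate <- function(params, options = model_options()) {
  trees <- build_strategy_trees(params, options)
  p <- param_list(params)
  n <- p$n_census

  ev_st <- expected_cost(trees$st, validate = FALSE)
  ev_msu <- expected_cost(trees$msu, validate = FALSE)
  cost_st_total <- n * ev_st
  cost_msu_total <- p$c_msu_annual + n * ev_msu +
    if (options$ed_scenario) n * p$c_ed_is else 0

  cons <- consequence_counts(trees$st, n, options$consequence_scope)

  structure(list(
    cost_st_total = cost_st_total,
    cost_msu_total = cost_msu_total,
    incremental_cost = cost_msu_total - cost_st_total,
    transfers_averted = cons$transfers,
    transfers_averted_air = cons$air,
    transfers_averted_ground = cons$ground,
    ed_encounters_averted = cons$transfers,
    per_patient_cost_st = ev_st,
    per_patient_cost_msu_variable = ev_msu +
      if (options$ed_scenario) p$c_ed_is else 0,
    n_census = n,
    options = options
  ), class = "msu_evaluation")
}

# Expected transfer counts on the ST tree; every transfer the ST arm incurs
# is one the MSU averts (the MSU arm has none), and each averted transfer
# also averts the receiving hospital's ED encounter.
consequence_counts <- function(st_tree, n, scope) {
  paths <- enumerate_paths(st_tree, validate = FALSE)
  type <- sub("/.*", "", paths$path)
  keep <- if (scope == "stroke_only") type %in% c("ischemic", "hemorrhagic")
          else rep(TRUE, nrow(paths))
  air <- n * sum(paths$probability[keep & paths$air_transfer])
  ground <- n * sum(paths$probability[keep & paths$ground_transfer])
  list(transfers = air + ground, air = air, ground = ground)
}

#' Expected consequence counts
#'
#' Expected annual numbers of secondary interhospital transfers averted by
#' the MSU (total, air, ground) and ED encounters averted, at baseline
#' parameter values. One ED encounter is averted per averted transfer.
#'
#' @inheritParams build_strategy_trees
#' @return A list with `transfers_averted`, `transfers_averted_air`,
#'   `transfers_averted_ground`, `ed_encounters_averted`.
#' @export
expected_consequences <- function(params, options = model_options()) {
  res <- evaluate(params, options)
  res[c("transfers_averted", "transfers_averted_air",
        "transfers_averted_ground", "ed_encounters_averted")]
}

#' Per-path breakdown of a strategy tree
#'
#' Enumerates every care pathway of one strategy at baseline values: path
#' labels, joint probability, total cost, and consequence flags. Useful for
#' auditing the tree and exporting to CSV.
#'
#' @inheritParams build_strategy_trees
#' @param strategy `"st"` or `"msu"`.
#' @return A data.frame, one row per pathway (see [enumerate_paths()]).
#' @export
path_breakdown <- function(params, options = model_options(),
                           strategy = c("st", "msu")) {
  strategy <- match.arg(strategy)
  trees <- build_strategy_trees(params, options)
  enumerate_paths(trees[[strategy]], validate = FALSE)
}

#' @export
print.msu_evaluation <- function(x, ...) {
  cat("MSU vs standard transport: annual cost-consequence evaluation\n")
  cat(sprintf("  Annual census:              %d patients\n", round(x$n_census)))
  cat(sprintf("  Cost, standard transport:  $%s\n", format(round(x$cost_st_total), big.mark = ",")))
  cat(sprintf("  Cost, MSU:                 $%s\n", format(round(x$cost_msu_total), big.mark = ",")))
  cat(sprintf("  Incremental cost (MSU-ST): $%s\n", format(round(x$incremental_cost), big.mark = ",")))
  cat(sprintf("  Transfers averted:          %.1f (air %.1f, ground %.1f)\n",
              x$transfers_averted, x$transfers_averted_air, x$transfers_averted_ground))
  cat(sprintf("  ED encounters averted:      %.1f\n", x$ed_encounters_averted))
  invisible(x)
}
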