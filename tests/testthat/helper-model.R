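# Shared fixtures: a seeded random-tree generator for oracle checks and the
# baseline parameter set.

baseline_params <- function() default_parameters()

# Random valid probability tree with bounded depth and branching. Branch
# probabilities are normalized uniforms; leaves carry 1-3 random cost items
# and a random flag subset.
random_tree <- function(max_depth = 6, max_branch = 4, depth = 0) {
  if (depth >= max_depth || (depth > 0 && runif(1) < 0.4)) {
    k <- sample(1:3, 1)
    costs <- stats::setNames(round(runif(k, 0, 1000), 2), paste0("item", seq_len(k)))
    flags <- sample(CONSEQUENCE_FLAGS, sample(0:2, 1))
    return(terminal_leaf(sprintf("leaf_d%d_%d", depth, sample.int(1e6, 1)),
                         costs, flags))
  }
  k <- sample(2:max_branch, 1)
  w <- runif(k, 0.05, 1)
  p <- w / sum(w)
  chance_node(sprintf("node_d%d_%d", depth, sample.int(1e6, 1)),
              lapply(seq_len(k), function(i) {
                branch(sprintf("b%d", i), p[i],
                       random_tree(max_depth, max_branch, depth + 1))
              }))
}

# Expected per-patient ST cost computed arithmetically (independent of the
# tree engine): direct conditional-probability algebra over the care paths.
closed_form_st_ev <- function(params) {
  p <- msucost:::param_list(params)
  mode_cost <- function(p_air) {
    p_air * (p$p_air_ok * p$c_air + (1 - p$p_air_ok) * p$c_ground) +
      (1 - p_air) * p$c_ground
  }
  tx_cost <- function(p_tx, p_air) (1 - p$p_csc) * p_tx * mode_cost(p_air)
  is_cost <- p$c_ed_is + p$c_ct + p$p_elig_st * p$p_recv_st * (p$c_tpa + p$c_obs) +
    tx_cost(p$p_tx_is, p$p_air_is)
  hem_cost <- p$c_ed_hem + p$c_ct + tx_cost(p$p_tx_hem, p$p_air_hem)
  mim_cost <- p$c_ed_is + p$c_ct + (1 - p$p_csc) * p$p_tx_mimic * p$c_ground
  p$p_is_st * is_cost + p$p_hem_st * hem_cost + p$p_mimic * mim_cost
}
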