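# Strategy model: tree construction, baseline evaluation identities,
# consequence accounting, multilinearity and monotonicity.

test_that("baseline strategy trees are valid and have the expected pathway counts", {
  trees <- build_strategy_trees(baseline_params())
  expect_length(validate_tree(trees$st), 0)
  expect_length(validate_tree(trees$msu), 0)

  st_paths <- enumerate_paths(trees$st)
  msu_paths <- enumerate_paths(trees$msu)
  # ST: ischemic 3 tPA resolutions x 5 transfer outcomes, hemorrhagic 5,
  # mimic 3 (ground-only transfer); MSU: 3 ischemic + hemorrhagic + mimic
  expect_equal(nrow(st_paths), 23)
  expect_equal(nrow(msu_paths), 5)
  expect_equal(sum(st_paths$probability), 1, tolerance = 1e-9)
  expect_equal(sum(msu_paths$probability), 1, tolerance = 1e-9)

  # the MSU arm never incurs a secondary transfer
  expect_false(any(msu_paths$air_transfer))
  expect_false(any(msu_paths$ground_transfer))
  # every ST pathway passes through the initial ED
  expect_true(all(st_paths$ed_encounter))
})

test_that("per-patient ST expectation matches independent conditional-probability algebra", {
  params <- baseline_params()
  res <- evaluate(params)
  expect_equal(res$per_patient_cost_st, closed_form_st_ev(params), tolerance = 1e-12)

  # and under perturbed parameters
  set.seed(11)
  for (i in 1:10) {
    pp <- params
    probs <- pp$kind == "probability"
    pp$baseline[probs] <- pmin(pmax(pp$baseline[probs] + runif(sum(probs), -0.05, 0.05), 0), 1)
    if (param_value(pp, "p_is_st") + param_value(pp, "p_mimic") > 1) next
    if (param_value(pp, "p_is_msu") + param_value(pp, "p_mimic") > 1) next
    expect_equal(evaluate(pp)$per_patient_cost_st, closed_form_st_ev(pp),
                 tolerance = 1e-12)
  }
})

test_that("a degenerate all-ischemic mixture collapses the type split", {
  params <- set_baseline(set_baseline(baseline_params(), "p_is_st", 1), "p_mimic", 0)
  params <- set_baseline(params, "p_is_msu", 1)
  trees <- build_strategy_trees(params)
  paths <- enumerate_paths(trees$st)
  live <- paths[paths$probability > 0, ]
  expect_true(all(grepl("^ischemic", live$path)))
})

test_that("an over-full mixture (p_is + p_mimic > 1) is rejected", {
  params <- set_baseline(baseline_params(), "p_mimic", 0.6)
  expect_error(build_strategy_trees(params), "hemorrhagic probability is negative")
})

test_that("zero-cost model evaluates to zero totals", {
  params <- baseline_params()
  params$baseline[params$kind == "cost"] <- 0
  res <- evaluate(params)
  expect_equal(res$cost_st_total, 0)
  expect_equal(res$cost_msu_total, 0)
  expect_equal(res$incremental_cost, 0)
})

test_that("the ED-inclusion scenario adds exactly one ED visit per MSU patient", {
  params <- baseline_params()
  base <- evaluate(params, model_options(ed_scenario = FALSE))
  scen <- evaluate(params, model_options(ed_scenario = TRUE))
  expect_identical(scen$cost_msu_total - base$cost_msu_total,
                   param_value(params, "n_census") * param_value(params, "c_ed_is"))
  expect_identical(scen$cost_st_total, base$cost_st_total)
  # incremental is the difference of the totals, by construction
  expect_identical(scen$incremental_cost, scen$cost_msu_total - scen$cost_st_total)
})

test_that("MSU ED admission policies order the MSU total as expected", {
  params <- baseline_params()
  totals <- vapply(c("none", "non_ischemic", "all"), function(pol) {
    evaluate(params, model_options(msu_ed_policy = pol))$cost_msu_total
  }, numeric(1))
  expect_true(totals["none"] < totals["non_ischemic"])
  expect_true(totals["non_ischemic"] < totals["all"])
  # 'all' policy differs from 'none' by one ED visit per patient (equal ED rates)
  expect_equal(totals["all"] - totals["none"],
               param_value(params, "n_census") * param_value(params, "c_ed_is"),
               ignore_attr = TRUE)
})

test_that("strategy totals are affine in each single parameter (3-point collinearity)", {
  params <- baseline_params()
  for (name in c("p_tx_is", "p_csc", "c_air", "n_census", "p_mimic", "c_msu_annual")) {
    i <- match(name, params$name)
    lo <- params$low[i]; hi <- params$high[i]; mid <- (lo + hi) / 2
    inc <- vapply(c(lo, mid, hi), function(v) {
      evaluate(set_baseline(params, name, v))$incremental_cost
    }, numeric(1))
    expect_equal(inc[2], (inc[1] + inc[3]) / 2, tolerance = 1e-9,
                 label = sprintf("midpoint collinearity for %s", name))
  }
})

test_that("totals are monotone in costs and transfer probabilities", {
  params <- baseline_params()
  st0 <- evaluate(params)$cost_st_total
  msu0 <- evaluate(params)$cost_msu_total
  for (name in c("c_ct", "c_tpa", "c_obs", "c_ed_is", "c_ed_hem", "c_air",
                 "c_ground", "p_tx_is", "p_tx_hem", "p_tx_mimic")) {
    up <- set_baseline(params, name, min(param_value(params, name) * 1.5,
                                         if (startsWith(name, "p_")) 1 else Inf))
    expect_gte(evaluate(up)$cost_st_total, st0)
  }
  for (name in c("c_msu_annual", "c_ct", "c_tele", "c_tpa", "c_obs")) {
    up <- set_baseline(params, name, param_value(params, name) * 1.5)
    expect_gte(evaluate(up)$cost_msu_total, msu0)
  }
})

test_that("consequence counts respect their structural bounds and limits", {
  params <- baseline_params()
  res <- evaluate(params)
  n <- param_value(params, "n_census")
  expect_lte(res$transfers_averted, n * (1 - param_value(params, "p_csc")))
  expect_equal(res$transfers_averted,
               res$transfers_averted_air + res$transfers_averted_ground)
  expect_identical(res$ed_encounters_averted, res$transfers_averted)

  # everyone starts at a CSC: nothing to avert
  expect_equal(evaluate(set_baseline(params, "p_csc", 1))$transfers_averted, 0)

  # forced ground transfer for every patient
  forced <- set_baseline(params, "p_is_st", 1)
  forced <- set_baseline(forced, "p_is_msu", 1)
  forced <- set_baseline(forced, "p_mimic", 0)
  forced <- set_baseline(forced, "p_csc", 0)
  forced <- set_baseline(forced, "p_tx_is", 1)
  forced <- set_baseline(forced, "p_air_is", 0)
  resf <- evaluate(forced)
  expect_equal(resf$transfers_averted, n)
  expect_equal(resf$transfers_averted_ground, n)
  expect_equal(resf$transfers_averted_air, 0)
})

test_that("mimic transfers are costed but excluded from the stroke-only count", {
  params <- baseline_params()
  stroke <- evaluate(params, model_options(consequence_scope = "stroke_only"))
  all_t <- evaluate(params, model_options(consequence_scope = "all_types"))
  p <- msucost:::param_list(params)
  mimic_tx <- p$n_census * p$p_mimic * (1 - p$p_csc) * p$p_tx_mimic
  expect_equal(all_t$transfers_averted - stroke$transfers_averted, mimic_tx,
               tolerance = 1e-9)
  # the scope changes counts, never costs
  expect_identical(all_t$cost_st_total, stroke$cost_st_total)
})
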