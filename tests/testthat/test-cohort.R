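# Synthetic cohort: simulation structure, parameter estimation with Wilson
# intervals, patient-level costing against the tree expectation.

test_that("cohort simulation handles edge sizes and is deterministic", {
  params <- baseline_params()
  expect_equal(nrow(simulate_cohort(params, 0)), 0)
  expect_error(simulate_cohort(params, -1), "non-negative")
  a <- simulate_cohort(params, 500, seed = 42)
  b <- simulate_cohort(params, 500, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(params, 500, seed = 43)))
})

test_that("conditional fields are NA exactly when their condition fails", {
  co <- simulate_cohort(baseline_params(), 3000, seed = 7)
  is_is <- co$stroke_type == "ischemic"
  expect_identical(is.na(co$tpa_eligible), !is_is)
  elig <- !is.na(co$tpa_eligible) & co$tpa_eligible
  expect_identical(is.na(co$tpa_received), !elig)
  # tPA received implies eligible
  expect_true(all(co$tpa_eligible[!is.na(co$tpa_received) & co$tpa_received]))
  expect_identical(is.na(co$needs_transfer), co$initial_csc)
  tx <- !is.na(co$needs_transfer) & co$needs_transfer
  expect_identical(is.na(co$transfer_air_indicated), !tx)
  # transfer implies a non-CSC initial hospital
  expect_true(all(!co$initial_csc[tx]))
  # mimic transfers are never by air
  expect_true(all(!co$transfer_air_indicated[tx & co$stroke_type == "mimic"]))
  air <- !is.na(co$transfer_air_indicated) & co$transfer_air_indicated
  expect_identical(is.na(co$air_feasible), !air)
})

test_that("a degenerate mixture yields an all-ischemic cohort", {
  params <- set_baseline(set_baseline(baseline_params(), "p_is_st", 1), "p_mimic", 0)
  co <- simulate_cohort(params, 100, seed = 1)
  expect_equal(nrow(co), 100)
  expect_true(all(co$stroke_type == "ischemic"))
})

test_that("type frequencies land within binomial sampling error", {
  co <- simulate_cohort(baseline_params(), 10000, seed = 123)
  p_hat <- mean(co$stroke_type == "ischemic")
  expect_lt(abs(p_hat - 0.53), 3 * sqrt(0.53 * 0.47 / 10000))
  m_hat <- mean(co$stroke_type == "mimic")
  expect_lt(abs(m_hat - 0.27), 3 * sqrt(0.27 * 0.73 / 10000))
})

test_that("estimation on handcrafted cohorts is exact counting", {
  co <- data.frame(
    patient_id = sprintf("pt%02d", 1:10),
    stroke_type = rep("ischemic", 10),
    tpa_eligible = c(rep(TRUE, 8), rep(FALSE, 2)),
    tpa_received = c(rep(TRUE, 6), rep(FALSE, 2), NA, NA),
    initial_csc = rep(c(TRUE, FALSE), 5),
    needs_transfer = ifelse(rep(c(TRUE, FALSE), 5), NA, FALSE),
    transfer_air_indicated = rep(NA, 10),
    air_feasible = rep(NA, 10),
    stringsAsFactors = FALSE
  )
  est <- estimate_parameters(co)
  g <- function(nm, col) est[[col]][est$parameter == nm]
  expect_equal(g("p_is_st", "estimate"), 1.0)
  expect_equal(g("p_elig_st", "estimate"), 0.8)
  expect_equal(g("p_recv_st", "estimate"), 0.75)
  expect_equal(g("p_csc", "estimate"), 0.5)
  expect_equal(g("p_tx_is", "denominator"), 5)
  # intervals contain their point estimates within [0, 1]
  ok <- !is.na(est$estimate)
  expect_true(all(est$lower[ok] <= est$estimate[ok] & est$estimate[ok] <= est$upper[ok]))
  expect_true(all(est$lower[ok] >= 0 & est$upper[ok] <= 1))
  # no transfers realized: air-mode conditionals are not estimable
  expect_true(is.na(g("p_air_is", "estimate")))
  expect_equal(g("p_air_is", "denominator"), 0)
})

test_that("an all-mimic cohort leaves the tPA cascade not estimable", {
  params <- set_baseline(set_baseline(baseline_params(), "p_mimic", 0.99), "p_is_st", 0.005)
  params <- set_baseline(params, "p_is_msu", 0.005)
  co <- simulate_cohort(params, 50, seed = 9)
  co <- co[co$stroke_type == "mimic", ]
  est <- estimate_parameters(co)
  expect_true(is.na(est$estimate[est$parameter == "p_elig_st"]))
  expect_error(estimate_parameters(co[0, ]), "non-empty")
})

test_that("single-record micro costs follow the path arithmetic", {
  params <- baseline_params()
  p <- msucost:::param_list(params)
  rec <- function(type, elig, recv, csc, tx, air_ind, air_ok) {
    data.frame(patient_id = "pt1", stroke_type = type, tpa_eligible = elig,
               tpa_received = recv, initial_csc = csc, needs_transfer = tx,
               transfer_air_indicated = air_ind, air_feasible = air_ok,
               stringsAsFactors = FALSE)
  }
  # ischemic, treated, initial CSC: treatment costs only
  mc <- micro_cost(rec("ischemic", TRUE, TRUE, TRUE, NA, NA, NA), params)
  expect_equal(mc$total_st_cost, p$c_ed_is + p$c_ct + p$c_tpa + p$c_obs)
  expect_equal(mc$transfer_count, 0)
  # mimic, non-CSC, ground transfer
  mc <- micro_cost(rec("mimic", NA, NA, FALSE, TRUE, FALSE, NA), params)
  expect_equal(mc$total_st_cost, p$c_ed_is + p$c_ct + p$c_ground)
  expect_equal(mc$transfer_count, 0)  # stroke_only scope excludes mimics
  mc_all <- micro_cost(rec("mimic", NA, NA, FALSE, TRUE, FALSE, NA), params,
                       model_options(consequence_scope = "all_types"))
  expect_equal(mc_all$transfer_count, 1)
  # hemorrhagic, air indicated but infeasible: ground charge
  mc <- micro_cost(rec("hemorrhagic", NA, NA, FALSE, TRUE, TRUE, FALSE), params)
  expect_equal(mc$total_st_cost, p$c_ed_hem + p$c_ct + p$c_ground)
  # hemorrhagic, air transfer realized
  mc <- micro_cost(rec("hemorrhagic", NA, NA, FALSE, TRUE, TRUE, TRUE), params)
  expect_equal(mc$total_st_cost, p$c_ed_hem + p$c_ct + p$c_air)
  expect_equal(mc$transfer_count, 1)
})

test_that("micro costs converge to the tree expectation (micro-macro agreement)", {
  params <- baseline_params()
  n <- 50000
  co <- simulate_cohort(params, n, seed = 2718)
  mc <- micro_cost(co, params)
  ev <- evaluate(params)$per_patient_cost_st
  se <- stats::sd(mc$per_patient) / sqrt(n)
  expect_lt(abs(mean(mc$per_patient) - ev), 3 * se)

  # realized transfer proportion vs the tree's stroke-only transfer probability
  trees <- build_strategy_trees(params)
  paths <- enumerate_paths(trees$st)
  type <- sub("/.*", "", paths$path)
  keep <- type %in% c("ischemic", "hemorrhagic")
  p_tx <- sum(paths$probability[keep & (paths$air_transfer | paths$ground_transfer)])
  prop <- mc$transfer_count / n
  expect_lt(abs(prop - p_tx), 3 * sqrt(p_tx * (1 - p_tx) / n))
})

test_that("estimates recover the generating parameters within sampling error", {
  params <- baseline_params()
  co <- simulate_cohort(params, 10000, seed = 31)
  est <- estimate_parameters(co)
  truth <- stats::setNames(params$baseline, params$name)
  for (i in seq_len(nrow(est))) {
    nm <- est$parameter[i]
    d <- est$denominator[i]
    if (d == 0) next
    se <- sqrt(truth[nm] * (1 - truth[nm]) / d)
    expect_lt(abs(est$estimate[i] - truth[nm]), 5 * se + 1e-12,
              label = sprintf("recovery of %s", nm))
  }
})

test_that("cohort CSV round-trips through the estimator", {
  params <- baseline_params()
  co <- simulate_cohort(params, 800, seed = 55)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co)
  expect_equal(estimate_parameters(back), estimate_parameters(co))
})
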