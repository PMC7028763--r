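---
title: "Methods: the MSU cost-consequence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MSU cost-consequence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msucost)
```

This vignette is the package's account of its model: the structure and
assumptions of the decision trees, how the parameters are interpreted, the
numerical choices behind the sensitivity analyses, what the synthetic
cohort generator does and does not emulate, and the known limitations.

## Model structure and assumptions

Both strategies are evaluated as per-patient probability trees whose
branches are mutually exclusive and exhaustive, evaluated by exact
expected-cost roll-back (`expected_cost()`), with a brute-force
path-enumeration oracle (`enumerate_paths()`) used throughout the test
suite as an independent route to the same number. The branch sequence is

1. **Stroke classification** — ischemic (probability `p_is_*` per arm),
   stroke mimic (`p_mimic`, shared between arms), and hemorrhagic as the
   derived complement `1 − p_is − p_mimic` (0.20 at baseline). The
   hemorrhagic share is not a free parameter; whenever `p_is` or `p_mimic`
   moves, the hemorrhagic branch absorbs the change.
2. **tPA cascade** (ischemic only) — eligible (`p_elig_*`), then received
   (`p_recv_*`); tPA administration and post-tPA observation are costed on
   the received pathway only. Hemorrhagic stroke is never thrombolysed.
3. **Initial hospital** (ST arm only) — a CSC with probability `p_csc`, in
   which case no secondary transfer can arise.
4. **Secondary transfer** (ST arm, non-CSC initial hospital) — needed with
   a type-specific probability (`p_tx_is`, `p_tx_hem`, `p_tx_mimic`); if
   needed, indicated by air with `p_air_is` / `p_air_hem`; an indicated air
   transfer is feasible with `p_air_ok`, otherwise it falls back to ground.
   Mimic transfers are ground-only: no air-indication probability exists
   for mimics, and introducing one would be an invention.

Cost placement encodes the care-process assumptions:

- Every ST patient incurs exactly one ED visit (at the initial hospital)
  and one CT there. No second ED encounter is costed at the receiving CSC
  for transferred ST patients; adding one would double-count against the
  averted-ED accounting below.
- Every MSU patient incurs the on-board CT and one telehealth consultation
  (`c_tele`); telehealth is MSU-only.
- MSU ED costs follow the `msu_ed_policy` option. The default,
  `"non_ischemic"`, reflects a service where the main receiving campus
  direct-admits MSU patients to the stroke unit while hemorrhagic and mimic
  patients — routed to other hospitals without a direct-admit pathway — are
  evaluated through the ED. This default is a calibration choice: it is the
  policy under which the model's annual totals reconstruct the reference
  totals most closely (both within ±1.6%), and it is exposed as an option
  (`"none"`, `"all"`) rather than hard-coded. Mimic ED visits are costed at
  the ischemic ED rate, as no mimic-specific ED cost exists in the tables.
- The **ED-inclusion scenario** (`ed_scenario = TRUE`) adds one ischemic-rate
  ED visit per MSU patient on top of the baseline policy, leaving ST
  untouched. It is implemented as an additive scenario rather than as the
  `"all"` policy switch so that the scenario-minus-baseline difference is
  exactly `n_census × c_ed_is` — an identity the test suite asserts.

Consequences: the MSU arm has no transfer stage, so the expected number of
transfers on the ST tree *is* the number the MSU averts, split air/ground
by pathway flags. One averted transfer is counted as one averted ED
encounter (the transferred patient would have been re-processed through the
receiving hospital's ED). The default consequence scope, `"stroke_only"`,
excludes mimic transfers from the averted counts while still costing them;
`"all_types"` includes them. There is no discounting (one-year horizon) and
no clinical-outcome axis.

## Parameters

The shipped file (`inst/extdata/parameters.json`) carries 24 parameters,
each with a baseline and a (low, high) range: 14 probabilities, 9 unit
costs in 2017 USD, and the annual census (355; range 100–600). Costs
quoted in other index years can be restated with
`adjust_cost_to_base_year()` (a price-index ratio) or uniformly via
`adjust_parameters_cpi()`. Probabilities are dimensionless; costs are USD
per event except `c_msu_annual` (USD per year).

Two invariants matter beyond ranges: `p_is + p_mimic ≤ 1` per arm (the
derived hemorrhagic share must be non-negative), and `low ≤ baseline ≤
high` for every row of a parameter *file*. Evaluation itself only requires
admissible values — sensitivity sweeps and PSA draws may legitimately leave
the reporting range.

## Deterministic sensitivity analysis

`one_way_sweep()` evaluates the incremental cost over a user grid;
`tornado()` does so at every parameter's range bounds and ranks by swing.
Because the tree expectation is multilinear in its parameters, the
incremental cost is affine in any single parameter — the test suite checks
this by three-point collinearity for all 24 parameters.

`find_threshold()` exploits the same affineness: the sign change is
bracketed by bisection to a relative tolerance of 1e-6, then finished with
one linear-interpolation step inside the final bracket, which for an affine
function lands the root to machine precision (the suite asserts the
residual incremental cost at the root is below $0.001 and that the root
matches an independent two-point linear solve). Ties — an incremental cost
of exactly zero at a bound — resolve to that bound. Search bounds default
to nothing: they are explicit arguments, because two of the interesting
break-even points sit at or beyond the published ranges, and the census
threshold is reported as a ceiling integer while being searched
continuously.

## Probabilistic sensitivity analysis

The ranges are nowhere defined as confidence intervals, so the package
fixes one interpretation and keeps it: a (low, high) range is read as a
central 95% interval, giving sd = (high − low)/3.92, and each distribution
is moment-matched with its mean at the baseline:

- **probabilities** → beta (feasible whenever sd² < mean(1−mean); otherwise
  the parameter falls back to a uniform over (low, high) and the fallback
  is recorded in the distribution table);
- **costs** → gamma, whose right skew also suits the MSU-operations cost,
  reported as skewed toward the lower end of its wide range — no extra skew
  parameter is introduced;
- **census** → discrete uniform over the integer range. Its midpoint (350)
  is not the baseline (355); this is the one assigned distribution that is
  not mean-centered, and it shifts the expected Monte-Carlo incremental
  cost upward by roughly $7.5k. At 10,000 iterations this remains within
  three Monte-Carlo standard errors of the baseline incremental cost, which
  is what the acceptance suite asserts.

Parameters are sampled independently (no correlation information exists);
the mixture constraint `p_is + p_mimic ≤ 1` is enforced per arm by
rejection-resampling the stroke-type triple, clipping after 1,000 attempts
(at baseline dispersions rejection occurs in roughly 1–2% of iterations, so
the induced bias is small). Ties in the strategy comparison count toward
ST. Defaults are 10,000 iterations and seed 20140701; identical seeds
reproduce the result bitwise. Reference Monte-Carlo summary tables are not
reproduced numerically — they depend on distribution choices that are not
recoverable — so the package asserts qualitative agreement only: ST cheaper
in the majority of iterations, a positively skewed incremental, ST costs
far more dispersed than MSU costs.

## The synthetic cohort generator

`simulate_cohort()` draws patient-level records from the conditional
Bernoulli/categorical structure of the ST tree: type, tPA cascade, initial
hospital, transfer realization. It emulates the registry-like cohort from
which such parameters are abstracted — including not-applicable fields
(`NA`, distinct from `FALSE`) for conditionals whose condition failed —
and feeds two validation loops:

- **parameter recovery** — `estimate_parameters()` returns conditional
  sample proportions with Wilson 95% score intervals (chosen over Wald for
  the small conditional denominators deep in the tree, e.g. air-feasibility
  among realized air transfers); coverage is checked over 50 replicates of
  n = 10,000, pooled across the 11 estimable probabilities.
- **micro–macro agreement** — `micro_cost()` costs each realized path with
  the same rules as the ST tree; its per-patient mean is checked against
  the tree expectation within three standard errors at n = 50,000.

What it does **not** emulate: geography (pickup locations and drive times
are reduced to the single Bernoulli `p_csc`), correlation between patient
characteristics, encounter-time versus final diagnoses (a real registry's
initially "suspected ischemic" patients get reclassified; the simulator
draws final types directly), and calendar structure. Passing recovery
tests therefore show that the estimation pipeline is consistent with the
generator — not that the model captures everything a real cohort would.

## Validation problem sizes

The suites run at sizes chosen to make sampling error negligible relative
to the asserted tolerances while keeping the whole run in minutes on one
core: 200 random trees (depth ≤ 6, branching ≤ 4) for the roll-back vs
enumeration oracle, 10,000 PSA iterations, 50,000 patients for
micro-costing, 50 × 10,000 for interval coverage.

## Known limitations

- No clinical outcomes, utilities or QALYs: this is an operational
  cost-consequence model, deliberately silent on treatment-time benefit.
- No reimbursement or billing revenue; costs only.
- The reconstructed trees match the reference annual totals to within
  about 1.6% but not exactly; the incremental cost, a small difference of
  two large totals, inherits those errors with a relative amplification of
  roughly five, and the acceptance suite documents where it falls outside
  the tight reproduction band.
- Because the hemorrhagic share is the derived complement, the mimic
  probability is a strong driver in the tornado (its wide range, 0.02–0.31,
  trades the cheapest type against the most transfer-intensive one). A
  parameterization with an independent hemorrhagic probability would rank
  drivers differently; the package keeps the complement construction
  because it is the only one consistent with the parameter set's
  constraints.
- Air-transfer practice is system-specific; the high baseline air fractions
  make `c_air` and `p_air_*` influential, and systems relying on ground
  transfer should re-parameterize before drawing conclusions.
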