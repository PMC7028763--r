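# msucost

Cost-consequence analysis of a Mobile Stroke Unit (MSU) versus standard
prehospital transport (ST) for suspected stroke, from the hospital
perspective, over one year of service.

An MSU is an ambulance with an on-board CT scanner, point-of-care labs and a
telemedicine link: it can diagnose stroke in the field, start thrombolysis
(tPA), and triage the patient directly to the appropriate hospital — a
comprehensive stroke center (CSC) when CSC-level care is needed. Under
standard transport the patient goes to the closest appropriate facility, is
worked up in its emergency department (ED), and, when that initial hospital
is not a CSC, may need a secondary interhospital transfer by ground or by
helicopter. The question the model answers: what does running the MSU cost
per year, net of the air transfers, ground transfers and ED encounters it
averts — and under what conditions does it become the cheaper strategy?

The package is aimed at health-economics and stroke-systems analysts who
want the model as auditable, re-parameterizable code rather than as a
spreadsheet or a proprietary decision-tree file.

## The model

Each strategy is a probability tree over the care possibilities: stroke
classification (ischemic / hemorrhagic / stroke mimic), tPA eligibility and
receipt for ischemic patients, whether the initial receiving hospital is a
CSC, whether a secondary transfer to a CSC is needed, and whether that
transfer goes by air (subject to feasibility) or ground. Branches at every
node are mutually exclusive and exhaustive, and each terminal pathway
carries the costs incurred along it. The expected per-patient cost is the
probability-weighted roll-back

&nbsp;&nbsp;&nbsp;&nbsp;E[C] = Σ_paths ( Π_branches p ) · C_path,

and annual totals are

&nbsp;&nbsp;&nbsp;&nbsp;C_ST = N · E[C_ST-tree],&nbsp;&nbsp;
C_MSU = C_ops + N · E[C_MSU-tree],&nbsp;&nbsp;
ΔC = C_MSU − C_ST,

with N the annual transport census and C_ops the annual MSU operating cost.
The MSU arm has no secondary-transfer stage (the unit triages to the right
center directly), so every expected transfer on the ST tree is a transfer
the MSU averts, along with the receiving hospital's ED encounter.
Consequences are reported as disaggregated counts next to ΔC — a
cost-consequence analysis, not a cost-effectiveness ratio: the model has no
clinical-outcome axis.

Around the baseline evaluation the package provides:

- **One-way sensitivity analysis and tornado diagram** — ΔC at each
  parameter's low/high range bound, ranked by swing (`tornado()`).
- **Threshold (break-even) analysis** — the parameter value where the
  cheaper strategy flips, by bisection with a linear finish exploiting the
  per-parameter affineness of ΔC (`find_threshold()`).
- **Probabilistic sensitivity analysis** — seeded Monte Carlo with beta
  distributions on probabilities and gamma on costs, moment-matched to each
  parameter's baseline and range, plus a cost acceptability curve
  (`run_psa()`, `acceptability_curve()`).
- **Synthetic cohort generator** — patient-level records drawn from the same
  conditional structure, with Wilson-interval parameter re-estimation and
  patient-level costing for end-to-end validation (`simulate_cohort()`,
  `estimate_parameters()`, `micro_cost()`).

## Worked example

```r
library(msucost)

params <- load_parameters()   # shipped probability/cost tables, 2017 USD
evaluate(params)
```

```
MSU vs standard transport: annual cost-consequence evaluation
  Annual census:              355 patients
  Cost, standard transport:  $797,932
  Cost, MSU:                 $862,687
  Incremental cost (MSU-ST): $64,755
  Transfers averted:          77.7 (air 51.9, ground 25.8)
  ED encounters averted:      77.7
```

Running the MSU for a year costs about $65k more than standard transport
would have for the same 355 patients — the $600k of operating cost is mostly
offset by the averted air transfers (at $7,412 each), ground transfers and
ED encounters. The break-even searches show how close the margin is:

```r
find_threshold(params, "n_census", c(100, 1000))
#> Break-even for 'n_census': 397.948 (msu optimal_above)
find_threshold(params, "c_air", c(5000, 15000))
#> Break-even for 'c_air': 8659.12 (msu optimal_above)
```

About 40 more transports a year, or modestly costlier helicopters, and the
MSU becomes the cheaper strategy outright. Without a direct-admit policy at
the receiving hospitals the picture changes sharply:

```r
evaluate(params, model_options(ed_scenario = TRUE))$cost_msu_total
#> [1] 1128582
```

The analysis scripts under `analysis/` run the full workflow in order —
`01_baseline.R`, `02_sensitivity.R` (tornado + thresholds), `03_psa.R`
(10,000 iterations), `04_cohort_validation.R` — each printing a short
narrative and writing its tables under `results/`.

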