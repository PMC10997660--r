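# pharmscreen

Drug-wide survival screening on claims data: stabilized IPTW, a covariate
balance gate, weighted Cox hazard ratios, Benjamini–Hochberg control, and
path-specific mediation through tumor subtype and nodal status.

## What it is for

Observational claims databases record every reimbursed dispensing,
diagnosis and procedure for millions of people. That makes it possible to
screen *all* commonly used non-cancer medications at once for association
with survival after a cancer diagnosis — if the analysis confronts the
fact that medication users are older, sicker and more surveilled than
non-users. `pharmscreen` packages that screen for epidemiologists and
biostatisticians working with breast-cancer-style cohorts:

* chronic-exposure phenotyping from dispensing streams (≥ 90 covered days
  of full dose in the 183 days before diagnosis; combination splitting;
  exclusion of diagnostic/antineoplastic/non-systemic codes; a ≥ 300
  exposed-patient filter),
* OS and DFS outcome construction from claims proxies (four recurrence
  rules anchored to the end of initial treatment or to surgery),
* per-drug propensity scores and stabilized
  inverse-probability-of-treatment weights
  `w = A·p̄/PS + (1−A)(1−p̄)/(1−PS)`,
* an adjustment-quality gate that discards a drug when any covariate keeps
  a weighted standardized mean difference above 0.1,
* the average treatment effect as the hazard ratio of a univariate
  weighted Cox fit with robust Wald inference, screened across drugs with
  Benjamini–Hochberg per endpoint,
* a three-way path-specific decomposition of significant effects — direct,
  via nodal status only, via subtype (possibly through node) — using
  mediator-probability-ratio weights on four counterfactual regimes, with
  patient-level bootstrap inference,
* weighted Kaplan–Meier curves and an adjusted log-rank test (threshold
  0.1) for the BH-significant drugs.

Because real data of this kind are protected, the package includes a
synthetic claims generator built on an explicit structural causal model
(`C → A → subtype → node → T`, confounded exposure, Weibull
proportional-hazards times, staggered administrative censoring) together
with Monte-Carlo oracles (`true_marginal_hr()`,
`true_path_specific_effects()`) so every estimator can be validated
against a known truth. The methods vignette
(`vignettes/pharmscreen-methods.Rmd`) documents the model, the estimators
and all numerical choices.

## Worked example

Simulate a 6000-patient cohort with eight screened drugs — one with a true
protective log hazard ratio of −0.4, seven null — on top of the index drug
(true conditional HR 0.8) and five background drugs, then run the screen:

```r
library(pharmscreen)

drugs <- data.frame(atc = sprintf("C%02dAA%02d", 1:8, 1:8),
                    beta = c(-0.4, rep(0, 7)), alpha_shift = -0.6)
cfg <- cohort_config(n_patients = 6000, seed = 42, screen_drugs = drugs)
claims <- generate_cohort(cfg)
claims
#> <claims_dataset> 6000 patients, 125260 dispensings, 4345 code events, 22160 care events

screen <- run_screen(claims, screen_config(endpoints = "os",
                                           top_k_coexposure = 5))
res <- screen$results
res[res$gate, c("drug", "hr", "ci_lower", "ci_upper", "p_value",
                "p_adjusted", "bh_reject")]
#>     drug    hr ci_lower ci_upper  p_value p_adjusted bh_reject
#>  C00AA01 0.816    0.724    0.920 0.000854    0.00598      TRUE
#>  C01AA01 0.741    0.636    0.863 0.000112    0.00156      TRUE
#>  C02AA02 0.922    0.802    1.059 0.249875    0.45683     FALSE
#>  ...     (null drugs: HRs near 1, none BH-significant)
```

Every drug passed the 0.1 SMD gate; the two true effects are the two
BH-rejections. `C00AA01` is the index drug: its estimate (HR 0.816, 95% CI
0.72–0.92) matches the Monte-Carlo oracle for this configuration,
`true_marginal_hr(cfg)` = 0.822 — the marginal HR over the study window,
slightly attenuated from the conditional 0.8 by non-collapsibility.
`C01AA01` (conditional HR `exp(-0.4)` = 0.67) screens at 0.741 marginally.

Drugs with a raw-significant ATE get a path-specific decomposition, and
BH-significant drugs get weighted KM curves and the adjusted log-rank test:

```r
screen$pse[["C01AA01.OS"]]
#> <pse_decomposition>C01AA01 OS
#>   total log-HR -0.3012 (HR 0.740)
#>   direct  -0.2804 (93.1%)
#>   node    -0.0215 (7.1%)
#>   subtype 0.0008 (-0.3%)

screen$logrank[["C01AA01.OS"]]
#> <adjusted log-rank> chisq = 19.9003 (1 df), p = 8.159e-06 [significant at 0.1]
```

The decomposition attributes 93% of the effect to the direct path — as it
should, since this generator configuration has no exposure→mediator
coupling; the three components always sum to the total exactly. Shares are
percentages of the total and may be negative (a protective total with a
deleterious node path yields a negative node share). Use
`pse_bootstrap_ci()` for interval estimates of the shares, and
`run_screen(..., out_dir = "...")` to write the results tables, balance
reports, KM curves and a run manifest to disk.

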