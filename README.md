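# pdcpersist

Adherence and persistence analysis of ophthalmic pharmacy claims.

Glaucoma is managed for decades with daily IOP-lowering eye drops, and
whether patients actually keep taking them is measurable from pharmacy
claims. `pdcpersist` implements a complete claims-database pipeline for
comparing **fixed-combination** eye drops (two drug classes co-formulated in
one bottle, e.g. latanoprost/timolol) against **unfixed combinations** (the
same two classes as two separate bottles) as second-line therapy:

* **Exposure normalization** — eye-drop claims report a dosage volume in mL
  and an unreliable period field. Supply is therefore derived from bottle
  arithmetic: `bottles = dosage / unit bottle volume` (2.5 mL for once-daily
  products, 5 mL otherwise), one bottle = 30 days for one eye, and a
  prescription of ≥ 7 bottles is read as treatment of both eyes (supply
  halved, with ceiling). Early refills are banked (stockpile carry-forward),
  never double-counted.
* **Cohort extraction** — new users of a second-line combination: ICD-10
  H401/H409 diagnosis, ≥ 365 days of single-class monotherapy immediately
  before the index date, no prior glaucoma surgery or laser, indexed on the
  first fixed-combination claim or on the first day a second distinct-class
  product is added while the first is still supplied. Every exclusion is
  counted in a flowchart-style ledger.
* **Adherence** — proportion of days covered over the 12-month post-index
  window,

  `PDC (%) = (covered days in [index, index + 365)) / 365 × 100`,

  where a covered day requires two-drug combination supply (for unfixed:
  both classes concurrently), capped at 100, with the a-priori adherence
  cutpoint PDC ≥ 80% and the standard five bins (80+, 60–79, 40–59, 20–39,
  < 20).
* **Persistence** — time from index to discontinuation, with a 30-day grace
  period after supply exhaustion; a claim adding a third concurrent class
  discontinues the episode at its date; patients still supplied at 12 months
  are censored. Kaplan–Meier persistence (`100% − cumulative discontinuation
  rate`) with complementary log-log pointwise CIs and two-group log-rank
  tests, via the survival package.
* **Switching patterns** — each trajectory classified as continued same
  class, switched two-drug regimen, third-class add-on, or discontinued all.
* **Risk factors** — Welch t / Pearson χ² group contrasts under Bonferroni
  control (α/m, m = 9 → 0.00556), then a univariate logistic screen
  (candidates at p < 0.1) feeding a forward/backward stepwise logistic
  model; odds ratios with Wald 95% CIs.
* **Synthetic claims generator** — real claims databases are proprietary, so
  the package ships a seeded generator that emulates the cohort structure
  (309 fixed / 329 unfixed patients, the observed regimen mix and adherence
  profile, an HbA1c→nonadherence link with OR 1.606 per 1%) and writes a
  planted ground-truth table so every pipeline stage can be validated by
  parameter recovery.

## Worked example

```r
library(pdcpersist)

out <- run_all(run_config(synthetic = synthetic_config(seed = 1)),
               outdir = "report")

summarize_adherence(out$adherence)[, c("group","n","mean_pdc","sd_pdc","pct_adherent")]
#>     group   n mean_pdc sd_pdc pct_adherent
#> 1     all 638     73.0   34.5         64.1
#> 2   fixed 309     80.3   30.1         74.4
#> 3 unfixed 329     66.1   36.9         54.4

out$tests$pdc_mean
#> t (Welch): statistic = 5.3514, p = 1.227e-07 (significant at 0.005556)
out$km$fixed
#> Kaplan-Meier persistence estimate (n = 309)
#>  day persistence_pct ci_low_pct ci_high_pct
#>  180            81.6       76.8        85.5
#>  365            74.4       69.2        78.9
out$logrank
#> Log-rank test: chi-square = 28.814, p = 7.968e-08
out$risk$multivariate$coefficients
#>                  term odds_ratio ci_low ci_high  p_value
#> 1 treatment_fixedTRUE       0.30  0.196    0.46 3.37e-08
#> 2       hba1c_percent       1.64  1.119    2.40 1.12e-02
#> 3             sexmale       1.63  1.067    2.50 2.41e-02
```

Reading it: fixed-combination patients are more adherent (mean PDC 80 vs 66,
74% vs 54% reaching the 80% cutpoint) and more persistent (74% vs 54% still
on therapy at 12 months; the curves differ by log-rank at far below the
Bonferroni threshold). The stepwise model recovers unfixed therapy and
higher HbA1c as nonadherence risk factors — the two effects the generator
plants — and, at this sample size, the occasional spurious survivor (here
`sex`), which is characteristic of p-value-driven stepwise selection.

`run_all()` writes the report bundle (assignments, exclusion ledger,
adherence tables shaped like the published summaries, per-group KM tables
and rates, switching-pattern table, risk-factor tables, a KM plot and a run
log with the seed and every policy flag) into `outdir`. Individual stages
are exported too: `load_claims()`, `build_cohorts()`,
`normalize_dispensing()`, `build_coverage()`, `compute_pdc()`,
`build_episode()`, `km_fit()`, `logrank_test()`, `classify_trajectory()`,
`univariate_screen()`, `stepwise_multivariate()`,
`generate_claims_data()`, `write_synthetic_data()`. Input formats are
documented in `?load_claims` with worked fixtures under `inst/extdata/`.

Policy choices the literature leaves open are explicit flags with documented
defaults (`both_eyes_policy`, `unfixed_day_rule`, `pdc_count_grace`,
`gap_anchor`, `t_test_variant`, stepwise thresholds); see the methods
vignette (`vignettes/claims-adherence-methods.Rmd`) for the rationale behind
each default and for what the synthetic generator does and does not emulate.

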