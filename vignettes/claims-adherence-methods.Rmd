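---
title: "Measuring adherence and persistence from ophthalmic pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring adherence and persistence from ophthalmic pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcpersist)
```

## The measurement problem

Pharmacy claims record what was dispensed, not what was instilled. For
eye drops the gap between the two is wider than for tablets: a claim
carries a dosage volume in mL and a coarse "period" integer, and neither
maps directly to days of therapy. `pdcpersist` turns dispensing records
into two standard endpoints for second-line glaucoma therapy —
**adherence** (proportion of days covered, PDC, over the 12 months after
a patient switches from monotherapy to a two-drug combination) and
**persistence** (time until the combination therapy is abandoned) — and
compares fixed-combination products against unfixed two-bottle regimens.

Everything below states the exact rule the code applies, the parameters a
user can move, and why each default is what it is.

## Exposure normalization

The unit of supply is the approved bottle: 2.5 mL for once-daily
formulations, 5 mL for twice-or-more-daily ones. One bottle lasts one eye
at least a month, and is counted as **30 days dispensed**. So a claim with
dosage 7.5 on a once-daily product is 3 bottles and 90 days of supply. A
dosage that is not within 10% of a whole number of bottles is rounded with
a warning; the claim's period field is ignored entirely, because the
bottle arithmetic is the reliable signal. A month is 30 days everywhere in
the package.

Two special rules:

* **Both eyes.** A single prescription of ≥ 7 bottles is read as treatment
  of both eyes. Under the default `both_eyes_policy = "halve"` the supply
  is consumed twice as fast: `days = ceiling(bottles × 30 / 2)` (the
  ceiling avoids zero-day supplies). The arithmetic consequence of the
  7-bottle flag is not fixed by convention, so `"none"` keeps the flag
  purely informational.
* **Stockpiling.** If a refill arrives before the previous supply is
  exhausted, its interval is shifted to start when the previous supply
  ends. The full refill is banked — shift, not truncation — so covered
  days are never double-counted and adherence is not underestimated for
  patients who refill early. Two 90-day dispensings at day 0 and day 60
  therefore cover [0, 90) and [90, 180).

All intervals are half-open `[start, end)` on calendar days, which makes
day counting unambiguous. The interval engine is validated against a
day-by-day bitmap oracle on randomized dispensing streams (1,000 streams
in the acceptance suite), and covered days are checked to be monotone in
added dispensings.

## Cohort extraction

A candidate becomes a second-line new user when all of the following hold:

1. a glaucoma diagnosis (ICD-10 H401 or H409, any date — claims extracts
   carry no reliable temporal anchoring for diagnoses, and unrelated codes
   are simply ignored);
2. an index event: the first claim of a fixed-combination product
   (**fixed** cohort), or the first day a second distinct-class
   monotherapy product is claimed while the first drug's coverage interval
   still contains that day (**unfixed** cohort). If both happen on the
   same day, fixed wins — a deterministic tie-break;
3. ≥ 365 days of single-class monotherapy immediately before index.
   Within-class product switches (latanoprost → tafluprost) do not break
   the run-in, and supply gaps up to the grace period are bridged;
4. no glaucoma surgery or laser procedure before index.

Patients with no database activity after the index date are assigned but
flagged `withdrawn` rather than silently dropped; analysis stages filter
on the flag. The exclusion ledger counts one rule per patient (the first
that fails, in the order above), so ledger counts plus assignments always
equal the candidate count.

## Adherence

`PDC(%) = covered days in [index, index + 365) / 365 × 100`, capped at
100. Only two-drug combination supply counts:

* fixed cohort: any fixed-combination product's interval (switching
  between fixed products of different class pairs keeps counting);
* unfixed cohort: by default a day counts only when **both** classes are
  concurrently supplied (`unfixed_day_rule = "both"`). The endpoint is
  adherence to the two-drug regimen, and joint coverage is the only
  reading under which a patient who abandons one bottle scores low. The
  `"either"` rule (union) is available because the alternative reading is
  defensible.
* days on and after the first day three distinct classes are concurrently
  supplied do not count — the two-drug therapy is considered withdrawn.

The adherence cutpoint is 80% a priori, with bins 80+, 60–79, 40–59,
20–39, < 20 (left-closed: 79.99 is 60–79). The 30-day grace period does
**not** add covered days by default: PDC counts prescription days, and
letting grace inflate the numerator would conflate the two endpoints. The
alternative is exposed as `pdc_count_grace = TRUE`, which extends each
supply run by up to 30 days into the following gap.

## Persistence

An episode runs from index until the first of:

* **gap** — supply is exhausted and the next qualifying refill arrives
  more than 30 days later (exactly 30 is not a discontinuation). The event
  time is the last covered day (supply end), matching the definition of
  persistence duration as last prescription date + prescription days. The
  gap clock is anchored at supply end by default; `gap_anchor =
  "dispense"` anchors it at the last dispense date instead, which is
  stricter for multi-bottle claims. An episode whose supply ends before
  day 365 with no qualifying refill afterwards is an event at supply end
  even when the supply end falls within 30 days of the horizon — only
  patients whose supply reaches the horizon are censored, at 365;
* **third drug added** — a claim creating three concurrent classes
  discontinues at its date (ties with a gap on the same day resolve to the
  third drug);
* **regimen changed** (product-subset mode only) — in the
  product-specific analyses (e.g. latanoprost/timolol only), any claim of
  an eye-drop product outside the index products ends the episode. In the
  main class-level mode, switching between two-drug regimens of different
  classes continues it.

Kaplan–Meier estimation and the log-rank test go through
`survival::survfit()` / `survival::survdiff()`; the package reports
pointwise 95% CIs on the complementary log-log scale (Greenwood variance),
which is stable near survival 0 and 1. Hall–Wellner simultaneous bands are
out of scope. Persistence rate at a time point is `100 × S(t)`, i.e. 100%
minus the cumulative discontinuation rate, read from the step function at
days 180 and 365. The product-limit arithmetic is verified against
hand-computed fixtures to 1e-12 and the log-rank statistic against a
brute-force risk-set computation.

## Statistical battery

Mean PDC contrasts use Welch's t-test by default — the two cohorts' PDC
standard deviations differ materially, and pooling is not warranted; a
pooled variant is a flag. Proportions use Pearson's χ² on the 2×2 table
without continuity correction. Significance for the study's family of
comparisons is judged at α/m with m = 9 (0.00556); a global-null
simulation in the acceptance suite confirms the family-wise error stays
controlled at 0.05.

Risk factors for nonadherence (PDC < 80) are screened with one univariate
logistic regression per covariate on that covariate's complete cases
(checkup variables are missing for many patients, and each variable keeps
its own n). Candidates at p < 0.1 enter a forward/backward stepwise
logistic model driven by likelihood-ratio p-values with entry and stay
thresholds of 0.05 — the classic defaults of the statistical environment
this style of selection comes from; both thresholds are arguments.
Odds ratios are reported with Wald 95% CIs. Constant covariates and
(quasi-)complete separation are detected and excluded with warnings;
aliased duplicates cannot enter twice because an aliased term never
improves the likelihood. Region of residence is an opaque categorical
covariate with a reference level; multi-level factors report a
likelihood-ratio p rather than a single OR.

## The synthetic generator

Real claims databases are proprietary, so the package ships a generator
(`generate_claims_data()`) whose defaults are the study conditions: 309
fixed / 329 unfixed patients; the observed index-regimen mix (78% PG/BB
among fixed, with latanoprost/timolol the most common product; PG+BB,
PG+AA and PG+CAI leading among unfixed); the observed five-bin adherence
profile per cohort; and covariates at the published means and rates, with
realistic missingness (about a third of HbA1c values missing).

Mechanism, per patient:

* a monotherapy run-in of 372–420 days dispensed every 30 days, the
  run-in drug's class consistent with the index regimen (PG monotherapy
  before a PG/BB combination, with 0.8 probability on the first class of
  the pair);
* an index regimen drawn from the mix; unfixed patients keep refilling
  the first drug in sync with the added one, with a two-bottle head start
  at index so the pair's joint coverage equals the added drug's coverage;
* latent nonadherence is Bernoulli with
  `logit(p) = α_cohort + log(1.606) × HbA1c`; α is solved numerically per
  cohort so the mean nonadherence rate matches the cohort's adherence
  profile. This is the only covariate–outcome link planted — everything
  else is independent noise, because nothing else is asserted;
* the number of 30-day supplies comes from the adherence profile:
  adherent patients refill through the full year; nonadherent patients
  draw a PDC bin and stop after the matching number of supplies (e.g.
  8–9 supplies for 60–79%). Inter-refill delays are zero-inflated
  geometric (on time with probability 0.7, else 1 + geometric(0.3) days,
  capped at 18). The cap keeps every delay inside the 30-day grace and
  inside the companion drug's supply lead, so delays thin coverage
  without ever causing an unintended discontinuation — which is what
  makes exact parameter recovery possible. `dropout_hazard` (default 0)
  adds an extra stopping hazard for stress tests; with a saturated
  adherence profile, on-time refills and zero dropout, every patient's
  PDC is exactly 100;
* optional decoy patients (the `contamination` fraction) violate one
  inclusion rule each — short run-in, prior laser surgery, or no
  post-index database activity — to exercise the cohort filter and the
  withdrawal flag.

A `truth` table records, per patient, the planted covered days, PDC,
adherent flag, latent nonadherence, discontinuation day and event flag
(the grace rule applied analytically to the planted schedule), plus the
true HbA1c before missingness. The acceptance suite verifies that the
pipeline recovers the cohort sizes exactly, reproduces PDC and episode
durations day-for-day, and re-estimates the planted HbA1c odds ratio
within ±15% on a 10,000-patient cohort using its own univariate logistic.

What the generator does **not** emulate: real refill behaviour (the true
inter-refill delay distribution is unknowable from published summaries;
the delay model is a configuration choice, not an estimate), switching
and add-on trajectories (post-index regimens stay fixed, so switching
categories beyond "continued" and "discontinued" are exercised by
constructed fixtures rather than by the generator), within-bin PDC shape,
seasonality, pricing, enrollment gaps, and death or disenrollment beyond
the simple no-post-index decoy. Passing the recovery tests therefore
shows the pipeline's rules are implemented correctly, not that the
generator reproduces real-world behaviour.

## Numerical choices and scale

Dates are calendar days (no times); intervals half-open; interval
arithmetic is exact integer work, so oracle comparisons use equality, not
tolerances. Product-limit fixtures are checked to 1e-12; χ² against its
closed form to 1e-9. Problem sizes in the test suite were chosen as the
smallest that make each check sharp: 1,000 random streams for the bitmap
equivalence, 10,000 patients for odds-ratio recovery (log-OR standard
error ≈ 0.05, comfortably inside the ±15% band), 500 replicates for the
family-wise error simulation, and study-sized cohorts (309/329)
everywhere the design is exercised end to end.

## Known limitations

* The both-eyes halving rule and the unfixed joint-coverage rule are
  interpretations of underspecified conventions; both are flags, and
  conclusions that depend on them should be checked under the
  alternatives.
* Stepwise selection on p-values is implemented faithfully, including its
  known appetite for occasional spurious survivors at moderate sample
  sizes; the worked example in the README shows one.
* The cohort builder models eligibility from claims presence only;
  enrollment spans and benefit changes are not modeled.
* Laterality (which eye) is not tracked; the 7-bottle rule is the only
  both-eyes signal.
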