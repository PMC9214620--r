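---
title: "Methods: medication-wide association screening for multiple birth"
author: "medwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medication-wide association screening for multiple birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screening problem

Multiple birth (MB) — delivery of twins, triplets or higher-order
multiples — is strongly linked to assisted reproductive technology (ART)
and fertility treatment, but little is known about other prescription
medications taken around conception. A medication-wide association study
(MWAS) turns the usual pharmacoepidemiology question around: instead of
testing one drug against many outcomes, it screens *every* medication
available in an EHR delivery cohort against one outcome, here MB, as a
hypothesis-generating device. `medwas` implements that screen end to end,
together with a synthetic EHR generator so the whole pipeline is testable
without access to protected health records.

## Cohort and exposure construction

The unit of analysis is the **delivery**, not the patient; a patient with
two deliveries contributes two independent rows (the screen fits plain
logistic models with no clustering adjustment, so repeat deliveries are a
documented limitation, not a modelled feature).

All date logic is day-granularity ISO-8601 arithmetic anchored at the
recorded delivery date:

* **Outcome.** MB = 1 iff an MB-list ICD code for the patient is dated
  *exactly on* the delivery date. MB codes during pregnancy are ignored,
  so multifetal pregnancies that do not end in a multiple delivery
  (vanishing twin) never count. "At the time of delivery" is
  operationalized as date equality because encounter linkage is not part
  of the data model; a `tolerance_days` knob (default 0) widens the match
  symmetrically for sources with imprecise coding dates.
* **Covariates.** ART-resulting-pregnancy and infertility indicators are
  1 iff a matching code is dated in `[delivery − 315 d, delivery]`, both
  endpoints inclusive. The literature phrases the window's right edge as
  the *expected* delivery date; that date is not observable in this data
  model, so the recorded delivery date stands in for it. This is the one
  deliberate approximation in the builders and is surfaced here rather
  than hidden.
* **Exposure.** A delivery is exposed to a medication iff the patient has
  at least one order of it dated in `[delivery − 275 d, delivery − 215 d]`,
  both endpoints inclusive — a window bracketing conception and the early
  first trimester for term and most preterm deliveries. Inclusivity at
  both endpoints is a choice (the defining phrase "from 275 to 215 days"
  does not settle it); it is symmetric, tested at the boundary, and
  config-overridable. Orders map to ingredient-level medication ids by
  case-insensitive exact match on an annotation's brand+generic name set;
  real terminology normalization (RxNorm) is upstream of this package.
* **Filter.** Medications prescribed to fewer than 5 *distinct patients*
  inside the window are dropped. The retained count `m` is frozen as the
  Bonferroni family size before any model is fitted, so non-estimable
  medications discovered during fitting do not shrink the family.

Code lists match exact `(system, code)` pairs, plus whole families via
dot-terminated prefixes (`"O30."` covers `O30` and every `O30.*` child).
The shipped MB/ART/infertility lists are editable defaults, not an
authoritative clinical artifact.

## The screen

For each retained medication $j$ the package fits

$$\operatorname{logit} P(\text{MB}_i = 1) = \beta_0 + \beta_j E_{ij} + \boldsymbol{\gamma}^\top \mathbf{z}_i$$

where $E_{ij}$ is the binary exposure and $\mathbf{z}_i$ is empty
(model 1), maternal age (model 2), or maternal age + ART + infertility
(model 3). The control group for each medication is every other delivery,
including the medication-unexposed majority.

Numerical choices:

* **Fitting** is iteratively reweighted least squares written in the
  package (the screen statistic is the package's contribution; generic
  GLM routines are used only as independent oracles in the tests).
  Convergence: max absolute coefficient change `< 1e-8` within 100
  iterations.
* **Intervals and tests** are Wald: `exp(beta ± 1.96·se)` and a two-sided
  z test, with 1.96 (not a t quantile) as is standard for large-sample
  GLMs. Profile-likelihood intervals are deliberately not offered.
* **Separation** is detected (coefficients drifting past ±30 log-odds, or
  failure to converge) and *flagged*, never penalized: a Firth-type fix
  would silently change every reported OR. Flagged medications keep their
  exposure counts but report `NA` effect estimates and count as negative
  significance calls — the same practical outcome as the near-infinite
  Wald SE a generic GLM reports in that situation.
* **Rank deficiency** (e.g. a covariate constant across deliveries) is
  handled by pivoted-QR aliasing, exactly as standard GLM software does:
  the aliased column gets `NA`, the others are unchanged.
* **Multiplicity**: `p_bonf = min(1, m·p)`; Bonferroni-significant
  implies nominally significant by construction, and the report renderer
  refuses artifacts violating that invariant.
* **Ordering**: results are sorted by medication id so reruns are
  byte-identical.

## Validation against a gold standard

Fertility/ART-treatment medications are assumed truly associated with MB
and serve as the gold standard. Calls (nominal or Bonferroni) are scored
as a binary classifier: TP/FP/FN/TN over all scored medications, then
sensitivity, specificity, accuracy, precision and F1. A metric with a
zero denominator is reported as *undefined* (`NA`), never coerced to 0.

Full precision is kept internally. The 2-dp presentation layer follows
the convention of published screen-performance tables: F1 is recomputed
from the *rounded* precision and sensitivity. The two conventions can
differ in the second decimal (e.g. counts 11/15/4/93 give full-precision
F1 0.537 but presentation F1 0.53); tests pin the presentation values.

## The synthetic world

`simulation_config()` defaults state one world and the tests never move
it after the fact:

* 63,334 deliveries; maternal age truncated-normal 29.5 (SD 6.1) on
  [12, 55] years; ART prevalence 0.39%; infertility 0.08%; marginal MB
  rate 2.47%.
* 123 medications with independent per-medication exposure draws at a
  common prevalence solved from $1-(1-p)^{123} = 0.0296$, so the
  any-exposure margin matches 2.96%. An optional correlated-block hook
  (shared Bernoulli draw with mixing weight `rho`) exists for stress
  tests only.
* Outcome model: `logit P = baseline + beta_age·age + beta_art·ART +
  beta_inf·INF + Σ beta_m·exposure_m`. Age enters linearly (no published
  functional form to copy). Defaults: `beta_age = log(1.05)` per year,
  `beta_art = log(8)`, `beta_inf = log(3)` — round values of the right
  order for known MB risk factors — and a planted `log(6)` on each of the
  15 fertility medications, a free parameter since no reference effect
  sizes are published. The intercept is calibrated by quadrature +
  root-finding so the marginal MB rate hits its target under all of the
  above.
* Exposed deliveries get an order dated uniformly inside the exposure
  window; ART/infertility codes uniformly inside the lookback; the MB
  code exactly at delivery. `emit_decoys()` then appends records a
  correct builder must ignore: mid-pregnancy MB codes on non-MB
  deliveries, covariate codes older than 315 days, and orders outside the
  exposure window (including post-delivery ones).

What the generator does **not** emulate: realistic ICD code frequency
distributions, co-prescription structure, confounding by indication
(exposures are drawn independently of age/ART/infertility, so adjusted
and unadjusted ORs estimate the same quantity up to non-collapsibility),
skewed per-medication exposure counts, and inter-pregnancy spacing
(multi-delivery patients use fixed 500-day gaps behind a flag). A green
test suite therefore establishes that the pipeline computes the stated
model correctly — not that the screen is robust to real EHR messiness.

One emergent and realistic property deserves note: at the stated margins
an average medication has only ~15 exposed deliveries and a 2.5% outcome
rate, so most *null* medications see zero MB events among the exposed and
their MLE diverges to $-\infty$. Those fits are flagged non-converged and
count as negative calls. This is the honest small-count regime of a
rare-exposure/rare-outcome screen, and it is why the property-based
calibration tests use higher exposure prevalences (below) rather than
pretending Wald asymptotics hold at 15 exposed.

## Calibration and recovery checks (settings fixed a priori)

* **Type-I error**: 20 seeds × 123 null medications, n = 20,000,
  exposure prevalence 0.10 (≈ 2,000 exposed, ≈ 50 exposed MB events, well
  inside the Wald regime); the nominal rejection fraction must sit within
  3 binomial SDs of 0.05.
* **Parameter recovery**: planted OR 6 at prevalence 0.02, n = 20,000
  (≥ 30 exposed guaranteed, ≈ 50 exposed events); the 95% Wald CI must
  cover 6 in ≥ 93 of 100 replicates.
* **Oracle agreement**: the IRLS fitter must match a reference GLM (run
  at `epsilon = 1e-12`) to ≤ 1e-6 on 50 seeded datasets, and the model-1
  OR must equal the 2×2 cross-product ratio on 1,000 random tables.

Both prevalence choices were fixed from the asymptotics argument above
before any acceptance run, not adjusted afterwards.

## Known limitations

* No clustering adjustment for repeat deliveries; no dose, form, route,
  duration or within-window timing; no over-the-counter capture.
* Exposure windows keyed to the recorded delivery date drift for very
  preterm deliveries (the window may then predate conception by more
  than intended).
* The gold standard is itself imperfect — fertility medications can be
  flagged through reverse causation, and the screen is hypothesis
  generation, not causal inference.
* Bonferroni is the only multiplicity control offered, by design.
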