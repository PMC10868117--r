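---
title: "Methods: auditing diagnosis codes against laboratory-based labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing diagnosis codes against laboratory-based labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diagnosis codes attached to hospital admissions are routinely used as
features, outcome labels and cohort filters for clinical machine-learning
models and multicenter network studies. But codes are produced by
institution-specific coding workflows and unit-specific clinical
practice, so their completeness can differ sharply between hospitals even
when the patients look the same. For outcomes that have a laboratory
definition — acute kidney injury (hypercreatinemia), hyperkalemia,
hypoglycemia, hyponatremia, anemia, neutropenia, thrombocytopenia — the
lab result itself supplies a pragmatic gold standard against which the
codes can be audited.

`labconcord` implements that audit as a reusable pipeline: build
per-admission labels from lab extrema and from diagnosis codes, quantify
their agreement, estimate how label odds differ between institutions
while respecting repeat admissions per patient, and compare label
prevalence across hospital units. Because real pediatric EHR extracts of
this kind are access-restricted, the package also ships a synthetic
two-institution generator with known ground truth, which is what the
test suite and acceptance script exercise end to end.

## Labels

For each admission and outcome, five binary labels are evaluated:

* **abnormal** — the admission extremum of the outcome's analyte lies
  outside the institution- and age-group-specific reference range, on
  the outcome's side only (above *or* below, never both);
* **mild / moderate / severe** — the extremum crosses fixed severity
  cutoffs. Severity is *nested*: a severe admission is also counted as
  moderate and mild. `abnormal` is an independent label and does not
  nest with the triple (with default cutoffs the mild count can exceed
  the abnormal count, e.g. for anemia where the mild cutoff sits above
  some reference-range lower bounds);
* **diagnosis** — at least one diagnosis record matches the outcome's
  code set (exact or prefix match per entry).

The extremum is the admission **maximum** for above-direction outcomes
(creatinine for AKI, potassium for hyperkalemia) and the **minimum**
otherwise. Values are first normalized to canonical units (creatinine
µmol/L; potassium, sodium, glucose mmol/L; ANC and platelets 10⁹/L;
hemoglobin g/L); creatinine mg/dL converts with the factor
10000/113.12 ≈ 88.4 from its molar mass. Comparisons at cutoffs are
strict (`<` for below, `>` for above), reading "below the range" as
strictly below; both the cutoffs and this convention live in editable
configuration (`inst/extdata/severity_thresholds.yaml`), not code.

Admissions with no measurement of an analyte are labeled negative, not
excluded, so prevalence denominators are all admissions of the cohort.
This mirrors how such audits are reported but makes "lab-negative"
conflate "tested normal" with "never tested" — a measurement-
ascertainment caveat that the synthetic generator reproduces
deliberately (see below).

Default severity cutoffs are drawn from common guideline families
(hypoglycemia < 3.9/3.0/2.2 mmol/L; hyponatremia < 135/130/125 mmol/L;
hyperkalemia > 5.5/6.0/6.5 mmol/L; anemia hemoglobin < 110/90/70 g/L;
neutropenia < 1.5/1.0/0.5 × 10⁹/L; thrombocytopenia < 150/100/50 ×
10⁹/L; AKI creatinine above 1.5×/2×/3× the age-group upper reference
bound). They are sensible defaults for a pediatric inpatient audit, not
authoritative clinical rules; deployments should review them. The same
holds for the ICD-10 prefix code sets and for the shipped reference-range
table, which is synthetic (two plausible pediatric institutions whose
ranges differ, as real institutional ranges do) and is labelled as such
in its filename.

Pediatric age groups follow the NICHD stratification. The published
month/year group labels are ambiguous at their edges, so boundaries are
fixed at day resolution — infant [28 d, 366 d), toddler [366 d, 3 y),
early childhood [3 y, 6 y), middle childhood [6 y, 12 y), early
adolescence [12 y, 18 y) with a year of 365.25 days — and are exposed in
`age_group_breaks()` rather than hard-coded. Eligibility keeps ages from
28 days (neonates aged 1–27 days are excluded, since institutions differ
in whether they see healthy newborns) to just under 18 years, inside a
closed admission-date window; whether the 18-year boundary is evaluated
in days or whole years is a configuration choice (`days_per_year`).

## Agreement statistics

With the diagnosis label as the "test" and one lab label as the gold
standard, each outcome yields a 2×2 table (tp, fp, fn, tn; n their sum).
The package reports:

* Cohen's κ = (p₀ − pₑ)/(1 − pₑ), p₀ = (tp + tn)/n,
  pₑ = [(tp+fn)(tp+fp) + (fp+tn)(fn+tn)]/n²; undefined (an explicit
  error) when a margin is degenerate;
* sensitivity tp/(tp+fn) and specificity tn/(fp+tn), with zero
  denominators erroring rather than returning NaN;
* summaries over outcomes (mean/SD and median/IQR/range) per cohort ×
  severity, with undefined metrics dropped and counted, never imputed.

Percentages in rendered tables are rounded half-away-from-zero to one
decimal, the convention of clinical prevalence tables; raw artifacts
keep full precision.

## Institution odds ratios

For each outcome × label type (7 × 5 = 35 evaluations), the label is
regressed on institution and pediatric age group with a Gaussian random
intercept per patient, accounting for correlated repeat admissions:

logit P(yᵢⱼ = 1) = β₀ + β₁·institutionᵢ + γ·age-groupᵢⱼ + bᵢ,
bᵢ ~ N(0, σ²).

Estimation integrates the random intercept out of the logistic
likelihood by adaptive Gauss–Hermite quadrature (`lme4::glmer`, default
15 nodes; configurable). Given the number of simultaneous evaluations,
intervals are Wald at the 99.9% level (z ≈ 3.2905) on the log-odds
scale, exponentiated for odds ratios; no p-values are produced. Wald
rather than profile intervals is a deliberate reporting choice, matching
common mixed-model practice. The reference institution is the first
sorted level unless `ref` is given, so OR > 1 means higher odds at the
comparator site. Per-label fit failures are recorded
(`converged = FALSE`) and skipped, never fatal, so the 35-row shape of
the output is stable.

Two properties pin the estimation contract down in the tests: with no
true between-patient variance, fits that land on the σ = 0 boundary
reproduce the plain logistic MLE to 10⁻⁴ on the log-odds scale; and
doubling the quadrature nodes from 15 to 30 moves the institution
log-OR by less than 10⁻³. An independent adaptive-quadrature evaluator
(`agq_loglik()`, written separately from the fitting path) reproduces
the fitted marginal log-likelihood, providing a second route onto the
same quantity. Lab-testing frequency (tests per inpatient day, with
denominator max(1, discharge − admit); a raw per-admission count is
available behind an option) is compared between institutions with the
analogous Gaussian random-intercept model (`lme4::lmer`, REML by
default).

## Hospital-unit concordance

Units differ in case mix and in coding behavior. For each unit, the
package computes weighted label proportions in which an admission
visiting k distinct units contributes weight 1/k to each — conserving
each admission's total contribution at exactly 1, which is why this
weighting was chosen over duration-based alternatives (stay durations
per unit are not part of the data model). The lab proportion is computed
per severity level and averaged across the four levels; Spearman's ρ
(Pearson correlation of midranks) between unit lab and diagnosis
proportions then summarizes within-institution coding consistency. A
flag (`per_severity = TRUE`) instead computes ρ per severity and
averages, for sensitivity analysis.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with every parameter explicit in `simulation_config()`:

* patients per institution, each with 1 + Poisson(λ) admissions (repeat
  admissions induce the within-patient correlation the random intercept
  models); λ defaults to 0.62/0.70, giving ≈1.6–1.7 admissions per
  patient;
* NICHD age-group mix, length of stay 1 + Poisson(1.6–2.0) days and
  in-hospital mortality 0.5–0.8% — the demographic profile of a large
  two-institution pediatric inpatient study, scaled to desk size
  (preset default 3600 + 1500 patients, ≈8300 admissions; tests use
  smaller cohorts and the closed-form oracle uses ≈50,000 admissions);
* a latent severity stratum per admission × outcome (none / mild band /
  moderate band / severe band), with lab values uniform between adjacent
  cutoffs within a band (the severe band extends one cutoff-width beyond
  the severe cutoff) and truncated-normal inside the reference range for
  non-cases — the simplest distributions that make severity labels
  exactly invertible for truth checking;
* per-day, per-analyte testing probabilities (an admission with no
  qualifying draw is lab-negative regardless of its stratum, reproducing
  the ascertainment caveat);
* diagnosis codes emitted with probability
  logit⁻¹(logit(sens_stratum) + bᵢ + u_unit) for positive strata and a
  flat false-positive rate otherwise. Coding heterogeneity enters on the
  logit scale so the association model is correctly specified under the
  generator (clean parameter recovery); the per-unit shift u_unit is the
  misspecification toggle used to reproduce low within-institution
  unit-level correlation.

A truth ledger records stratum, tested and coded per admission ×
outcome, and `expected_metrics()` gives the analytic prevalence,
sensitivity, specificity and κ of the diagnosis label against each
severity level: with stratum masses π, marginal coding sensitivities a,
false-positive rate f and testing probability p_t, the gold-standard
prevalence at level s is p = p_t·Σ_{b≥s}π_b, sensitivity is the
π-weighted mean of a over bands ≥ s, and the effective false-positive
rate among negatives includes both coded sub-threshold bands and coded
but untested positives — which is why specificity degrades as testing
thins out. κ follows from p₀ and pₑ as above. With patient SD > 0 the
stratum sensitivities are marginalized by Gauss–Hermite quadrature;
per-unit effects are not covered by the closed form (the oracle configs
set them to zero), and the `abnormal` label has no closed form because
its expectation depends on where range bounds sit relative to cutoffs.

Three presets encode the study contrasts: `null` (identical
institutions; ORs ≈ 1), `similar-labs-different-coding` (identical lab
generation, coding sensitivity ~7-fold higher and false-positive rate
higher at site_b: diagnosis-label ORs far exceed lab-label ORs), and
`unit-heterogeneous-coding` (site_a adds a per-unit coding shift of SD
1.5 logits: its unit-level ρ drops). Generator parameters are the
package's own constructs — real coding behavior has no agreed generative
model — and all were fixed as scenario definitions, not fitted to any
dataset.

What passing tests therefore show is that the *pipeline* is correct
under a faithful but idealized data-generating process; they cannot show
that any real institution's coding behaves like the generator. Features
of real data deliberately not simulated: longitudinal physiology within
an admission, severity-dependent testing intensity, medications and
free text, inter-analyte correlation, seasonal admission patterns.

## Numerical and degenerate-input choices

* Counts are coerced to doubles before κ's pₑ product to avoid 32-bit
  integer overflow at n ≈ 50,000.
* κ, sensitivity and specificity raise explicit errors on degenerate
  tables in the low-level API; the cohort-level `concordance_metrics()`
  converts those to `NA` so summaries can drop and count them.
* Ties in Spearman's ρ use midranks; constant vectors error.
* Truncated-normal draws use inverse-CDF sampling (no rejection), so
  generation is deterministic given the seed with a fixed number of
  RNG draws.
* Orphan rows, type-coercion failures, inverted dates and negative ages
  are dropped with row-level entries in a machine-readable violation
  report rather than failing the whole read.
* Mixed-model fits flag singular variance estimates and optimizer
  non-convergence; `or_by_institution()` records per-row failures and
  continues.

## Known limitations

The AKI label is plain hypercreatinemia against a multiple of the upper
reference bound — no delta-creatinine (KDIGO-style) staging. Code-set
matching is prefix/exact on code strings; no vocabulary mapping service
is consulted. The abnormal label depends on the supplied reference
ranges, and the shipped table is synthetic. Regressions are restricted
to two-institution pediatric comparisons by design; adult cohorts are
supported descriptively (labels, prevalence) when adult reference
ranges are provided.
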