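# labconcord

Diagnosis codes attached to hospital admissions are widely used as
features, outcome labels and cohort filters for clinical machine-learning
models — yet how completely an institution codes a condition varies with
its coding workflow and its units' clinical practice. For outcomes that
have a laboratory definition, the lab result itself provides a pragmatic
gold standard against which the codes can be audited. `labconcord` is an
R package for exactly that audit, aimed at clinical informaticians and
biostatisticians working with OMOP-style inpatient extracts.

For each admission and each of seven outcomes (acute kidney injury via
hypercreatinemia, hyperkalemia, hypoglycemia, hyponatremia, anemia,
neutropenia, thrombocytopenia) the package derives five binary labels:

* **abnormal** — the admission extremum of the analyte falls outside the
  institution- and age-group-specific reference range, on the outcome's
  side only;
* **mild / moderate / severe** — the extremum crosses configurable
  severity cutoffs, with severity *nested* (severe ⊆ moderate ⊆ mild);
* **diagnosis** — at least one diagnosis record matches the outcome's
  code set (exact or prefix).

Agreement of the diagnosis label against each lab gold standard is
summarized by Cohen's κ = (p₀ − pₑ)/(1 − pₑ), sensitivity tp/(tp+fn) and
specificity tn/(fp+tn). Institution effects are estimated per outcome ×
label type (35 evaluations) by random-intercept logistic regression,

&nbsp;&nbsp;logit P(yᵢⱼ = 1) = β₀ + β₁·institutionᵢ + γ·age-groupᵢⱼ + bᵢ, bᵢ ~ N(0, σ²),

fitted by adaptive Gauss–Hermite quadrature with Wald 99.9% intervals on
exp(β₁). Per-hospital-unit concordance uses weighted label proportions
(an admission visiting k units contributes 1/k to each) compared by
Spearman's ρ. Because the pediatric EHR data such audits run on are
access-restricted, the package includes a seeded synthetic
two-institution generator with a truth ledger and closed-form expected
metrics, which is what the tests and the acceptance script exercise.

## Worked example

Simulate two institutions with identical lab-generating processes but an
order-of-magnitude difference in coding sensitivity, then audit the
codes against the labs:

```r
library(labconcord)

cfg <- scenario_presets(
  n_patients = c(site_a = 1000, site_b = 700)
)[["similar-labs-different-coding"]]
sim  <- generate_cohort(cfg, seed = 42)
sim$bundle
#> <cohort_bundle>
#>   admissions          2745 rows
#>   measurements       12525 rows
#>   diagnoses           1170 rows
#>   unit_stays          3643 rows
#>   reference_ranges      70 rows
#>   institutions: site_a (1587), site_b (1158)
#>   violations: 0

labs <- label_cohort(sim$bundle, cfg$definitions)
prev <- prevalence_table(labs)
subset(prev, outcome == "anemia" & severity %in% c("mild", "diagnosis"))
#>    cohort  severity outcome n_admissions count  pct
#> 9  site_a      mild  anemia         1587   300 18.9
#> 30 site_a diagnosis  anemia         1587    80  5.0
#> 44 site_b      mild  anemia         1158   412 35.6
#> 65 site_b diagnosis  anemia         1158   319 27.5
```

The lab-based mild-anemia prevalences differ moderately (18.9% vs
35.6%, driven by testing intensity and length of stay), but the
diagnosis-label prevalences differ five-fold — the coding gap. Agreement
with the lab gold standard is correspondingly asymmetric:

```r
m <- concordance_metrics(labs)
s <- summarize_metrics(m, "kappa")
s[s$severity == "mild", c("cohort", "severity", "mean", "median", "min", "max")]
#>   cohort severity      mean    median        min       max
#> 3 site_a     mild 0.1433040 0.1437282 0.06449906 0.1947459
#> 4 site_b     mild 0.4193485 0.4186458 0.32654955 0.5094052

ors <- or_by_institution(labs)   # 35 random-intercept logistic fits
subset(ors, outcome == "anemia")[, c("label_type", "or", "ci_low", "ci_high")]
#>    label_type   or ci_low ci_high
#> 6    abnormal 2.29   1.70    3.07
#> 7        mild 2.37   1.77    3.18
#> 8    moderate 1.95   1.40    2.73
#> 9      severe 2.33   1.35    4.04
#> 10  diagnosis 8.02   4.85   13.28
```

Mean mild-severity κ is 0.14 at the low-coding site versus 0.42 at the
high-coding site, and the institution odds ratio for the anemia
*diagnosis* label (8.0, 99.9% CI 4.9–13.3) dwarfs every lab-label OR
(≈2) — the signature of a coding-practice difference that test results
alone cannot explain. `run_pipeline(cfg, "out/")` runs the same stages
end to end and writes delimited artifacts, a rendered prevalence/OR
table and a JSON run manifest; `inst/scripts/labconcord` wraps it for
the shell.

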