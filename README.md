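# temporeg

Quantifying the **temporal regularity (TR)** of primary-care visits for
chronic-disease patients in HMO-style electronic health record extracts, and
profiling clinics on case-mix-adjusted regularity.

Patients with chronic conditions benefit from *evenly spaced* primary-care
follow-up, not just frequent follow-up. Three patients may each see their
family physician six times in a year: one precisely every 60 days, one at
somewhat uneven intervals, one in bursts separated by long gaps. `temporeg`
measures that difference, models who tends to receive the least-regular
care, and asks which clinics have more (or fewer) such patients than their
case mix predicts — the operational questions behind outreach programs for
proactive chronic-disease care.

## The statistic and the models

**Patient level.** For each patient with at least three qualifying
primary-care visits (family physician, ≥ 5 minutes chart-open time, any
modality) in the two-year study window, TR is the coefficient of variation
of the inter-visit intervals *g₁ … gₖ* (whole days, same-day visits
collapsed):

```
TR = COV = SD(g) / mean(g)
```

TR = 0 means perfectly even spacing; larger TR means less regular care, and
the COV is comparable across patients with different visit frequencies.
Because the TR distribution is strongly non-normal (Jarque–Bera test on raw
and log scale), it is dichotomized: patients in the least-regular quintile
(TR at or above the empirical 80th percentile, or a fixed threshold such as
1.2) versus all others.

**Risk model.** Bivariate and fully adjusted logistic regressions predict
least-regular membership from age band, sex, ethnic/cultural group, region,
area-SES group, kidney function (eGFR category, lowest value with fallback
and mode imputation), current smoking, and 23 ICD-phenotyped chronic
conditions. Fitting is by IRLS with Wald 95% CIs; discrimination is
summarized by the c-statistic.

**Clinic level.** For each clinic with ≥ 30 eligible patients, `O` is the
observed number of least-regular patients and `E` the sum of
model-predicted probabilities; `O/E` is the case-mix-adjusted regularity
score (1 = as expected, < 1 = fewer irregular patients than expected).

**Synthetic cohort.** Because real HMO claims data cannot be shipped, the
package includes a seeded generator that emulates such an extract:
Table-style marginal prevalences, concrete ICD-9/ICD-10 diagnosis codes
drawn from the packaged code lists, eligibility failures (age < 40, no
index condition, hemodialysis, < 3 visits), and a gamma-renewal visit
process whose target COV is calibrated so that the probability of falling
in the least-regular group follows a logistic model with known
ground-truth log-odds plus clinic-level effects. Every downstream stage is
therefore testable against known truth.

## Worked example

```r
library(temporeg)

cfg    <- generator_config(n_patients = 8000, n_clinics = 60, seed = 2024)
bundle <- generate_cohort(cfg)          # synthetic 5-table extract
cohort <- build_cohort(bundle)          # eligibility filters + phenotyping
cohort$attrition
#>                   filter n_before n_removed n_after
#> 1:          age_under_40     8000       301    7699
#> 2:    no_index_condition     7699       311    7388
#> 3: fewer_than_min_visits     7388       368    7020
#> 4:          hemodialysis     7020       151    6869

scored <- score_cohort(cohort)          # TR + least-regular quintile
summary(scored$scores$tr)               # min 0.13, median 0.95, max 2.21
jarque_bera(scored$scores$tr, "TR")
#> Jarque-Bera normality check for TR (n = 6869)
#>   skewness 0.6810, kurtosis 4.1006, JB = 877.672, p = 2.61e-191

fit <- adjusted_model(scored$patients)$fit
fit$c_statistic                         # 0.583
or_table(fit)[term %in% c("cond:diabetes", "cond:osteoporosis")]
#>                 term coefficient ... or ci_low ci_high marker
#> 1:     cond:diabetes       ...  0.68   0.57    0.81      †
#> 2: cond:osteoporosis       ...  0.82   0.70    0.96      *
```

Diabetic and osteoporotic patients are markedly *less* likely to be in the
least-regular group (the generator's ground-truth effects, recovered by the
model), TR is right-skewed and clearly non-normal, and the model's
discrimination is modest — the expected behavior for this outcome.

Clinic profiling on the same run:

```r
m  <- adjusted_model(scored$patients)
cc <- clinic_counts(scored$patients$clinic_id, scored$patients$flagged,
                    m$probabilities[as.character(scored$patients$patient_id)])
oe <- oe_scores(cc, min_n = 30)
profile_summary(oe$scores)
#> 50 clinics profiled (10 excluded); O/E 0.41-1.51; 13 (26%) within 0.90-1.10
```

The whole chain is also available as one call
(`run_pipeline(run_config(...))`), which writes every stage artifact plus a
markdown report and a checksummed manifest, and as a command-line tool
(`inst/cli/temporeg.R` with `simulate | build | score | model | profile |
report | run-all` subcommands).

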