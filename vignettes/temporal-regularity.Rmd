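---
title: "Measuring and modelling the temporal regularity of primary care"
author: "temporeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling the temporal regularity of primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporeg)
```

## The problem

Continuity of care is usually discussed as *seeing the same doctor*.
Temporal regularity (TR) is the orthogonal axis: *seeing the doctor at
even intervals*. For chronic-disease patients, evenly spaced follow-up
creates opportunities for proactive care that a burst of visits followed by
a long gap does not, even at the same visit count. `temporeg` implements a
complete analytic chain for this construct on HMO-style EHR extracts:
cohort construction, the TR statistic, a patient-level risk model for
least-regular care, and case-mix-adjusted clinic profiling — plus a
synthetic-extract generator with known ground truth, because real claims
data of this kind are proprietary and cannot travel with the package.

## The TR statistic

For a patient with qualifying visit dates $t_1 < \dots < t_n$ ($n \ge 3$),
the inter-visit intervals are $g_i = t_{i+1} - t_i$ in whole days and

$$\mathrm{TR} = \frac{\mathrm{SD}(g)}{\overline{g}}.$$

TR is dimensionless and scale-free: a patient seen every 30 days and one
seen every 90 days both score 0 if perfectly regular, so patients with
different visit frequencies are comparable. Higher TR = less regular care.

Numerical conventions, all switchable where noted:

* **SD convention.** The sample SD ($n-1$ denominator) is the default;
  `sd_type = "population"` selects the $n$ denominator. With the small
  per-patient interval counts typical here the choice matters little, but
  it is surfaced rather than buried.
* **Same-day visits** collapse to one date before intervals are taken; a
  zero-day interval would otherwise put probability mass at COV
  singularities.
* **Intervals are whole days**; visit timestamps below day resolution are
  not modelled.

Because the TR distribution is strongly right-skewed (and remains
non-normal after a log transform — both checks are run with the
Jarque–Bera statistic, $JB = \frac{n}{6}(S^2 + \frac{(K-3)^2}{4})$ with
moment-based skewness $S$ and kurtosis $K$, $\chi^2_2$ reference, plus Q-Q
pairs), linear regression on TR is inappropriate. The analysis therefore
dichotomizes: the **least-regular quintile** (TR at or above the empirical
80th percentile; linear-interpolation quantile, the default convention in
mainstream statistical software) versus the rest. The flag rule is
inclusive (`TR >= threshold`), and a fixed threshold (default 1.2, a
typical data-derived quintile cut for cohorts like this) is available as
`rule = "fixed_threshold"`.

## Cohort construction

The extract comprises five delimited tables (demographics, visits,
diagnoses, labs, procedures). Eligibility, applied in order with an
attrition log:

1. **Age 40+**, with age computed as `2015 - birth_year` — patient-level
   variables are anchored to the year before the observation period, so
   birth years 1966–1975 form the 40–49 band.
2. **At least one index condition** — heart failure, chronic lung disease,
   or diabetes — phenotyped as *at least one* diagnosis code matching the
   condition's code list during 2016–2019.
3. **At least three qualifying visits** in 2018–2019: family physician,
   duration (chart-open time) ≥ 5 minutes, any modality (in person, video,
   phone, text). Shorter contacts are mostly prescription refills and do
   not constitute meaningful clinical encounters.
4. **No hemodialysis, even once, in 2015–2019**: dialysis patients see
   physicians on a fixed schedule, so the TR construct does not apply.

The retained set is invariant to filter order; only the attrition log
depends on it.

**Code lists.** Conditions are defined by ICD-9-CM lists (physical
conditions) and ICD-10 lists (mental health conditions) shipped as a
human-editable YAML resource. The pattern grammar supports literal codes
(`714.0`), `x`-suffixed prefixes (`427.3x`, matching the bare stem too,
since real data contain un-suffixed codes), bare roots (`173`, the whole
family), inclusive root ranges (`140-239`), and decimal ranges
(`209.40-209.9x`), with `BUT NOT` exclusion arms. Matching ignores case; a
code must match an include pattern and no exclude pattern.

**Kidney function** is taken directly from eGFR labs rather than codes:
the category (60+ / 45–59 / 30–44 / <30) of the lowest value in 2018–2019,
falling back to 2016–2017, and finally imputing the mode (60+) when no
value exists. **Smoking** comes from the demographics table's
current-smoker field, never from codes — direct registry fields capture
far more smokers.

## The risk model

A logistic model predicts least-regular membership. Categorical predictors
are encoded as indicators against fixed reference levels (age 40–49,
female, General population, Central region, Highest SES, eGFR 60+, absence
of each condition). Fitting is by iteratively reweighted least squares
with step-halving, so the deviance trace is non-increasing; standard
errors are Wald (observed information), intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. Separation is signalled, not
fatal: when any coefficient magnitude exceeds 15 (or the iteration cap is
reached) the fit is marked non-converged and partial results are returned
with a warning — synthetic cohorts with rare conditions at small $n$ do
hit this. There is no multiple-testing adjustment; p-values are flagged at
0.05 and 0.001. Bivariate (single-predictor) models mirror an unadjusted
column next to the adjusted one.

The c-statistic — the probability that a random flagged patient outranks a
random unflagged one, ties counting one half — is computed by the rank
method in $O(n \log n)$ and reported **in-sample**, the usual convention
in case-mix adjustment work (the package does not cross-validate it; with
~40 parameters and tens of thousands of observations, optimism is
negligible).

## Clinic profiling

With predicted probabilities $\hat p_i$ from the adjusted model, each
clinic gets $O_c$ (observed flagged count), $E_c = \sum_{i \in c} \hat
p_i$, and the score $O_c/E_c$. Clinics under 30 patients are excluded for
estimate stability (the excluded list is reported). Because an ML logistic
fit with an intercept satisfies $\sum_i (y_i - \hat p_i) = 0$ on its
estimation cohort, total O equals total E exactly, hence the E-weighted
mean of clinic O/E over all clinics is exactly 1 — a built-in calibration
identity the test suite asserts to $10^{-8}$. The near-expected band
0.90–1.10 is treated as inclusive at both ends. O/E ratios are raw: no
shrinkage or empirical-Bayes stabilization, and no uncertainty intervals,
matching standard O/E practice for this design; both would be natural
extensions but are deliberately not defaults.

## The synthetic generator

The generator emulates a chronic-disease HMO extract at configurable size.
Design choices that matter:

* **Marginals.** Condition prevalences default to the marginal rates of a
  ~70k-patient chronic-disease cohort (e.g. diabetes 0.78, hypertension
  0.46, depression 0.28); demographics and eGFR categories follow the same
  source. SES group probabilities are normalized from cohort counts (the
  group percentages in the source tabulation are internally inconsistent
  with its counts, so counts are used). Conditions are drawn as
  independent Bernoulli variables — the real joint comorbidity structure
  is not modelled, a documented limitation.
* **Index-condition calibration.** Prevalences are interpreted as
  *eligible-cohort* marginals. Since eligibility requires at least one
  index condition, the generator solves $q_X = p_X Z$ with
  $Z = 1 - \prod_X (1 - p_X Z)$ (fixed point via `uniroot`) and
  rejection-samples so that conditional-on-eligibility marginals equal the
  configured values exactly.
* **Visit process.** Inter-visit gaps follow a gamma renewal process with
  shape $k = 1/\mathrm{COV}^2$, chosen because the interval COV is
  analytically $k^{-1/2}$, giving closed-form oracles; gaps are rescaled
  to fit the window after random start/end offsets (COV is scale-free, so
  rescaling is harmless) and rounded to whole days with a 1-day minimum.
  Visit counts are truncated-Poisson (≥ 3) with mean 12 per two years —
  roughly six family-physician contacts per year, a realistic rate for
  chronic-disease patients; the source data do not publish the rate, so
  this is the package's own choice.
* **Effect pathway and calibration.** Each patient's linear predictor
  $\eta = \mathrm{logit}(p_0) + x^\top\beta + u_c$ (baseline flag rate
  $p_0 = 0.20$, ground-truth log-odds $\beta$ defaulting to the log
  adjusted odds ratios of the reference analysis, clinic effects $u_c \sim
  N(0, \sigma^2)$) is mapped to a target COV through a Monte-Carlo
  calibration curve: $P(\text{sample COV} \ge 1.2)$ is estimated on a COV
  grid by simulating the *exact* series path (gamma gaps, rescaling,
  rounding) marginal over the visit-count distribution, isotonic-smoothed,
  and inverted. The curve uses its own fixed internal RNG stream and is
  memoised, so generation is deterministic and repeated cohorts are cheap.
  By construction $P(\text{flag} \mid x) = \mathrm{logit}^{-1}(\eta)$ *at
  the calibration threshold*; parameter-recovery checks therefore use the
  fixed-threshold rule, while the quintile rule is the analysis default.
* **Code emission.** Flagged conditions emit 1–3 concrete ICD codes drawn
  from the packaged lists' expansions, restricted to codes unique to each
  condition's list: real ICD chapters overlap (hypertensive heart disease
  codes sit in both the hypertension and heart-failure lists), and
  sampling from the overlap would make simulated flags unidentifiable.
  Decoy codes that match only exclusion arms (e.g. `173.2`, `327.35`,
  `F10.11`) are sprinkled in so the matcher's exclusion logic is exercised
  end to end. Two tabulated conditions are special: headache has a
  prevalence but no published code list (it is carried in the prevalence
  map and never emitted), and sleep disorders has a code list but no
  published prevalence or effect (prevalence set to 0.05, effect 0, not in
  the default model).
* **Planned ineligibility.** Independent per-patient marks (defaults:
  under-40 4%, no index condition 4%, hemodialysis 2%, under-3-visits 5%)
  generate patients that each eligibility filter must remove; visit
  durations are lognormal with median 5 minutes, so the 5-minute filter
  also removes a nontrivial share of individual contacts.
* **Seeding.** One master seed expands into independent per-table
  substreams, so enlarging one table does not perturb the draws of
  another; identical configuration and seed give byte-identical bundles.

**What passing tests do and do not show.** The generator reproduces
marginal prevalences, a realistic TR distribution (median ≈ 0.95, strongly
non-normal), the specified logistic effect pathway, and clinic-level
dispersion — so green tests demonstrate that the *pipeline* is correct and
that the models recover known truth. They do not demonstrate anything
about real comorbidity correlations, visit-process seasonality,
provider-switching behavior, or coding practice variation, none of which
the generator models.

## Problem sizes and numerical tolerances

The test suite exercises: marginal calibration at $n = 10{,}000$ (3
binomial SEs); parameter recovery at $n = 20{,}000$ over 20 seeds
(≥ 90% Wald-CI coverage of the true log-odds, nominal 95%); the O/E
calibration identity at $n = 5{,}000$ / 50 clinics (tolerance $10^{-8}$);
and the monotone widening of the O/E distribution over clinic-effect SDs
$\{0, 0.3, 0.6\}$ with 10 seeds each at $n = 6{,}000$ — sizes chosen so
Monte-Carlo noise is well below the asserted margins while the full suite
stays fast on one CPU. IRLS converges on relative deviance change below
$10^{-10}$; oracle-equivalence checks (pattern matcher vs full
enumeration, concordance vs all-pairs, COV vs direct formula, Jarque–Bera
p vs the closed-form $e^{-JB/2}$ tail) are exact or at numerical
tolerance.

## Known limitations

* Conditions are independent in the generator; real comorbidity clustering
  (and any resulting confounding structure) is absent.
* The calibration makes the logistic model exactly correctly specified
  only at the calibration threshold; quintile-based flags are
  approximately logistic in the linear predictor.
* The c-statistic is in-sample; no cross-validation is offered.
* No alternative regularity indices (Gini, entropy) and no
  provider-continuity indices (UPC, Bice–Boxerman) — TR is deliberately
  the only construct.
* Clinic O/E has no shrinkage and no uncertainty intervals by default.
* Real-data headline values from proprietary cohorts are not reproducible
  here by construction; the package's claims are about definitional
  identities and recovery of known synthetic truth.
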