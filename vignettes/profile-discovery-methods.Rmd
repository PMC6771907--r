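---
title: "Methods: subgroup discovery for renal function preservation"
author: "rfprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgroup discovery for renal function preservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfprofile)
```

## The problem

Two oral antidiabetic drug classes (generically "class A" and "class B" in
this package; in the motivating setting, SGLT2 inhibitors versus DPP-4
inhibitors) are compared on a binary renal outcome in routine-care claims
data. The outcome, *renal function preservation* (RFP), is derived from
serum creatinine: a patient preserves renal function when the follow-up
estimated glomerular filtration rate (eGFR) at roughly twelve months shows
no decline from baseline. Because treatment choice in routine care is
driven by patient characteristics, the raw comparison is confounded; and
because the clinical interest is in *which patients* benefit, the analysis
must search for subgroups ("profiles") in which the class effect is
amplified, without the search itself producing false discoveries.

The package implements the full chain as a reproducible pipeline:

1. **Synthetic cohort generation** with a known confounded assignment model
   and implanted benefit subgroups (`simulate_cohort()`), since the original
   claims database is proprietary.
2. **Cohort preparation**: eligibility filtering with an attrition log,
   eGFR computation, window-based lab selection, outcome derivation
   (`prepare_cohort()`).
3. **Propensity estimation** from a fixed confounder list
   (`fit_propensity()`), with baseline balance diagnostics.
4. **Effect models**: propensity-adjusted logistic (RFP) and Gaussian
   (HbA1c change) regressions (`class_effect_binary()` and relatives).
5. **Profile search**: exhaustive enumeration of all 1- and 2-criterion
   rules over a quantile grid, screened by four credibility indicators
   (`discover_profiles()`).
6. **Hold-out validation**: stratified 70/30 split, re-evaluation of the
   screened profiles on the held-out 30%, Benjamini-Hochberg control at the
   10% level (`validate_profiles()`).

`run_pipeline()` executes the whole sequence deterministically from one
master seed.

## Outcome definitions

eGFR uses the creatinine-based Japanese coefficient equation

$$\mathrm{eGFR} = 194 \cdot \mathrm{Cr}^{-1.094} \cdot \mathrm{age}^{-0.287}
\;(\times\, 0.739 \text{ for women}),$$

in mL/min/1.73 m^2 with creatinine in mg/dL. The baseline value is the
last in-window measurement at or before the index date (window: 183 days);
the follow-up value is the in-window measurement (274-457 days) closest to
day 365, with an exact-distance tie resolved to the *earlier* date — a
deterministic convention we fixed because nothing in the clinical
definition prefers either side. RFP (primary) is
$\mathrm{eGFR}_{fu} \ge \mathrm{eGFR}_{base}$, compared at full floating
precision; the sensitivity definition relaxes this to a relative decline
greater than $-5\%$, so every primary-preserved patient is also
sensitivity-preserved by construction. Month-based windows are mapped to
fixed day counts (183/274/457) to avoid calendar arithmetic; all dates are
integers relative to each patient's index date.

## The effect and benefit estimands

With treatment indicator $t$, propensity score $e(x)$ and outcome $y$:

* **Class effect** — logistic regression
  $\mathrm{logit}\, P(y=1) = \beta_0 + \beta_t t + \beta_s e(x)$ fitted
  within a subgroup; the adjusted odds ratio (aOR) is $e^{\beta_t}$, with
  Wald 95% CI and two-sided p-value, and the c-statistic is the AUC of the
  fitted probabilities.
* **Class benefit** — one interaction model on all patients,
  $\cdots + \beta_m m + \beta_{tm}\, t\,m + \beta_s e(x)$ with membership
  indicator $m$; the *ratio of aORs* (within vs outside the profile) is
  $e^{\beta_{tm}}$ and its Wald test is the benefit p-value. Stratified
  within/outside fits are reported alongside for display. We chose the
  single-interaction-model formulation because it yields a proper test of
  effect modification; the two stratified estimates coincide with it
  asymptotically.
* The HbA1c-change analogues replace the logistic model by a Gaussian one;
  the estimand is the adjusted mean difference.

The propensity score is a plain binary logistic regression on the fixed
confounder list (age category 18-44/45-64/65+, hospitalisation status,
baseline eGFR as a continuous term, baseline HbA1c category <6.5/6.5-<7/>=7,
comorbidity index, sex, hyperlipidaemia, hypertension, four baseline
drug-class flags, neuropathy, nephropathy, retinopathy, prior regimen
category). It enters the outcome models as a single continuous covariate on
the probability scale — no matching, trimming or weighting — and the global
scores are reused in every subgroup model rather than refitted per
subgroup. Reference levels are the first listed category throughout.

Numerical safeguards: fits that fail to converge or separate are refitted
with a ridge-stabilised IRLS (penalty $10^{-4}$ on all non-intercept terms)
and flagged; zero cells in the unadjusted 2x2 odds ratio receive the
Haldane-Anscombe $+0.5$ correction, also flagged; a fully zero margin is an
error rather than a number.

## The profile search

A *criterion* is `variable >= cut`, `variable <= cut` (continuous) or
`variable = modality` (categorical/binary); a *profile* is a conjunction of
one or two criteria, never two criteria with the same operator on one
variable (a two-sided interval on one variable is allowed and consumes both
slots). Continuous cuts are the deciles of the learning-set distribution —
a grid that keeps the search exhaustive in spirit while bounding it in
size; the grid is configurable. The search enumerates every profile and
evaluates four credibility indicators on the learning set:

1. size $\ge$ 10% of the learning set;
2. treated-class share inside the profile within $\pm 10$ *percentage
   points* (absolute difference; we made this configurable because the
   relative reading is also defensible) of the overall share;
3. class effect aOR $\ge 1.5$ with $p < 0.05$;
4. class benefit ratio $\ge 1.5$ with $p < 0.05$.

Both p-value requirements apply, since the reporting format publishes a
p-value for each indicator. Passing profiles are ranked by benefit p-value,
then benefit ratio; near-duplicates (membership Jaccard > 0.9) collapse to
the better-ranked representative. The expert clinical-review step of the
original workflow is replaced by configurable allow/deny lists on profile
variables — we make no attempt to encode clinical judgement. For batch
speed the search skips a profile's model fits once a cheaper indicator has
already failed; `evaluate_profile()` on a single profile always computes
every indicator it can.

## Validation

Patients are split 70/30 within each treatment class (largest-remainder
rounding, so each stratum deviates from 70% by at most one patient).
Discovery sees only the learning set. Every screened profile is then
re-evaluated on the validation set with identical rules, and
Benjamini-Hochberg adjustment is applied across the carried family,
separately for the class-effect and the class-benefit p-values (the
published table format shows one BH column per indicator, which implies
per-indicator families). A profile is *validated* when its validation-set
threshold flags hold and its BH-adjusted class-effect p-value is below
0.10. The benefit BH requirement is configurable and off by default: the
motivating study retained profiles whose benefit BH p-values exceeded 0.1
while still calling them validated, so the effect-only reading matches the
observed behaviour.

## What the generator emulates — and what it does not

The generator's default `study_preset()` reproduces the *shape* of the
motivating cohort: 5247 patients, 19% in the treated class, covariates
named and scaled like a claims-derived diabetes cohort (baseline eGFR,
diabetes duration, HbA1c, haemoglobin, LDL, comorbidity flags, prior
regimen), confounded assignment (younger, higher-eGFR, more intensively
pre-treated patients are likelier to receive class A), an overall RFP rate
calibrated to ~40% — a documented modelling choice, since only the treated
group's rate (42%) is public — a small base class effect (log OR = log 1.1)
and one implanted benefit subgroup, *no hyperlipidaemia and antithrombotic
use* (~22% prevalence), carrying an extra treatment log odds ratio of
log 2.5. That places the within-profile aOR (~2.75) and the benefit ratio
(2.5) on the scale of the published validated profiles (aOR 2.2-3.3,
ratios 2.0-2.9). The HbA1c-change outcome has a zero treatment effect by
default, mirroring the finding that glycaemic control did not differ.

Design choices worth stating explicitly:

* **The implanted profile uses binary criteria.** Ground truth defined by
  continuous thresholds can never lie exactly on a data-driven decile grid,
  so exact rank-1 recovery would be ill-posed; binary modalities are always
  representable. Recovery of continuous-threshold profiles is still
  exercised, approximately, by the neighbouring grid cuts.
* **Assignment confounding acts through the analysis's own encodings.**
  Age and HbA1c affect assignment through the same fixed categories the
  confounder list uses, so the propensity model is correctly specified and
  the method's no-unmeasured-confounding assumption holds by construction
  in the emulation. A generator that confounds on *continuous* age while
  the analysis only adjusts for age categories would embed unmeasured
  confounding — a different (interesting) experiment, but not the one the
  method assumes; it can be produced by passing custom
  `confounding_coefficients`.
* **Overlapping implanted profiles add on the log-odds scale** — the
  simplest composable convention.
* **Per-stage RNG streams** are derived from the master seed, so changing
  the outcome model cannot perturb the covariate draws; identical configs
  give byte-identical tables.
* **Raw-table emission** back-solves creatinine from the intended eGFR
  values exactly (so preparation round-trips the generator's truth when no
  ineligible records are injected) and places noisy distractor measurements
  where window selection must ignore them. A configurable fraction of
  patients receives one deliberate violation (invalid creatinine, missing
  follow-up, short exposure, short activity) to exercise the attrition log.

What the generator does *not* emulate: real prescription sequences and
dosing, ICD-10 coding and its misclassification, informative missingness of
labs, time-varying confounding, or calendar effects. Covariates are drawn
independently, so the correlation structure of real claims data (e.g.
age-eGFR dependence) is absent. Passing tests therefore demonstrate that
the pipeline's statistics behave as designed under a known, favourable
generative model — not that the clinical findings of any particular study
are correct.

## Problem sizes and stochastic checks

The test suite exercises the estimator oracles on toy data (<= 50 rows),
calibration properties at $n = 10^5$ where law-of-large-numbers tolerances
apply, parameter recovery at $n = 20\,000$, and the full discovery pipeline
at the study scale ($n = 5247$) over 20 seeds for power (implanted profile
at rank 1 in >= 80% of seeds, validated in >= 70%) and 50 seeds for false
discovery under the null preset (<= 20% of runs with any validated
profile). These sizes were chosen so each property's sampling noise is well
inside its assertion margin while a full suite run stays comfortably
interactive.

## Known limitations

* The probability-scale propensity adjustment is a one-degree-of-freedom
  control; with strong misspecification it leaves residual confounding that
  subgroup models inherit. The logit-scale alternative can be had by
  passing `qlogis(scores)` wherever scores are accepted.
* Exhaustive search over correlated candidate rules is subject to winner's
  curse: in a minority of seeds a chance refinement outranks the implanted
  truth on the learning set. The hold-out validation exists precisely to
  temper this, and the false-validation rate under the null stays within
  the BH design level.
* The ratio-of-aORs test is asymptotic (Wald); very small strata fall back
  to ridge stabilisation and are flagged rather than silently trusted.
* `bh_adjust()` controls FDR across the carried family only; profiles
  discarded before validation contribute no multiplicity correction, as in
  the original two-stage design.

## CLI

A thin command-line front end ships in `inst/cli/profilepipe.R`
(subcommands `simulate`, `prepare`, `run`, with `--config` accepting a
YAML/JSON simulation config via `read_sim_config()`); discovery and
validation are reachable through `run` or the R API, which is the
package's primary interface.
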