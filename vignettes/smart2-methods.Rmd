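---
title: "Methods: competing-risk estimation and validation of recurrent ASCVD risk"
author: "smart2risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing-risk estimation and validation of recurrent ASCVD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smart2risk)
```

## The problem and the model

Patients with established atherosclerotic cardiovascular disease (ASCVD) —
coronary artery disease, cerebrovascular disease, peripheral artery disease
or abdominal aortic aneurysm — remain at substantial but highly variable
risk of a recurrent event. Guidelines increasingly ask clinicians to
quantify that residual 10-year risk rather than label every such patient
"very high risk". Over a 10-year horizon in a population aged 40–80,
non-cardiovascular death is a competing event that a naive Cox model
ignores, which overstates ASCVD risk precisely in the older patients in
whom treatment decisions are hardest.

`smart2risk` implements the full methodology of a SMART2-style recurrent
ASCVD score as a reusable toolkit:

* a **Fine–Gray subdistribution-hazard engine**. The subdistribution
  hazard at time $t$ is the hazard of the ASCVD event among subjects who
  have not yet had it, with subjects who died of non-CVD causes *retained*
  in the risk set. Coefficients $\beta$ maximize the inverse-probability-
  of-censoring-weighted (IPCW) partial likelihood: a subject with a
  competing event at time $s$ contributes weight $G(t^-)/G(s^-)$ at later
  event times, $G$ being the Kaplan–Meier estimate of the censoring
  survivor function. Newton–Raphson starts at $\beta = 0$ and stops when
  $\max_j |U_j(\beta)| < 10^{-9}$ or the relative log-likelihood change
  falls below $10^{-12}$ (at most 100 iterations, with step-halving);
  non-convergence is reported in the fit object, never silently ignored.
  The covariance is the inverse observed information. Ties use the Breslow
  convention, matching the Breslow-type baseline estimator.
* the **scoring function**. Thirteen predictors (age; sex; current
  smoking; systolic blood pressure, mmHg; non-HDL cholesterol, mmol/L,
  log-transformed; diabetes; CAD; CeVD; PAD; AAA; years since the first
  ASCVD diagnosis, squared; eGFR, mL/min/1.73 m², squared; hsCRP, mg/L,
  log-transformed) form a linear predictor centered at derivation means.
  Baseline antithrombotic therapy enters as a fixed **offset** with hazard
  ratio 0.81 — fixed, not estimated, because the score is intended to
  guide decisions that may themselves involve these drugs. The individual
  risk at horizon $t$ in region $r$ is
  $$\mathrm{risk} = 1 - \exp\{-\,c_r\, \Lambda_0(t)\, e^{\mathrm{LP}}\},$$
  with $\Lambda_0 = -\log S_0$ the baseline cumulative subdistribution
  hazard at the centering point and $c_r$ the region's multiplicative
  recalibration factor.
* **regional recalibration**. The expected/observed (E/O) ratio divides
  the mean predicted risk by the observed Aalen–Johansen ASCVD cumulative
  incidence at the horizon. Because $\mathrm{mean}\{1 - \exp(-c\,H_i)\}$
  is nonlinear in $c$, the package also solves for the constant $c$ that
  makes the post-recalibration mean predicted risk *equal* the observed
  incidence (bracketed 1-d root search, tolerance $10^{-8}$) — this turns
  the calibration claim into an exact, testable fixed point. Both the raw
  E/O ratio and the solved constant are reported; the solved constant is
  what `recalibrate()` stores. With several cohorts per region the factors
  are pooled by unweighted arithmetic mean (an n-weighted option exists).
  Factors can be keyed by horizon when regions are validated at different
  horizons (2/3/6/10 years).
* **validation metrics under competing risks**. Calibration uses octiles
  of predicted risk against Aalen–Johansen incidences (never the
  Kaplan–Meier complement, which overestimates incidence when competing
  death is present). Discrimination comes in the incident/dynamic variant
  (cases are the failures at each event time; the time-specific AUCs are
  aggregated with pair-count weights into an integrated C) and the
  cumulative/dynamic variant (cases are events by the horizon). In both,
  subjects with a prior competing event are kept as IPCW-weighted controls
  at every later time; the alternative of censoring them is deliberately
  not offered. Internal validation uses seeded, cause-stratified 10-fold
  cross-validation; out-of-fold predictions are pooled and scored once,
  which is stabler than per-fold averaging when events are rare. Cohort
  results pool by DerSimonian–Laird random effects with a 95% prediction
  interval on $t_{k-2}$ (for $k \ge 3$ cohorts).
* **decision curves**. Net benefit at threshold $p_t$ is
  $p_{hi} F_{hi} - p_{hi}(1 - F_{hi})\, p_t/(1-p_t)$ with $F_{hi}$ the
  Aalen–Johansen incidence inside the treated subset — the competing-risk
  correction of the classic formula, to which it reduces exactly with no
  censoring and no competing events. The 0.20–0.50 threshold band relevant
  to intensified secondary prevention is flagged.

## Numerical choices

* **Baseline estimator.** The baseline cumulative subdistribution hazard
  is stored in product-limit form,
  $\Lambda_0(t) = \sum_{t_j \le t} -\log(1 - d_j / S^{(0)}(t_j))$, rather
  than the raw Breslow sum. The two agree to first order, but the
  product-limit form makes the null-model predicted incidence equal the
  nonparametric Aalen–Johansen estimate *exactly* at every event time — a
  sharp invariant the test-suite asserts at machine precision.
* **Step conventions.** $G$ is evaluated left-continuously ($G(t^-)$);
  baselines are right-continuous step functions; a requested horizon
  between baseline knots uses the last knot at or before it; horizons
  beyond the last knot are an error, never an extrapolation.
* **Transforms.** Log transforms floor their argument at 0.01 (with a
  warning) — values below that are at or under assay detection limits.
  Ages outside the supported 40–80 range are rejected by default, with an
  explicit clamp-with-warning option.
* **Ties.** Breslow handling in the engine; octile binning breaks ties in
  predicted risk by stable input order; concordance counts tied risks as
  1/2.
* **C-statistic variance.** Confidence intervals for the IPCW
  C-statistics use a DeLong-type two-sample component decomposition
  (per-case and per-control concordance components) computed in the same
  pass as the estimate. It is approximate under weighting but costs
  nothing at derivation scale, where a resampling interval would dominate
  the runtime of an entire validation.
* **Transformation search.** `select_transformation()` compares identity,
  log, square and a restricted cubic spline (3 knots at the 10th/50th/90th
  percentiles) by AIC of the weighted partial likelihood, breaking ties
  toward identity. Because the spline nests the identity with one extra
  degree of freedom, AIC will prefer it in a predictable minority of
  null-truth datasets; the tests treat the selection accordingly.

## The synthetic derivation cohort

The generator exists so that every estimation and validation routine can
be exercised under the exact conditions the derivation assumes, with known
truth. Its defaults are fixed once:

* **Published marginals** (used as-is): age $61 \pm 9$ truncated to
  40–80; 74% male; 30% smokers; SBP $139 \pm 20$; 18% diabetes; CAD
  62% / CeVD 29% / PAD 17% / AAA 8% (at least one guaranteed by
  construction — the independent draw probabilities are deflated by a
  deterministic fixed point so the *marginals* still match); eGFR
  $77 \pm 18$; hsCRP log-normal, median 2.0, IQR 1.0–4.4 (hsCRP is
  handled in mg/L throughout: a median of 2.0 is plausible only on that
  scale). Antithrombotic use 78%.
* **Unpublished marginals**, chosen once as realistic for an outpatient
  secondary-prevention population and then frozen: non-HDL cholesterol
  log-normal with median 3.3 mmol/L and $\sigma_{\log} = 0.34$
  (consistent with the cohort's total-minus-HDL cholesterol); years since
  first ASCVD diagnosis log-normal with median 1.8 y, $\sigma_{\log} = 1$,
  truncated at 15 y (a newly-referred population: many recent diagnoses,
  a long-history tail).
* **Correlation structure**: a Gaussian copula with age–eGFR $\rho = -0.4$
  and age–years-since $\rho = +0.2$; all else independent. True
  covariate correlations in the derivation cohort are unpublished, so the
  discrimination the generator produces is approximate by construction;
  both correlations are profile elements and can be changed.
* **True coefficients**: the published subdistribution hazard ratios.
  Continuous-predictor ratios are published as 3rd-vs-1st-quartile
  contrasts (and per-10 mmHg for SBP); they are converted to per-unit
  coefficients on the transformed scale using the default profile's own
  quartiles. The conversion, the centering means and the baseline
  survival in the shipped coefficient file are therefore *synthetic
  stand-ins* for the non-public derivation parameter table — the file is
  named `smart2_synthetic_default.json` to say so — while the hazard
  ratios themselves and the 0.81 offset are the published values.
* **Event model**: cause-1 times follow
  $F_1(t \mid X) = 1 - \{1 - p(1 - e^{-\lambda t})\}^{\exp \eta}$
  (the mass-at-infinity construction), so the generated data satisfy
  *exactly* the model the engine fits and parameter recovery is a sharp
  test; non-CVD death is exponential; censoring is uniform administrative
  follow-up over 2.5–21 years (a 1996–2019-style accrual window) plus
  light exponential dropout. $p = 0.355$, $\lambda = 0.08$,
  $\mu_2 = 0.0172$ and dropout $0.004$ were calibrated once so that
  $n = 8355$ reproduces the derivation event profile — on average about
  1680 ASCVD events and 960 non-CVD deaths over a median ~8.1 years of
  follow-up (IQR ~4.3–13.3), with a 10-year ASCVD cumulative incidence
  near 0.20 — and were not revisited afterwards.

What passing tests on this generator do **not** show: real cohorts have
non-proportional hazards, measurement error, informative censoring,
correlated comorbidity patterns and regional case-mix differences that the
generator does not emulate. Results on the synthetic cohort validate the
*machinery*, not the clinical performance of any coefficient set, and the
shipped coefficient file is for methodological work, not patient care.

## Problem sizes used in checks

Derivation-scale experiments use $n = 8355$ (parameter recovery averaged
over 20 seeded replicates; one cohort for 10-fold cross-validation; 10
seeds for the event-profile counts). Property checks run at the smallest
size that makes the property sharp: brute-force likelihood and
concordance oracles at $\le 15$ records, self-calibration at
$n = 20\,000$, closed-form generator checks at $n = 50\,000$.

## Known limitations

* The competing-death rate is covariate-independent; in reality non-CVD
  mortality rises with age, which would mildly dampen observed ASCVD
  incidence among the oldest patients.
* The incident C integration weight (pair-count) is one of several
  published conventions; it is declared rather than configurable per call.
* Fine–Gray coefficient standard errors come from the inverse observed
  information and ignore the (small) contribution of estimating $G$;
  the cross-check against `cmprsk::crr` shows coefficient agreement to
  $10^{-6}$ and near-identical standard errors at moderate $n$.
* Missing-data handling is single mean-imputation of continuous
  predictors (the behaviour of the deployed calculators); multiple
  imputation is out of scope.
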