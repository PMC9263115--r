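---
title: "Coronary flow endotypes and the CCFVR companion metric: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary flow endotypes and the CCFVR companion metric: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## The measurement model

All indices derive from six vitals per subject measured at rest and during
adenosine hyperemia: the diastolic peak flow velocity in the left anterior
descending artery (DPVr, DPVh, cm/s), cuff systolic/diastolic pressures
(mmHg) and heart rate (bpm). From these:

* **CFVR** = DPVh/DPVr — dimensionless vasodilator reserve; ≤ 2.5 defines
  coronary microvascular dysfunction (CMD).
* **CCFVR** = √(DPVr² + DPVh²) (cm/s) — the radius of the velocity pair in
  the (DPVr, DPVh) plane. CFVR fixes only the angle of that pair
  (angle = atan CFVR), so two subjects with identical CFVR can sit at very
  different radii; CCFVR is the level information CFVR discards. It equals
  √2 × the quadratic mean of the two velocities (the conversion factor
  1/√2 rounds to 0.71).
* **MAP** = (2·DAP + SAP)/3; **BMR** = MAPr/DPVr and **HMR** = MAPh/DPVh
  (mmHg·s/cm) — each condition's pressure paired with the same condition's
  velocity. The alternative reading (resting MAP in both quotients) was
  rejected because resistance is a within-condition quantity; the code
  takes `map` and `dpv` as explicit arguments, so either pairing is
  available.
* **ARI** = BMR − HMR — the resistance drop attainable under maximal
  hyperemia. A negative ARI is anomalous but not impossible (pressure drift
  between readings); it is returned and flagged (`ari_negative`), not
  rejected.
* **rpCFVR** = CFVR/RPP × 10⁴ with RPP = HR × SAP. Which condition's RPP
  normalises is genuinely open; the default is the resting product (CFVR is
  reported once per subject and resting work is the conventional
  normaliser), with `rpp_condition = "hyperemia"` as a switch. The 10⁴
  factor puts typical values on the CFVR scale (order 2–4).

Velocities, pressures and rates must be positive and SAP > DAP in each
condition; violations are rejected at parse time with the row and field
named, never silently dropped.

## Thresholds and endotypes

Three cut-offs dichotomise the cohort, with "impaired" meaning
**value ≤ cut-off** throughout (one convention for all three):

| cut-off | default | provenance |
|---|---|---|
| CFVR | 2.5 | fixed, external convention |
| DPVh | cohort median (≈ 75 cm/s) | no external reference exists in HT patients |
| CCFVR | cohort median (≈ 80 cm/s) | same |

Medians use the standard linear-interpolation quantile (even-sized cohorts
average the middle pair), and any cut-off can be fixed by configuration.
With continuous data this puts each median-based flag's prevalence within
one subject of n/2.

Endotypes combine CMD with the DPVh flag: 1 = preserved CFVR/impaired DPVh,
2 = both preserved, 3 = both impaired, 4 = impaired CFVR/preserved DPVh.
Variant endotypes substitute CCFVR for DPVh but follow their own
numbering — 1A = impaired CFVR with preserved CCFVR, 2A = both preserved,
3A = both impaired, 4A = preserved CFVR with impaired CCFVR — i.e. 1A is
*not* the positional analogue of 1. The package keeps that convention
verbatim rather than "fixing" it, because the labels are established.
`reclassification_table()` cross-tabulates subjects and deaths across the
two schemes; row/column sums and the death total are conserved by
construction, which the tests assert against a brute-force tally.

## Survival layer

Subjects enter the risk set at 5 years post-transplant (the cohort is
enrolled conditional on 5-year survival); time zero stays at transplant.
Kaplan–Meier and Cox fits handle this as left truncation
(`Surv(entry, time, event)`). The log-rank test is computed without the
entry term: a delayed entry *common to all subjects* leaves every risk set
unchanged (nobody is at risk, and no event occurs, before it), and the
underlying routine does not accept counting-process input;
subject-specific entry vectors are refused rather than approximated.

Cox models use the Breslow tie approximation — the simplest to verify
against an independent oracle, and immaterial here since simulated times
are continuous. Non-convergence and separation raise errors (any
|coefficient| > 20 is treated as divergence) instead of returning unstable
estimates. The univariable screen fits each candidate alone and keeps those
with p < 0.10 (configurable), preserving input order; an empty selection
produces a warning so the multivariable step can be skipped explicitly.

Model comparison follows the "separately added marker" design: each flow
marker (CMD, low DPVh, low CCFVR) is added alone to the clinical base
model, never jointly, and judged by Harrell's C (ties in risk count 1/2;
apparent, in-sample performance — no cross-validation, as the comparison is
between nested models on one cohort), the likelihood-ratio test
(2·ΔLL ~ χ² with df = added coefficients, clamped at 0 against floating
point), and the continuous NRI
(= [P(up|event) − P(down|event)] + [P(down|non-event) − P(up|non-event)],
"up" being any risk increase; range [−2, 2], antisymmetric under swapping
the models).

## Reproducibility statistics

Paired CFVR readings are summarised by (i) the Pearson r and the residual
standard error of the regression of the second reading on the first (the
SEE is computed directly from the residual sum of squares; `summary.lm`
warns on perfect fits), (ii) Bland–Altman limits d̄ ± 1.96·SD(d) with
t-based confidence intervals (SE(d̄) = s/√n, SE(limit) = s·√(3/n)), and
(iii) the single-measure ICC from the two-way model. The ICC form is
genuinely underdetermined by convention alone; the default is absolute
agreement, ICC(A,1) — the natural choice for two fixed sessions/raters,
since a systematic offset between readings *should* count against
reproducibility — with `type = "consistency"` as the switch. ICC ≥ 0.81 is
flagged as satisfactory.

## The synthetic cohort generator

The generator exists so every downstream stage can be exercised without
patient-level data. Its defaults *are* the study conditions: 134 HT
subjects in endotypes of sizes 32/60/31/11 plus 50 controls; per-endotype
velocity laws; crude death fractions 13/32, 16/60, 14/31, 6/11; follow-up
horizon normal(15.1, 5.8²) years truncated to [6.2, 28.5]; entry at 5
years.

**Velocities.** Each endotype's DPVr and DPVh are log-normal (positive
support, right skew consistent with median < mean in the printed
summaries), quantile-matched to the published median (Q1–Q3): location
ln(median), scale (ln Q3 − ln Q1)/(2·z₀.₇₅). The two velocities are coupled
by a Gaussian copula (default latent correlation 0.5 — no joint law is
published; 0.5 encodes that resting and hyperemic flow share subject-level
determinants without being collinear). Pairs are rejection-sampled onto the
endotype's cell of the CFVR-2.5 × DPVh-75 dichotomy, so endotype counts are
exact by construction. Because that truncation would shift the constrained
medians by several percent, the sampler runs a two-iteration fixed-point
recalibration of the log-normal locations (4000-draw calibration batches on
the same RNG stream, so a fixed seed still gives a bit-identical cohort);
residual median error is under 1.5%. Quartiles are matched only
approximately — truncation narrows them — and only the medians are treated
as calibration targets. Infeasible configurations (constraints that the
velocity law essentially never satisfies) abort after a bounded number of
attempts (`max_tries` per subject).

**Survival.** Event times are exponential after entry, with each
endotype's rate solved numerically (integration over the horizon law +
root finding) so the *expected* crude death fraction equals the target;
censoring is administrative at the drawn horizon. Exponential hazards are
the minimal model identifiable from a crude fraction — the data offer
nothing richer.

**Planted reclassification structure.** Within endotype 1, velocity pairs
are reassigned so that decedents hold the block's lowest CCFVR values
(marginal distributions untouched). This reproduces the qualitative
signature the analysis is designed to expose — deaths under preserved CFVR
concentrate at low companion values and reclassify to variant 4A — and
makes it testable deterministically.

**Vitals and covariates.** Pressures and heart rates are normal with
physiologic ranges: HT subjects SAP 130 ± 12 / DAP 85 ± 8 (MAP ≈ 100 mmHg,
which combined with the velocity targets reproduces the published BMR/HMR
levels), resting HR 85 ± 10 (denervated grafts run fast), small pressure
drop and 15 bpm rise under adenosine; controls 120/75 with HR 70 ± 10 and
CMD excluded by rejection. Clinical covariates (ages, sexes, diabetes,
pre-transplant ischemic heart disease, ischemic time, CAV grade with onset
= grade > 0) are drawn per endotype from the published prevalences/means.
They exist to exercise the Cox screen; no claim is made that the generator
reproduces the published hazard ratios — those are unidentifiable from
summary tables, and the package does not attempt it.

**What passing tests do and do not show.** The generator emulates marginal
velocity distributions, crude mortality, and one planted dependence
(endotype-1 death ↔ low CCFVR). Real cohorts add measurement error,
covariate–hazard confounding, non-exponential hazards and informative
censoring that it does not model; tests passing on synthetic data validate
the *computations*, not clinical transportability.

## Numerical choices and problem sizes

* Internal computation is full double precision; reporting precision (one
  decimal for velocities/ratios, two for resistances) is applied only in
  report tables.
* Polar round-trip and the algebraic identities
  (CCFVR = DPVr·√(1+CFVR²); ARI = MAPr/DPVr − MAPh/DPVh) are tested at
  1e-9 relative tolerance.
* The test suite sizes simulations to be decisive yet quick: Cox bias and
  null-p calibration use 500 replicates at n = 2000 (|mean log-HR bias| <
  0.05, Kolmogorov–Smirnov uniformity of null p-values); generator
  calibration pools 200 seeded cohorts (medians within 3%, death fractions
  within 2 binomial SE); oracle comparisons (exhaustive concordance,
  product-limit, cross-tabulation) use n ≤ 60 where enumeration is exact.
* Log-rank power across endotypes at the study's own size and death
  fractions is close to one half — the mortality gradient (27%–55%) is
  real but modest at n = 134 — so significance in any single realisation
  is a coin toss; the tests assert the majority property over a fixed seed
  panel rather than significance of one cohort.

## Limitations

* No competing risks and no time-varying covariates (out of scope).
* CCFVR inherits the measurement error of both velocities; agreement
  statistics here cover repeated CFVR readings only (two sessions/raters).
* The generator's copula correlation and vitals parameters are reasoned
  defaults, not fitted quantities; analyses sensitive to them should vary
  the configuration.
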