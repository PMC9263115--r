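# coroflow

Analysis of transthoracic Doppler coronary flow measurements in
heart-transplant (HT) cohorts: hemodynamic indices including the
velocity-domain companion to coronary flow velocity reserve, microvascular
endotype classification, death reclassification between endotype schemes,
and the prognostic survival layer — with a calibrated synthetic cohort
generator so the whole pipeline runs end-to-end without patient data.

## The problem and the core quantities

Coronary flow velocity reserve,

    CFVR = DPVh / DPVr,

is the ratio of the hyperemic to the resting diastolic peak flow velocity in
the left anterior descending artery (adenosine hyperemia; CFVR ≤ 2.5 marks
coronary microvascular dysfunction, CMD). Being dimensionless, CFVR is blind
to the *level* of flow: a patient with velocities 25→50 cm/s and one with
40→80 cm/s share CFVR = 2.0 despite very different perfusion states. The
companion metric keeps the units:

    CCFVR = √(DPVr² + DPVh²)   [cm/s],

the distance of the velocity pair from the origin of the (DPVr, DPVh) plane
— √2 times the quadratic mean of the two velocities (factor 1/√2 ≈ 0.71). In
polar coordinates the angle encodes CFVR and the radius is CCFVR, so the two
are complementary: for the pairs above, CCFVR is 55.9 and 89.4 cm/s.

Around these the package computes mean arterial pressure
((2·DAP + SAP)/3), basal and hyperemic microvascular resistance
(BMR = MAPr/DPVr, HMR = MAPh/DPVh), the arteriolar resistance index
(ARI = BMR − HMR), the rate-pressure product and work-normalised reserve
(rpCFVR = CFVR/RPP × 10⁴), and ΔDPV in absolute and percent terms.

Subjects are dichotomised at three cut-offs (CFVR 2.5 fixed; DPVh and CCFVR
at the cohort medians, typically ≈ 75 and ≈ 80 cm/s) into four **endotypes**
(CFVR × DPVh) and four **variant endotypes** (CFVR × CCFVR), and the
cross-tabulation shows how cardiovascular deaths redistribute between the
schemes — notably, deaths occurring despite preserved CFVR concentrate at
low CCFVR and reclassify to variant 4A. The survival layer provides
Kaplan–Meier curves (left-truncated at the 5-year conditional-entry
landmark), log-rank tests, Cox models with a univariable p < 0.10 screen,
Harrell's C, likelihood-ratio tests and the continuous net reclassification
improvement for comparing prognostic models; a reproducibility module gives
regression agreement (r, SEE), Bland–Altman limits and the intraclass
correlation for repeated CFVR readings.

## Worked example

```r
library(coroflow)

compute_cfvr(25, 50)    # 2
compute_ccfvr(25, 50)   # 55.9017

res <- run_pipeline(seed = 42)   # simulates 134 HT subjects + 50 controls
res
```

prints

```
Coronary-flow pipeline: 134 HT subjects, 50 controls
Flow dichotomisation thresholds (impaired = value <= cut-off)
  CFVR  <= 2.5    [fixed]
  DPVh  <= 76.53  cm/s [cohort_median]
  CCFVR <= 80.85  cm/s [cohort_median]

Endotype sizes (HT):
 1  2  3  4
35 57 32 10

Log-rank across endotypes: chi-square 3.11 (df 3), p = 0.375
Prognostic model comparison (each marker added to the base separately)
            model c_index  loglik lrt_chisq lrt_p    nri
             base   0.615 -198.53        NA    NA     NA
       base + cmd   0.653 -197.10      2.85 0.091 -0.005
  base + low_dpvh   0.626 -198.40      0.26 0.610  0.247
 base + low_ccfvr   0.625 -198.35      0.36 0.550  0.204
```

The thresholds block shows the fixed CFVR cut-off and the two cohort-median
cut-offs derived from this realisation; endotype sizes differ slightly from
the generator's 32/60/31/11 because the realised DPVh median (76.5 cm/s)
replaces the generator's 75 cm/s reference. The model comparison adds each
flow marker separately to a clinical base model (age at transplant, donor
age, ischemic time, CAV onset) and reports discrimination (Harrell's C),
the likelihood-ratio test against the base, and the continuous NRI.

The death reclassification (`res$reclassification`) for the same seed:

```
Deaths:
        variant
endotype 1A 2A 3A 4A
       1  0  0  0 12
       2  0 15  0  1
       3  0  0 14  0
       4  5  0  0  0
```

— all 12 deaths of endotype 1 (preserved CFVR, impaired DPVh) carry CCFVR
below the cut-off and move to variant 4A: the companion metric recovers
high-risk patients that the ratio alone calls preserved.

A thin command-line wrapper is installed at
`system.file("cli", "coroflow", package = "coroflow")` with subcommands
`simulate`, `metrics`, `endotype`, `survive`, `agree`, `report`
(`--input`, `--out`, `--seed`).

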