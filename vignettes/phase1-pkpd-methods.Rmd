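---
title: "Methods: phase 1 antibody PK/PD analysis and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase 1 antibody PK/PD analysis and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

phasepk implements the analytic chain of a first-in-human antibody
dose-escalation study. This vignette documents the models and their
assumptions, the tunable parameters with their defaults and the reasoning
behind them, what the synthetic-trial generator does and does not emulate,
and the numerical choices that matter when reproducing its outputs.

## The disposition model

All kinetics are linear two-compartment with constant-rate IV infusion:

$$\dot A_1 = u(t) - (k_{10} + k_{12}) A_1 + k_{21} A_2,\qquad
  \dot A_2 = k_{12} A_1 - k_{21} A_2,$$

with $k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$ and
$C(t) = A_1/V_1$. `conc_2cmt()` evaluates the closed-form solution through
the hybrid constants $\alpha > \beta > 0$ (roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10} k_{21}$), writing the
infusion response as $R\,[G(t) - G(t - T_{\mathrm{inf}})]$ where $G$ is the
cumulative unit-rate response. That form is continuous at the infusion end
by construction and superposes over arbitrary dose schedules. When the two
roots coincide to within a relative $10^{-8}$ the evaluation switches to
the analytic repeated-root limit
$C_{\text{bolus}}(t) = e^{-\lambda t}\,(1 + (k_{21}-\lambda)t)/V_1$, which
avoids the catastrophic cancellation of the generic two-exponential form.
Internal time is hours; the reporting layer converts terminal half-life to
days and clearance to L/day, matching how such studies print mixed
µg·h/mL and per-day units.

Assumptions worth stating: no target-mediated (nonlinear) disposition, and
no within-subject time variation of clearance. Real anti-PD-1 antibodies
show a modest intra-individual clearance decrease over repeated cycles;
that effect is deliberately not modelled, so multiple-dose accumulation in
the synthetic data reflects half-life and schedule only.

**Steady state** is detected numerically: cycles are added until the trough
immediately before a dose changes by less than 0.1% (relative) from the
previous cycle, rather than assumed at a fixed cycle number — robust when
the half-life is long against the dosing interval. For evenly spaced equal
doses the successive troughs are computed by $O(1)$-per-dose partial
geometric sums (algebraically identical to the superposition sum); uneven
schedules and the repeated-root case fall back to full superposition.
Steady-state AUC integrates the converged cycle by adaptive quadrature
split at every infusion start and end.

## Noncompartmental analysis

* **AUC** uses the linear-up/log-down trapezoid: linear when the
  concentration rises or an endpoint is zero, logarithmic
  $\Delta t\,(C_1-C_2)/\ln(C_1/C_2)$ when strictly declining. A window edge
  inside an interval is interpolated consistently with that interval's rule.
* **Terminal slope** $\lambda_z$: log-linear least squares over contiguous
  terminal windows of at least 3 points ending at the last quantifiable
  sample, excluding $T_{\max}$; the window with the largest adjusted $R^2$
  wins, and ties within $10^{-4}$ prefer the longer window. This is the
  standard industry heuristic; with fewer than 3 eligible points the slope
  is reported not-estimable and every dependent parameter is missing rather
  than guessed.
* **BLQ policy**: pre-dose BLQ samples count as zero, embedded BLQ samples
  are excluded, trailing BLQ samples truncate the profile at the last
  quantifiable point.
* **Trough** is the sample closest to the cohort's nominal trough time
  within ±10% of the dosing interval (nominal-time reporting).
* **Vss** uses the infusion-corrected mean residence time
  $\mathrm{MRT} = \mathrm{AUMC}_\infty/\mathrm{AUC}_\infty - T_{\mathrm{inf}}/2$ —
  necessary for a 0.5-h infusion.
* An extrapolated-AUC fraction above 20% raises a flag but the value is
  still reported, since tiny escalation cohorts are routinely summarised
  even when extrapolation is heavy.
* Cohort summaries are geometric means with
  $\mathrm{GCV\%} = 100\sqrt{e^{s^2}-1}$; for $n \le 2$ only the min–max
  span is shown.

## Dose proportionality

The power model $\ln Y = a + b \ln(\text{dose})$ is fit by OLS per
parameter (Cmax, AUC(0–τ), AUC(0–∞)) on cycle-1 single-dose values of the
escalation cohorts, dose on the mg/kg scale. The 90% CI uses the $t$
distribution with $n-2$ df and the verdict is the encompasses-one rule. A
zero-width CI from an exactly proportional fit is accepted with a
machine-epsilon guard. Subjects with a non-estimable parameter simply
reduce $n$ — this mirrors published tables where one cohort member lacks an
AUC(0–∞).

## Two-stage population PK

The estimator is deliberately two-stage rather than full nonlinear
mixed-effects: with rich sampling the stage-1 fits are individually
consistent, the artifact stays dependency-light, and the `poppk_model`
contract (typical values, weight exponent, log-scale variances, residual
model) is estimator-agnostic, so an NLME backend could be substituted
without changing any interface.

Stage 1 fits each subject by Levenberg–Marquardt on log parameters with
residuals weighted by the combined error model
$\sigma(c) = \sqrt{(\sigma_{\mathrm{prop}} c)^2 + \sigma_{\mathrm{add}}^2}$
(defaults 15% CV + 0.05 µg/mL). Starting values come from an NCA pass
(self-priming), with 5 additional restarts from ±50% log-perturbed starts
under deterministic sub-seeds; the best objective is kept. Two robustness
choices were added after observing stage-2 breakdown on weakly informative
profiles: the optimiser runs inside a wide plausibility box
(CL $10^{-5}$–1 L/h, $V_1$ 0.2–50 L, $Q$ $10^{-5}$–5 L/h, $V_2$ 0.05–100 L),
and a fit only counts as converged when the Gauss–Newton standard error of
$\log CL$ is below 0.5. A profile truncated around one terminal half-life
simply does not identify clearance — the gate excludes such subjects from
stage 2 instead of letting them dominate the variance estimates.

Stage 2: $\theta_{WT}$ and $\theta_{CL}$ come from regressing
$\ln CL_i$ on $\ln(WT_i/70)$ (reference weight 70 kg, the conventional
allometric anchor), with $\omega^2_{CL}$ the residual variance of that
regression; the other typical values are geometric means with log-scale
sample variances; the proportional residual CV is re-estimated from pooled
relative residuals with a 4-parameters-per-subject df correction. The
clearance–weight trend test is the two-sided $t$ test of the log–log slope
at the 0.05 level.

Parameter-recovery studies in the test suite use washout sampling to
1344 h (≈3.2 terminal half-lives). At the study's own scale (17 subjects)
the median typical-CL error across 20 replicates is within 20%; at
100 subjects the weight exponent is recovered within ±0.15. These are the
problem sizes the suite runs; they were chosen to match the scale of the
data the method is meant for.

## Virtual-population exposure and occupancy margins

`simulate_ctrough()` draws weights from a log-normal truncated to the
observed 45.6–145.6 kg span (the default meanlog/sdlog, log 76 / 0.22,
give a realistic right-skewed adult oncology population), then individual
parameters via the covariate and log-normal deviations, then the numeric
steady-state trough per subject. `summarize_exposure()` reports:

* the arithmetic mean trough;
* a 90% CI of the mean computed on the log scale and back-transformed
  (exposures are log-normal, so the log-scale interval is the natural one —
  note it is centred on the geometric mean);
* a 90% prediction interval as empirical 5th/95th percentiles — always
  wider than the CI;
* the fold-margin of the CI lower bound over the full-RO threshold
  (reported to 1 decimal), and the same margin divided by the typical
  threefold tissue dilution of monoclonal antibodies.

Published trough intervals of this kind are sometimes population-wide
(prediction-type) even when labelled CIs; both interval types are therefore
reported side by side and the margin is defined against the CI bound.

## Receptor occupancy

The generator's forward model is the sigmoid
$\mathrm{RO}(C) = C^h/(EC_{50}^h + C^h)$; real assays report the saturation
level empirically, so the sigmoid is an artifact of the generator, not a
claim about assay mechanics. "Full RO" is a ratio within 0.10 of the
saturation value 1 — the band is configurable because "full" is never
quantified in assay terms. The cohort threshold estimate is the arithmetic
mean of per-subject minimum full-RO concentrations; subjects with no
full-RO measurement are excluded from the mean and listed as non-achievers.
Whether a published threshold of this kind is a mean of per-subject minima
or a pooled mean is genuinely ambiguous — the per-subject reading is
implemented. Anomalous-flagged measurements are excluded; flagging is an
input, not detected. Defaults $EC_{50} = 0.81$ µg/mL, $h = 2$ put the 90%
band crossing at $3\,EC_{50} \approx 2.44$ µg/mL, the magnitude at which
full peripheral occupancy is observed for this drug class.

## Trial logic

* **3+3**: 0/3 safe, 1/3 expand to 6, ≥2 DLT exceeded, ≤1/6 safe.
* **Modified 6+6** (the published description gives only the <33% rule):
  0/6 safe, the borderline 1/6 expands to 12, ≥2/6 exceeded; with 7–12
  evaluable the <33% rule applies directly. This is an interpretation and
  is documented as such.
* **AE tables** count subjects once per category; related AEs are also
  tabulated per preferred term, keeping terms whose incidence reaches 10%
  in at least one dose group of a study part (the printed footnote is
  ambiguous between "part" and "group"; the group reading keeps low-n
  groups visible). Percentages round half-up to 1 decimal to match printed
  tables exactly.
* **Responses**: irCR/irPR (and irPD) require confirmation by a second
  assessment at least 28 days later showing the same or a better category;
  an unconfirmed response contributes stable disease; stable disease needs
  no minimum duration (none is stated for this design). ORR = (CR+PR)/n,
  DCR = (CR+PR+SD)/n.

## The synthetic-trial generator

`trial_config()`/`simulate_trial()` emulate the default study: 21 part-1
subjects (1/3/10 mg/kg Q2W on 28-day cycles, including 3 + 6 PK/PDy
subjects who skip the cycle-1 day-15 dose to open a full-cycle sampling
window) and 13 part-2A subjects (500 mg Q3W, 1000 mg Q6W). Typical values
(CL 0.2 L/day, $V_1$ 3.5 L, $Q$ 0.03 L/h, $V_2$ 1.5 L → $t_{1/2}$ ≈ 17.7 d,
$V_{ss}$ = 5 L) reproduce the magnitudes such studies print for an IgG4
antibody; they are generator inputs, not claims about any real fit.
Between-subject variances (ω² 0.0625/0.04/0.09/0.09 on CL/$V_1$/$Q$/$V_2$)
give GCV% in the 20–35% range typical of mAb exposure. The default weight
exponent on clearance is 0.25: a mild trend that stays non-significant at
trial scale, matching the qualitative finding such studies report.

The nominal sampling schedule is pre-dose, 0.5 (end of infusion), 1, 2, 4,
8, 12, 24, 48, 72, 120, 168, 240, 336 h plus the cohort trough time (336 h
for the Q2W DLT cohorts, 504 h for the PK/PDy and Q3W cohorts, 1008 h for
Q6W). The true schedule of such trials lives in inaccessible supplements;
this one was chosen so that noise-free NCA recovers clearance within 2%
even for profiles ending at 336 h — a sparser draft schedule (without 12,
48, 120, 240 h) failed that requirement because the terminal window was
contaminated by the distribution phase. Actual sample times jitter
uniformly by ±10% of the preceding inter-sample gap, never crossing a dose
time, exercising nominal-versus-actual handling. LLOQ defaults to
0.1 µg/mL; BLQ rows carry a flag and a missing value.

One subject (94 kg, in the 1 mg/kg PK/PDy cohort) emulates anti-drug
antibodies: the generator solves (by root finding) for the clearance
multiplier that puts the noise-free day-22 concentration at 1.51 µg/mL,
below the full-RO band at the trough assessment. AE terms are drawn
per-subject from a probability table approximating the usual anti-PD-1
related-AE frequencies (fatigue ≈ 1/3), plus unrelated background terms;
every subject gets at least one event, as all treated patients in such
trials do. Response sequences are built from latent best-response draws
(part 1: P(irPR) = 2/21, P(irSD) = 5/21) over the part-specific visit
schedules, with confirmation visits spaced ≥ 28 days.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: target-mediated disposition, time-varying
clearance, dropout and dose modification, correlated random effects,
assay-specific occupancy differences (both assay streams share one
sigmoid), tumour dynamics behind the response categories, and MedDRA
coding (terms are plain strings). Tests passing on this generator establish
that the *analysis machinery* is correct under the stated statistical
assumptions, not that those assumptions hold in any particular trial.

## Data formats and reproducibility

Concentration data use a NONMEM-convention CSV (ID, TIME, AMT, RATE, DV,
EVID, BLQ, WT, COHORT, PART): dose rows have AMT > 0, EVID = 1 and an empty
DV; missing DV is an empty field, never 0, with BLQ a separate flag.
Validation is strict and reports row numbers. RO, AE and response streams
are one CSV each, sharing ID. Configurations and fitted population models
serialize to YAML at full double precision, so `run_pipeline()`'s log
(config snapshot, seed, version, row counts) reproduces a run exactly. All
randomness flows from a single integer seed through `withr::with_seed`,
leaving the global RNG untouched; identical config + seed gives
byte-identical output.

## Known limitations

* The two-stage estimator needs profiles spanning roughly three terminal
  half-lives to identify clearance per subject; on trough-limited schedules
  it degrades gracefully (subjects are gated out) but the between-subject
  variances are then biased upward by estimation noise.
* The ±10% trough-matching window assumes one trough sample per interval;
  designs with multiple late samples would need a stricter nominal-time
  join.
* The modified 6+6 boundaries beyond the published <33% sentence are an
  interpretation.
* Percent rounding is half-up to one decimal everywhere a printed table is
  mirrored; re-deriving counts from rounded percentages can therefore be
  off by one in edge cases, which is inherent to the printed presentation.
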