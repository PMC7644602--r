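---
title: "Mapping visual-tactile peripersonal space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping visual-tactile peripersonal space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppsmap` implements a complete analysis chain for two visual-tactile
psychophysics paradigms — the crossmodal congruency effect (CCE) and dynamic
peripersonal space (PPS) mapping — together with a trial-level synthetic data
generator so that every stage is testable without access to human data. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the synthetic data do and do not establish.

## The two paradigms

**CCE.** A vibrotactile target is delivered to the thumb or index finger,
preceded by no visual cue (baseline), a cue at the same location (congruent)
or at the other digit (incongruent). Six trial types (3 conditions x 2
digits) are each presented 15 times — 90 trials, inter-trial interval uniform
on 1.5-2.5 s. The congruency metrics are differences of per-condition
summaries: `cce_rt = median RT(incongruent) - median RT(congruent)` and
`cce_acc = accuracy(congruent) - accuracy(incongruent)` in percentage
points. Cleaning: responses slower than 2.0 s are discarded (strictly
"slower than", so a 2.0 s response is kept), and a subject is excluded when
any of the six cells retains fewer than 10 trials (exactly 10 is kept).
Medians are computed over correct-response trials; this is a documented
interpretation — whether incorrect-finger trials belonged in the RT medians
is not stated in the source task descriptions, and a mean-based variant is
available via `center = "mean"`.

**PPS.** Eleven LEDs sit 5-105 cm from the hand in 10 cm steps. Each trial
sweeps the LEDs in sequence (50 ms on, 200 ms gap: one 250 ms step per LED),
appearing to approach (D11 to D1) or recede (D1 to D11). A tactile stimulus
is triggered in synchrony with one LED (22 experimental conditions x 16
repetitions), alone (2 baseline conditions x 16), or not at all (2 catch
conditions x 39) — 462 trials in 3 equal blocks. Because touch arrives later
in a trial the nearer the approach has come, elapsed time and distance are
confounded: RTs drift faster with elapsed onset time (the expectancy
effect). The pipeline removes this by the time-matched subtraction

    delta_i = mean RT(approach, D_i) - mean RT(recede, D_(12-i)),  i = 1..11

— approach D1 and recede D11 share the same tactile onset (2.5 s), so time
cancels exactly and only distance and direction remain. A pure expectancy
drift with no multisensory signal produces an exactly flat delta curve; this
is a tested invariant.

## The sigmoid model of the PPS boundary

The delta curve is summarised by

    y(x) = ymin + (ymax - ymin) * exp((x - xc)/b) / (1 + exp((x - xc)/b))

with saturations fixed at `ymin = min(delta)` and `ymax = max(delta)` (not
free parameters), central point `xc` (PPS size, cm) and gradient parameter
`b` (cm): the slope at `xc` is `(ymax - ymin) / (4b)`, so smaller `b` means
a sharper PPS-EPS boundary. The widely printed variant of this equation
saturates at `ymin` and `ymin + ymax`, which contradicts the stated meaning
of fixed saturation points; we implement the bounded form above as the
default and keep the literal variant behind `form = "printed"`.

Estimation is bounded nonlinear least squares over `xc` in [5, 105] and `b`
in (0.1, 100]: a 25-point multi-start grid (5 `xc` values x 5 log-spaced `b`
values) is screened in one vectorised pass and L-BFGS-B refinement is run
from the best candidates, ties broken by lowest SSE then smallest `b`. The
suite verifies on random curves that this attains the optimum of an
exhaustive 0.25 cm-resolution grid search to within 1e-6 relative SSE. Fits
are made to the 11 per-distance means, not to trial-level RTs: an R-squared
threshold applied to trial-level noise would exclude nearly every subject,
while the curve-level fit matches how such data are summarised and plotted
(mean +/- SEM per distance). Retention requires `r2 > 0.5` (strict) and
convergence; a constant curve has zero total sum of squares and is reported
as `r2 = 0`, not kept.

The direction labels follow the physically coherent reading: "approach"
presents D11 toward D1 (the percept loops toward the hand) and "recede" the
reverse; D1 is always the distance nearest the hand, and delta curves are
reported in the approach frame of reference.

## Group inference

Each outcome (`cce_rt`, `cce_acc`, PPS `xc`, PPS `b`) is modelled with a
cumulative probability model (CPM): proportional-odds logistic regression
treating every distinct outcome value as an ordered category. The model is
fitted by full Newton-Raphson with step-halving on the exact gradient and
Hessian, in the parameterization `P(Y <= k | x) = plogis(zeta_k - x'beta)`
with strictly increasing cut points. `exp(beta)` is the adjusted odds ratio
for a higher outcome value per unit predictor; inference is Wald (matching
the aOR + CI95 reporting style), not likelihood-ratio. Two properties pin
the implementation down in tests: with a binary outcome the coefficients
equal binary logistic regression, and any strictly monotone transform of the
outcome leaves the coefficients unchanged to machine precision. Wald
calibration is checked empirically (type-I error 0.05 +/- 0.02 over 500
null cohorts of n = 50).

Predictor sets follow the study design: the CCE RT model adjusts for gender,
age, full-scale IQ, baseline tactile RT and diagnostic group (TD reference);
the CCE accuracy model swaps in baseline accuracy; the PPS models use
gender, age, full-scale IQ and group. Outcomes enter raw — the CPM ranks
internally — and predictors are not standardised, so aORs are per raw unit.

Missing covariates (gender, full-scale IQ) are handled by 40-fold multiple
imputation using bootstrap predictive mean matching: each imputation refits
a linear predictor on a bootstrap resample of the complete cases and
replaces each missing entry with the observed value of one of the 5
nearest-prediction donors, so imputed values are always observed, in-range
values. This is a standard approximation to additive-regression bootstrap
PMM. Per-imputation CPM fits are pooled with Rubin's rules
(total variance = within + (1 + 1/m) x between; Barnard-Rubin degrees of
freedom, collapsing to the normal reference — and to each fit's exact
standard errors — when the between-imputation variance is zero).

Secondary associations use tie-corrected Spearman correlations (Pearson on
mid-ranks, two-sided p from the t approximation) of `xc` and `b` with the
SRS-2 total T score, in the whole sample and within groups, with Bonferroni
adjustment (`min(1, p*m)`) over the two whole-sample tests.

## The synthetic generator

Per subject, experimental PPS trials follow

    RT = mu - kappa * onset - amp_dir * L(d) + exGaussian(0, sigma, tau)

with `L(d) = 1/(1 + exp((d - xc_true)/b_true))` (1 near the body, 0 far),
truncated below at 0.1 s. Baseline trials set the amplitude to zero; catch
trials draw a response with probability `fa_rate`; responses lapse with
probability `lapse_rate`. CCE trials shift a baseline RT by the programmed
congruent benefit / incongruent cost and draw correctness per condition.
Ex-Gaussian noise is the standard RT model; its exponential tail adds `tau`
to every condition mean and therefore cancels in all difference scores.
The expectancy effect is linear in elapsed onset time — the minimal model
consistent with its description as "the longer the wait, the faster the
response" — and receding stimuli receive an independent, smaller amplitude.

Defaults are artifact configuration, not reported values (the source study
reports no raw RT magnitudes): baseline tactile RT `mu` = 0.35 s, trial
noise `sigma` = 20 ms with `tau` = 35 ms tail, expectancy slope `kappa` =
20 ms of speeding per second of onset delay, approach amplitude 50 ms
(between-subject SD 20 ms), recede amplitude 10 ms, lapse rate 2%, catch
false-alarm rate 0.5%. The amplitude heterogeneity is deliberate: subjects
drawn with weak amplitudes produce flat, unfittable delta curves and fail
the R-squared rule, reproducing the reported data-loss mechanism (about
10-30% of subjects per group excluded for poor sigmoid fits) while leaving
clean curves among retained subjects. These values were fixed once, by
matching the published retention fractions and the direction and rough
magnitude of the published group effect, before the test suite was written.

Cohort defaults emulate the published sample structure: group sizes
36/26/22 (TD/ASD/SZ); age, full-scale IQ (truncated at the inclusion
threshold of 70), SRS-2 total T and gender mix per group from the published
descriptives; PANSS scores for SZ only; one-in-22 missing gender (SZ) and
3/26 + 2/22 missing IQ. PPS truth: TD and SZ centred at `xc` = 60 cm, ASD
at 40 cm with a sharper gradient (b 5 vs 10 cm), between-subject SD 8 cm —
the qualitative pattern the pipeline is meant to detect, with magnitudes
chosen, not measured.

## What the simulations do and do not show

Passing tests establish that the pipeline recovers what the generator put
in: the subtraction removes a linear expectancy drift exactly; `xc` is
recovered with a median error under one LED step (10 cm) at the study
design; a 20 cm group difference in true `xc` at the study's group sizes is
detected (ASD aOR < 1, p < 0.05) in well over 80% of simulated cohorts with
the SZ null preserved. They do not establish anything about real data:
real RT distributions are not exactly ex-Gaussian, expectancy need not be
linear, amplitudes and noise are correlated with clinical status in unknown
ways, and missingness in the study may not be completely at random.

Two limitations are worth stating plainly. First, fixing the saturations to
the curve extremes inflates fitted `b`: noisy extremes exaggerate the
apparent range, and the optimizer compensates with a shallower transition.
Fitted `xc` group differences survive this (compressed but detectable);
fitted `b` differences largely do not at realistic noise, so gradient
effects of the size reported in comparable studies are at the edge of what
this design can resolve. Second, retention-by-fit-quality is selective:
subjects retained in each group are those with stronger, cleaner
facilitation, so retained-sample summaries are not unbiased estimates of
the group's generative parameters.

## Problem sizes and numerics

The test suite and the acceptance script run entirely on synthetic data at
these sizes: 50 random curves for the optimizer-vs-grid check, 100 simulated
subjects for recovery and expectancy-removal checks, 500 null cohorts of
n = 50 for CPM calibration, and 100 cohorts of 84 subjects for the
end-to-end group-pattern check — sizes chosen to make Monte-Carlo bounds
tight enough to be informative while keeping a full run in minutes on one
CPU. Newton iterations stop at gradient norm 1e-8 or a log-likelihood change
below 1e-12, with up to 30 step-halvings; the sigmoid refinement uses
L-BFGS-B with `factr = 10`. Degenerate inputs are handled explicitly:
constant outcomes are an error for the CPM, constant curves give `r2 = 0`,
zero-variance contrasts report "no effect" (p = 1) rather than NaN, and an
empty cell among the 22 direction-distance cells flags the subject
unfittable rather than silently dropping a distance.
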