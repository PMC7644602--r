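# ppsmap

Visual-tactile multisensory analysis for psychophysics cohorts: crossmodal
congruency effects (CCE), peripersonal space (PPS) mapping from dynamic
visual-tactile reaction times, and proportional-odds group inference — with
a trial-level synthetic data generator so the whole chain is testable end to
end.

## The problem

Within a radius around the body — peripersonal space — an approaching visual
stimulus speeds reaction times (RT) to touch; beyond it, it does not. Two
numbers summarise a person's PPS: its size and the sharpness of its
boundary. Estimating them from a looming/receding LED paradigm is
confounded by *expectancy*: the longer a trial runs before touch arrives,
the faster the response, and approach trials deliver near-body touches late.
`ppsmap` removes the confound with a time-matched subtraction — approach at
distance D_i minus recede at D_(12-i), which share the same tactile onset —
and fits the resulting distance curve with a sigmoid

$$y(x) = y_{min} + (y_{max} - y_{min})\,\frac{e^{(x - x_c)/b}}{1 + e^{(x - x_c)/b}}$$

where $x_c$ is the PPS central point (size, cm) and $b$ the gradient
parameter (the slope at $x_c$ is $(y_{max}-y_{min})/4b$; smaller $b$ =
sharper boundary). Saturations are fixed to the curve extremes; $x_c, b$
are estimated by bounded multi-start least squares and fits are retained
when $R^2 > 0.5$.

Group differences in $x_c$, $b$, and the congruency metrics are tested with
a cumulative probability model (CPM): proportional-odds logistic regression
treating each distinct value of the continuous outcome as an ordered
category, reported as adjusted odds ratios (aOR) with Wald 95% CIs,
adjusting for age, gender and full-scale IQ (plus baseline tactile
performance for the CCE models). Missing covariates are handled by 40-fold
bootstrap predictive-mean-matching imputation with Rubin pooling. The CPM,
the imputation and the sigmoid fit are implemented in the package and
verified against independent references (binary logistic reduction,
`MASS::polr`, exhaustive grid search) in the test suite.

## Worked example

The `analysis/` scripts run the full workflow on a simulated cohort with the
study-like structure (TD n = 36, ASD n = 26, SZ n = 22; ASD generated with
a smaller, sharper PPS):

```sh
Rscript analysis/01_simulate.R      # 84 subjects, 46368 trials
Rscript analysis/02_cce.R
Rscript analysis/03_pps.R
Rscript analysis/04_group_models.R
```

Output from one run (seed 20201023):

```
congruency effect, RT: mean 79.3 ms, t = 66.38, p = 1e-73
expectancy drift: -28.6 ms of RT per s of onset delay (CI -29.4..-27.7)
group ASD: kept 23/26 sigmoid fits
group SZ: kept 20/22 sigmoid fits
group TD: kept 23/36 sigmoid fits
nearest-distance facilitation: -48.8 ms, t = -18.71, p = 1.6e-31
pps_size      ASD       aOR =  0.22 CI95 [0.06, 0.75] p = 0.0158
pps_size      SZ        aOR =  1.09 CI95 [0.30, 3.96] p = 0.894
whole-sample xc~srs_total_t: r = -0.25, p = 0.0448 (Bonferroni 0.0896)
recovery: median |xc error| = 7.5 cm over 66 kept fits
```

Reading: every group shows a congruency effect and near-body facilitation;
the expectancy drift is present in raw RTs (and exactly cancelled by the
subtraction); the ASD group's odds of a larger PPS are reduced (aOR < 1)
with no SZ effect — the pattern the generator encodes — and smaller PPS
size tracks higher social-impairment scores across the whole sample. The
fitted central point recovers the generative truth to within one LED step.

Programmatic use mirrors the scripts:

```r
library(ppsmap)
cfg <- run_config(seed = 1, out_dir = "out", cohort = cohort_spec())
run_simulate(cfg)
res <- run_analyze(cfg)
res$models$pps_size      # pooled CPM fit: aORs, CIs, p-values
res$pps$retention_log    # kept/attempted sigmoid fits per group
```

`run_analyze()` also accepts existing `trials.csv` / `subjects.csv` files in
the documented schema (see `?read_trials`).

## Package layout

- `R/` — session plans and trial-log IO, the synthetic generator, the CCE
  and PPS pipelines, the sigmoid fit, the CPM/imputation/pooling machinery,
  and the workflow orchestration.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property and end-to-end acceptance tests; all
  fixtures are generated in code.
- `vignettes/ppsmap-methods.Rmd` — the models, parameter choices, numerics
  and known limitations, in full.
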