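# boldhrf

Linear and biophysical models of the ageing BOLD impulse response.

The BOLD signal is an indirect readout of neural activity, filtered through
neurovascular coupling and vascular physiology — all of which change with
age. When the haemodynamic response function (HRF) differs between people,
the difference may be neural or vascular in origin, and telling the two
apart requires more than descriptive curve features. `boldhrf` implements,
on a common region-of-interest (ROI) pipeline, four model families for
characterising the HRF and its change across the adult lifespan:

| model | parameters | nature |
|---|---|---|
| `FIR32` | 32 × 1 s time bins | unconstrained linear basis (selective averaging) |
| `Can3`  | canonical two-gamma HRF + temporal & dispersion derivatives | informed linear basis |
| `NLF4`  | amplitude offset/scaling, latency offset/scaling | nonlinear template refit of the FIR curve |
| `HDM3`  | neural efficacy β, vasoactive decay rate κ (Hz), blood transit rate 1/τ (Hz) | biophysical generative model, inverted by Variational Laplace |

Around these sit the standard ingredients of an event-related fMRI
analysis: a maximal-length m-sequence design generator with jittered
onsets; microtime convolution design matrices; prewhitened first-level
GLMs (AR(1)+white-noise ReML, 1/128 Hz cosine high-pass, grand-mean 100
scaling); within-participant voxel selection and SVD eigenvariates;
group-level Parametric Empirical Bayes with Bayesian Model Reduction;
Volterra-kernel summaries of haemodynamic nonlinearity; HRF peak features;
and leave-one-out cross-validated age prediction.

For the `HDM3` core, the four hidden states (vasoactive signal s, inflow
f, venous volume v, deoxyhemoglobin q) follow

    f' = s
    s' = beta * z(t) - kappa * s - gamma * (f - 1)
    tau * v' = f - v^(1/alpha)
    tau * q' = f * (1 - (1-E0)^(1/f))/E0 - v^(1/alpha) * q/v

with BOLD observation
`y = 100 V0 [k1 (1-q) + k2 (1-q/v) + k3 (1-v)]`,
`k1 = 4.3 theta0 E0 TE`, `k2 = eps r0 E0 TE`, `k3 = 1 - eps`.

Because the cohort datasets such analyses target are access-controlled,
the package includes a synthetic-cohort generator (`cohort_spec()`,
`generate_cohort()`) with known age-dependent parameters — decay rising
and transit falling with age on the log scale, efficacy age-invariant by
default — so every stage is testable against ground truth.

## Worked example

Generate a 40-participant synthetic cohort, invert the hemodynamic model
on each participant's auditory-cortex eigenvariate, and ask what age does:

```r
library(boldhrf)

spec   <- cohort_spec(n_participants = 40, seed = 7)
cohort <- generate_cohort(spec)
dct    <- dct_highpass_set(261, 1.97)

posts <- lapply(cohort$participants, function(p) {
  eig <- roi_eigenvariate(scale(p$voxel_data$lAC, scale = FALSE))
  vl_fit(eig$eigenvariate, p$events, tr_s = 1.97, n_scans = 261,
         nuisance = cbind(dct, p$confounds))
})

decay   <- sapply(posts, function(f) posterior_rates_hz(f)[["decay"]])
transit <- sapply(posts, function(f) posterior_rates_hz(f)[["transit"]])
spearman_age(decay, cohort$ages)    # rho = 0.64,  p = 7.3e-06
spearman_age(transit, cohort$ages)  # rho = -0.64, p = 9.5e-06

bm <- bmr_search(peb_fit(posts, ages = cohort$ages))
bm$table[bm$table$covariate == "age", ]
#>   parameter covariate expectation  ci_lower  ci_upper retained
#> 4      beta       age      0.0000 -1.65e-05  1.64e-05    FALSE
#> 5     kappa       age      0.1370  1.03e-01  1.71e-01     TRUE
#> 6   transit       age     -0.0863 -1.21e-01 -5.16e-02     TRUE

feats <- cbind(beta = sapply(posts, function(f) f$mean[["beta"]]),
               decay, transit)
loo <- loo_age_prediction(feats, cohort$ages)
#> LOO age prediction: r = 0.82 (p = 4.7e-11), median abs error = 10.2 years
```

Reading the output: the posterior decay rate rises and the transit rate
falls with age (the Spearman correlations), and Bayesian model reduction
keeps exactly those two age effects — with the expected signs, in log-Hz
units per z-scored age — while pruning the age effect on neural efficacy,
which is how this cohort was generated. The three inverted parameters
alone predict held-out age with r = 0.82.

`run_pipeline(run_config(...))` orchestrates the same stages (plus the
FIR32/Can3/NLF4 fits, feature extraction and model comparison) end to end
and writes tab-separated result tables; see the vignette
`vignettes/bold-hrf-models.Rmd` for the model details and design choices.

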