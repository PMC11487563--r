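---
title: "Modelling the ageing BOLD impulse response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ageing BOLD impulse response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldhrf)
```

# The problem

The BOLD signal measured with fMRI is an indirect, haemodynamically filtered
reflection of neural activity. When the shape of the BOLD impulse response
(the HRF) differs between people — for instance across the adult lifespan —
those differences may arise from neural activity, from neurovascular
coupling, or from vascular physiology. `boldhrf` implements four model
families of increasing physiological commitment for characterising the HRF
from region-of-interest (ROI) timeseries, together with the group-level
machinery needed to ask which parameters age actually moderates:

* **FIR32** — a finite impulse response basis of 32 contiguous 1 s time
  bins: an unconstrained, assumption-light estimate of the HRF.
* **Can3** — the canonical two-gamma HRF plus its temporal and dispersion
  partial derivatives: a parsimonious linear basis.
* **NLF4** — a four-parameter nonlinear refit of each individual FIR curve
  against a group template, separating amplitude offset/scaling from latency
  offset/scaling.
* **HDM3** — a biophysical hemodynamic (balloon-type) model with three free
  parameters — neural efficacy, vasoactive-signal decay rate, and blood
  transit rate — inverted per participant by Variational Laplace, with
  group effects estimated by Parametric Empirical Bayes (PEB) and pruned by
  Bayesian Model Reduction (BMR).

Because the cohort data such analyses are normally run on are access
controlled, the package ships a synthetic-cohort generator with known
age-dependent parameters; every stage of the pipeline is exercised against
that ground truth in the test suite.

# The hemodynamic model

Four hidden states evolve in response to a binary neural input $z(t)$:
vasoactive signal $s$, inflow $f_{in}$, venous volume $v$, and
deoxyhemoglobin $q$:

$$\dot f_{in} = s, \qquad
  \dot s = \beta z - \kappa s - \gamma (f_{in} - 1),$$
$$\tau_h \dot v = f_{in} - v^{1/\alpha}, \qquad
  \tau_h \dot q = f_{in}\frac{1 - (1-E_0)^{1/f_{in}}}{E_0}
                 - v^{1/\alpha}\frac{q}{v}.$$

The observation equation maps $(v, q)$ to percent signal change:
$y = 100\,V_0\left[k_1(1-q) + k_2(1 - q/v) + k_3(1 - v)\right]$ with
$k_1 = 4.3\,\vartheta_0 E_0 \mathrm{TE}$,
$k_2 = \epsilon_h r_0 E_0 \mathrm{TE}$, $k_3 = 1-\epsilon_h$.

Free parameters (`HDM3`) and their interpretation:

| parameter | units | default / prior centre | role |
|---|---|---|---|
| $\beta$ (efficacy) | — | prior mean 0, variance 1 | gain from neural input to the vasoactive signal; may be negative |
| $\kappa$ (decay) | Hz | 0.64 | decay rate of the vasoactive signal |
| $1/\tau_h$ (transit) | Hz | 1.02 | rate of blood transit through the venous compartment |

The remaining parameters are fixed at conventional 3T values:
$\gamma = 0.41$ Hz, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$,
$\vartheta_0 = 40.3$ Hz, $r_0 = 25$ Hz, $\epsilon_h = 1$,
$\mathrm{TE} = 0.03$ s. All are exposed through `hdm_params()`. The exact
empirical prior table used by the original toolbox is not published in the
main literature we follow; the variances used here (1 for efficacy, 1/16
for log-deviations of the rates) are documented assumptions, configurable
via `hdm_priors()`.

## Numerical integration

`hdm_integrate()` uses a fixed-step classical Runge–Kutta scheme with the
flow, volume and deoxyhemoglobin states propagated in log space, which
enforces their positivity by construction. The public step is `dt = 0.375`
s (a finer 0.062 s grid does not change results materially); internally
each bin is integrated with two RK4 substeps, since the neural input is
constant within a bin. Halving `dt` changes the response by less than
$10^{-3}$ in relative L2 norm, and the error against an adaptive stiff
solver shrinks at approximately fourth order — both are asserted in the
test suite. States are bounded (|log state| < 25); regimes that escape the
admissible region raise an error naming the offending parameters rather
than returning garbage.

Event onsets are snapped to the integration grid and each event drives a
whole number of bins (default one), so an event contributes the same input
energy regardless of its phase relative to the grid. This matters: a naive
"all bins overlapping the burst" rule makes the input energy depend on the
jitter, which biases every amplitude downstream.

## Nonlinearity

Because the model is nonlinear, responses to closely spaced stimuli do not
superpose. `volterra_kernel1()` and `volterra_kernel2()` characterise this:
the first-order kernel is the isolated impulse response; the second-order
kernel is the response to an impulse pair minus the two isolated responses,
computed by direct integration (symmetric by construction).
`second_order_variance_fraction()` summarises how much of the variance
explained over a given event design is carried by the pairwise interaction
terms; it vanishes for isolated events and in the small-efficacy limit, and
grows with design density.

# First-level GLM

`build_design_matrix()` convolves a delta train at event onsets with each
basis column in a microtime space of 32 bins per TR (0.062 s for the 1.97 s
TR protocol) and samples at the middle microtime bin of each scan, matching
a middle-slice slice-timing reference. Data are scaled to a grand mean of
100. Scan noise is modelled as white plus AR(1): `reml_ar1()` estimates the
mixture weights of an identity and an AR(1) correlation component by
restricted maximum likelihood (Fisher scoring with the design projected
out, stopping at a log-likelihood change below $10^{-6}$ or 32 iterations),
and whitens model and data with the inverse symmetric square root of the
fitted covariance. Slow drifts are carried by a discrete cosine set with
all periods above 128 s — `floor(2 n_{scans} TR / 128)` cosines plus a
constant — included as nuisance columns so that model and data are filtered
identically.

One deliberate design choice: the AR coefficient of the second covariance
component is, by default, estimated from the lag-1 autocorrelation of the
pooled OLS residuals before the ReML step, rather than fixed at the 0.2
convention some analysis packages use. A fixed coefficient bounds the lag-1
correlation the mixture can represent at that coefficient's value, so data
with stronger autocorrelation would be left coloured after whitening; the
estimated-coefficient default keeps whitened residuals near-white across
the plausible range (asserted in tests), while `ar_coef = 0.2` reproduces
the fixed convention when comparability matters.

Within each participant, voxels with a significant F contrast across the
basis regressors (p < 0.05 uncorrected) are retained; participants with no
surviving voxels are excluded, mirroring practice with real cohorts. The
retained voxels are summarised by the first SVD component
(`roi_eigenvariate()`), scaled to the region's typical amplitude with sign
set by the mean voxel weight.

# NLF template fitting

`make_template()` takes the first right singular vector of the
participants-by-bins FIR matrix, oriented so its dominant extremum within
8 s is positive. `fit_nlf()` then fits each individual curve as
$\hat Y(t) = a_1 Y(t_1 t - t_0) + a_0$. Because Pearson correlation is
invariant to affine amplitude transforms, the warp $(t_0, t_1)$ is fitted
by maximising the correlation between warped template and individual curve
(3×3 multi-start plus identity, bounded quasi-Newton, ties broken toward
the identity warp), after which $a_0, a_1$ have a closed-form least-squares
solution. Published renderings of this model's equation are typographically
ambiguous about whether the warp is scale-then-shift or shift-then-scale;
both are implemented (`convention` argument), with $Y(t_1 t - t_0)$ the
default. Interpolation is linear and the template is zero outside its
support; warp bounds default to $t_0 \in [-4, 4]$ s, $t_1 \in [0.5, 2]$.
The test suite validates recovery against an exhaustive 0.01-resolution
grid-search oracle. For the age analyses the amplitude scaling $a_1$ and
the absolute latency scaling $|t_1|$ are the exported features; since
$t_1$ is bounded positive, taking the absolute value is a no-op under the
defaults and is retained only for symmetry with how the latency feature is
reported elsewhere.

# Variational Laplace inversion

`vl_fit()` estimates a Gaussian posterior over the free parameters on an
estimation scale — efficacy linear around 0, rates as log deviations from
0.64 Hz (decay) and 1.02 Hz (transit) — by Gauss–Newton ascent on the
Laplace free energy, with:

* central finite-difference prediction gradients (step $10^{-4}$);
* Levenberg–Marquardt damping, adapted ×8 on rejection, ÷4 on acceptance;
* a single white-noise log precision with Gaussian hyperprior (mean set
  from the data variance, variance 16), updated by safeguarded Newton
  steps and clamped to $[-40, 40]$ so that noise-free fits (residuals
  approaching machine zero) cannot overflow the exponential;
* nuisance regressors (constant, cosine set, confounds) carried as
  flat-prior parameters whose columns enter the Jacobian exactly;
* convergence declared after the free-energy change stays below 0.01 for
  four consecutive accepted iterations (cap 64).

The free energy is evaluated as a deterministic function of the parameters
and noise precision, and steps are accepted only when they increase it, so
the trace is non-decreasing by construction — a property the tests assert
on every synthetic fit. Parameters given zero prior variance are held at
their prior mean exactly. Posterior rate expectations are mapped back to Hz
via `posterior_rates_hz()`.

Calibration is checked, not assumed: with truth drawn from the
(physiologically truncated) prior and white noise added, 90% credible
intervals cover the truth at close to nominal rate over 200 replicates in
the acceptance tests.

# PEB and BMR

`peb_fit()` treats each participant's posterior mean as an observation of
their true parameters with the posterior covariance as within-subject
noise, regresses true parameters on group covariates (a constant and
z-scored age by default), gives the group effects a Gaussian prior (the
first-level priors for the mean column, zero-centred for covariates), and
optimises a diagonal between-subject covariance by evidence ascent
(Nelder–Mead on log variances, initialised at 1/16 of the prior
variances). Because each participant's full covariance enters, parameters
whose effects covary are handled jointly.

`bmr_evidence()` computes, analytically, the change in log evidence and
the posterior implied by replacing the prior with a reduced one — no
refitting. An unchanged prior returns exactly zero. "Pruning" an effect
shrinks its prior variance to $10^{-10}$ around zero (numerically, not
exactly, zero, to keep precision matrices invertible; the refit-agreement
tolerance of $10^{-3}$ is unaffected). `bmr_search()` scores all on/off
mixtures of the switchable effects (exhaustively up to 8, greedy backward
beyond), breaking evidence ties toward the sparser model, and reports
retained effects with posterior expectations and 90% credible intervals.

# The synthetic cohort

`cohort_spec()` defines the study conditions the generator emulates:

* ages uniform on 18–88 years;
* a 255-element degree-8 m-sequence design (any primitive feedback
  polynomial is accepted; the default taps are {8, 6, 5, 4}), base SOA 2 s,
  per-trial additive jitter U(0.1, 0.3) s, 120 bimodal plus 8 catch trials;
* TR 1.97 s, 261 scans;
* per-participant true parameters: decay
  $0.64\,e^{0.15 z(\mathrm{age}) + \varepsilon}$ Hz and transit
  $1.02\,e^{-0.10 z(\mathrm{age}) + \varepsilon}$ Hz (age effects on the
  log scale, matching the estimation-scale parameterisation), efficacy
  linear with intercept 0.8 and no age slope by default — so age acts on
  the vasculature, not on neural drive; between-subject SDs 0.12 / 0.08 /
  0.06;
* four ROIs of 16/12/10/8 voxels sharing the model-generated signal
  (shared-signal fractions 0.7/0.7/0.6/0.5), with per-voxel AR(1) noise,
  slow drift, and small leakage (SD ≤ 10% of signal SD) of eight confound
  regressors (six motion-like random walks, two compartment-like AR
  series).

The noise levels were chosen once so that single-participant eigenvariate
fits achieve $R^2$ of roughly 0.2–0.6, a plausible regime for ROI-level
event-related fMRI; the efficacy intercept of 0.8 puts the average peak
response near 0.4% signal change. A negative-efficacy regime (a young
negative response, as seen in ipsilateral motor cortex) is available by
configuring a negative efficacy intercept; default cohorts use positive
efficacy. Whether residual noise should itself grow with age is left
configurable rather than assumed: pass larger `voxel_noise_sd` profiles to
emulate it.

What the generator does **not** emulate: volumetric image structure,
physiological (cardiac/respiratory) cycles, motion-by-susceptibility
interactions, multi-echo acquisition, or model mismatch in the HRF family
itself (the data really are generated by the model the HDM3 stage fits, so
parameter-recovery results speak to the estimator, not to biophysical
model adequacy on real tissue).

# Problem sizes and runtime choices

The test suite runs cohorts of 100 (group-reduction pattern) and 200
(end-to-end age-effect signs and cross-validated age prediction), 200
replicates for credible-interval calibration, 50 random instances for the
GLM and BMR oracles, and short degree-5/6 designs where full-length runs
add nothing. These sizes were chosen as the smallest at which the
stochastic properties under test are comfortably resolved.

# Known limitations

* The Laplace posterior is Gaussian on the estimation scale; strongly
  skewed posteriors (e.g. efficacy near zero with low SNR) are summarised
  by mean and covariance only.
* The ReML noise model carries a single AR coefficient shared across the
  pooled voxels of a region.
* The second-level FIR age model pools residual variance across bins for
  its omnibus tests; bin-wise heteroscedasticity is not modelled.
* `bmr_search()` beyond 8 switchable effects is greedy and can in
  principle miss non-nested optima.
* LOO age prediction uses unregularised multiple regression, so the
  feature count must stay well below the cohort size (the pipeline warns
  below a 3× margin and refuses below `n = k + 2`).
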