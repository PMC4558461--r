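---
title: "Methods: spectral DCM for seizure-wise excitation-inhibition tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral DCM for seizure-wise excitation-inhibition tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(seizuredcm)
```

This vignette is the package's own account of its science: the generative
model and its assumptions, the priors and tunable parameters, how data are
reduced to spectral features, how inversion and model comparison work, the
design choices made where the design was genuinely open, and what the
synthetic-data validation does and does not establish.

## 1. The scientific question

Focal seizures evolve slowly relative to the EEG rhythms they contain:
activity that begins fast and small typically slows and grows over tens of
seconds. The package asks which slowly drifting quantities are *required*
to explain that evolution — inhibitory intrinsic connectivity, excitatory
intrinsic connectivity, the spectrum of afferent input from the rest of the
brain, or combinations of these — and estimates their time courses. The
currency of the answer is Bayesian model evidence: a hypothesis is a
restriction on which parameter groups may change across seizure windows,
and the eight possible restrictions are compared by variational free
energy.

## 2. The canonical microcircuit

A single epileptogenic source is modelled as four interacting neural
masses: spiny stellate (granular) cells, superficial pyramidal cells,
inhibitory interneurons, and deep pyramidal cells. Each population k has a
mean depolarisation $v_k$ and current $i_k$ obeying the second-order
synaptic kernel

$$\dot v_k = i_k,\qquad
\dot i_k = T_k u_k - 2 T_k i_k - T_k^2 v_k ,$$

with rate constants $T = (250, 170, 80, 70)$ Hz. Depolarisation maps to
(centred) firing rate through $\sigma(v) = 1/(1+e^{-\gamma v}) - 1/2$ with
slope $\gamma = 0.67$; the centred form makes the origin an exact resting
state at zero input for *every* parameter value, which is what a
steady-state spectral treatment requires. The drive $u_k$ sums ten signed
intrinsic connections:

| connection | path | sign | role |
|---|---|---|---|
| g1 | ss → ss | − | gain control (recurrent) |
| g2 | sp → ss | − | gain control |
| g3 | ii → ss | − | inhibitory |
| g4 | ii → ii | − | inhibitory (recurrent) |
| g5 | ss → ii | + | excitatory |
| g6 | dp → ii | + | excitatory |
| g7 | sp → sp | − | gain control (recurrent) |
| g8 | ss → sp | + | excitatory |
| g9 | ii → dp | − | inhibitory |
| g10 | dp → dp | − | gain control (recurrent) |

Exogenous input enters the granular population only. Between-population
connections carry a single conduction delay $d$ (prior 1 ms); recurrent
connections none. This is the unique wiring in which exactly three
connections originate from the inhibitory population and exactly three
excitatory connections remain, matching the grouping of the time-dependent
parameters; the remaining four connections are the constant gain-control
set. Two open assignments had to be fixed here: the rate constants
$T_1..T_4$ are mapped to (granular, superficial, inhibitory, deep) so that
the fast kernels sit in the populations that carry fast activity, and the
constant connections $(g_1, g_2, g_7, g_{10})$ take the descending prior
means $(800, 600, 400, 200)$ Hz.

At prior means the resting linearisation is stable (max Re eig ≈ −57 s⁻¹)
with resonances between 10 and 30 Hz — a beta-band source, appropriate for
seizure onset activity.

## 3. The spectral forward model

Linearising at rest and transforming to the frequency domain gives the
transfer function $H(\omega) = C\,(i\omega I - J_0 - J_d e^{-i\omega
d})^{-1} B$, where $J_0$ and $J_d$ are the instantaneous and delayed
Jacobians, $B$ injects input into the granular currents and $C$ reads out
depolarisations. Delays enter *exactly* through the $e^{-i\omega d}$
factor rather than a Taylor approximation — exact and cheap in the
frequency domain. The observed channel mixes the pyramidal depolarisations
as $H_{obs} = \kappa (H_{sp} + c_{dp} H_{dp})$: the superficial weight is
fixed at 1 (the dominant generator of EEG), the deep weight $c_{dp}$ is a
free parameter (prior mean 0.5), and $\kappa = 1000$ is a fixed
observation gain.

The gain deserves a comment, since it is a units convention and not a
parameter. Source-reconstructed EEG has arbitrary units, and with the
published prior scales alone the depolarisation transfer gain is of order
$10^{-3}$, which would leave the neuronal spectral term six orders of
magnitude below a unit-amplitude measurement-noise floor. $\kappa = 1000$
simply declares units in which the two terms are commensurate at
prior-mean parameters; it is never estimated, and a global rescaling of
the data absorbs any residual mismatch (section 6).

The endogenous input is "scale-free" noise with cosine-shaped
innovations,
$g_u(f) = a_1 f^{-a_2} \exp\big(\sum_k d_k \psi_k(f)\big)$,
where $\psi_k$ are the first eight discrete cosine functions over the 1-40
Hz grid, and measurement noise adds $b_1 f^{-b_2}$:

$$S_y(f) = |H_{obs}(f)|^2 g_u(f) + b_1 f^{-b_2}.$$

All amplitudes and the innovation coefficients are positive by
construction: every parameter is estimated as a log-scaling of its prior
mean, $\theta = \mu e^{\lambda}$. One consequence worth knowing: with
prior mean 1 for each $d_k$, the innovation coefficients live in the
positive cone, so input-spectrum shaping is multiplicative around a fixed
coloured base rather than free-form. Mid-band spectral bumps therefore
arise mostly from circuit resonances and the power-law tilt $a_2$, not
from the innovations — which is how the synthetic presets generate their
chirps (section 8).

The frequency grid is 1-40 Hz at 1 Hz steps: the band where the seizure
rhythms live, at the coarsest resolution consistent with 2 s windows.
Power laws diverge at 0 Hz, so the grid must stay positive.

## 4. Slow drift over windows

Each time-dependent parameter group (inhibitory $g_3,g_4,g_9$; excitatory
$g_5,g_6,g_8$; endogenous $a_1,a_2,b_1,b_2,d_{1..8}$) may drift across the
onset-aligned seizure windows. Drift is expanded on an orthonormal
8-component type-II discrete cosine basis over the *window index* (spectra
are averaged over seizures after aligning to onset, so the window index is
the natural time axis):
$\lambda(t) = \sum_{k=1}^{8} \beta_k \psi_k(t)$.
The constant (first) cosine component doubles as the baseline deviation, so
no separate baseline latent exists to trade off against it. Coefficient
priors are zero-mean Gaussians: the full tabled log-variance on the
constant component and half of it on components 2-8, encoding the prior
belief that fluctuations are slow and modest. Parameters outside a model's
varying set carry only the constant component. Positivity of $\theta(t)$
is automatic under the exponential map, and the expansion is linear in
$\beta$ on the log scale.

Prior log-variances follow the reference table: 0.0625 for rate constants
and connectivities, 0.03125 for $\gamma$ and $d$, 0.0078125 for the
input/noise spectral parameters; $c_{dp}$ is grouped with the constants at
0.0625 (its prior is not tabled anywhere, so mean 0.5 — deep contribution
smaller than superficial — with the constants' variance is this package's
choice).

## 5. From EEG to spectral features

* **Filtering.** Zero-phase 5th-order Butterworth band-pass 0.5-70 Hz, a
  50 Hz biquad notch (Q = 30), and common-average re-referencing for
  multichannel input. A sampling rate of at least 160 Hz is required to
  represent the 70 Hz edge comfortably.
* **Window length.** The analysis window should be the longest over which
  spectral activity is approximately stationary. The package quantifies
  this with a complex-Gaussian-wavelet time-frequency power estimate
  (3-cycle wavelets, 2-40 Hz): for each candidate length L the power field
  is smoothed over L/2 and the retained fraction is the energy of its
  piecewise-constant window projection; the longest candidate retaining at
  least 90% wins. The smoothing step is an operational choice — without
  it, estimator variance (wavelet power is roughly exponentially
  distributed) would dominate the criterion and no window would ever
  retain 90% even on stationary data. Defaults candidates are 0.5, 1, 2, 4
  s; 2 s is the reference choice for seizure data.
* **AR spectra.** Each 2 s window is reduced to an AR spectral density,
  fitted by ridge-regularised least squares (relative ridge weight 1e-3) —
  a fixed-shrinkage stand-in for a fully Bayesian autoregression, which
  the pipeline does not need since the density is used only as a data
  feature. Fits are stabilised by reflecting any unstable roots, and the
  one-sided density integrates to the segment variance. Crucially, the
  series is first resampled (sharp FFT low-pass) to 2.5× the band's upper
  edge (100 Hz for a 40 Hz band): a low-order all-pole fit at the raw rate
  spends its poles describing out-of-band roll-off and underestimates
  in-band density by tens of percent, a bias measured directly against
  the generative model during development. Order 12 at the resampled rate
  is the default.
* **Averaging.** Windows are cut from seizure onset, trailing partial
  windows discarded (zero-padding would leak), densities averaged across
  seizures per window index. Seizures differ in length; windows beyond the
  shortest seizure are averaged over the subset that reaches them, with
  the count recorded — this preserves late-seizure windows instead of
  truncating every seizure to the shortest.

## 6. Inversion by variational Laplace

The data features are **log** spectral densities stacked over windows ×
frequencies — the log scale turns the multiplicative sampling noise of
spectral estimates into approximately additive noise with a single scalar
precision $\pi = e^h$. The hyperprior on $h$ is Gaussian (mean 0, variance
1/16); because the accuracy term scales with the number of features, the
likelihood dominates this weak hyperprior and $h$ adapts to the actual
residual scale. Measured spectra in arbitrary units are first scaled by
one global factor matching their grand mean log-density to the prior-mean
prediction — the tight priors on $a_1, b_1$ (log-SD 0.088) are meant for
physiology, not for absorbing unit mismatches.

The free energy is

$$F = -\tfrac{\pi}{2}\big(e^\top e + \mathrm{tr}(J \Sigma J^\top)\big)
 + \tfrac{n}{2} h - \tfrac{n}{2}\log 2\pi
 - KL[q(\lambda)\,\|\,p(\lambda)] - KL[q(h)\,\|\,p(h)],$$

with $\Sigma = (\pi J^\top J + \Pi_0)^{-1}$ the Laplace posterior
covariance. The expected-accuracy trace term is retained deliberately: it
is the part of the bound that charges a model for fitting noise, and
dropping it (a common shortcut) biases model comparison toward complex
models. For a linear model the stationary point is the exact conjugate
posterior, which the test suite verifies to 1e-6.

Optimisation is Gauss-Newton ascent with Levenberg-Marquardt damping:
steps are accepted only if F increases; damping doubles on rejection and
halves on acceptance (floor 1/64 — without a floor, a long run of
acceptances drives damping so small that a subsequent rejection cascade
cannot restore a useful trust region within its 10-step budget).
Convergence is three consecutive accepted steps with dF < 0.01, or a
rejection plateau whose best candidates lie within that tolerance of the
optimum; ten consecutive rejections anywhere else returns the best-so-far
posterior with a warning flag. Initialisation is at the prior means (zero
latents) — standard, and free of data-dependent starts. Prediction
gradients are central finite differences (step 1e-3) on the per-window
log-scalings, chained through the exact linear cosine-basis map; windows
are independent given their parameters, so this costs O(windows ×
parameters) forward sweeps instead of O(latents) and is implemented in
compiled code. Windows whose linearisation loses stability predict a
large finite log-density (20 nats) so that such proposals are rejected
rather than fatal. Everything is deterministic: the same data give
bit-identical posteriors.

Variance explained is reported on mean-centred features,
$1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$.

## 7. The model space and its read-outs

The eight models are all combinations of the three varying groups, ordered
full model first, null model (nothing varies) last. Comparison is fixed
effects: free energies relative to the null, and softmax probabilities
under uniform model priors; $\Delta F = 3$ is odds of about 20:1. The
winning posterior yields:

* **Balance time courses** — the per-window mean log-scaling over the
  three inhibitory and the three excitatory connections, and their
  difference (balance = excitatory − inhibitory; the sign convention is
  stated here once and used everywhere). The group mean is the symmetric
  aggregation choice; posterior ±2 SD bands propagate exactly through the
  linear basis map.
* **Reconstructions** — predicted observed spectra per window,
  per-population time-frequency surfaces $|H_{pop}|^2 g_u$ (no
  measurement noise), and the input-spectrum surface, all at
  posterior-mean parameters. The observed mixture is coherent, so the
  population surfaces do not sum to the observed spectrum.
* **Peak tracking** — peak frequencies are reported within a 4-40 Hz band
  by default: the power-law shoulder otherwise pins the maximum to the
  lowest bin, masking in-band rhythms (the same reason clinical chirp
  tracking excludes delta).

## 8. The synthetic generator

With no public recordings of this kind, validation rests on synthetic data
generated by the same model family, with ground truth serialised alongside.

* **Presets.** "patient1": 55 seizures of 20 s (10 windows); an inhibitory
  log-scaling bump centred at a quarter of the seizure (amplitude 0.32),
  an excitatory bump at 60% (amplitude 0.40), input amplitude rising by
  0.35 over the first half and the power-law exponent tilting from −0.15
  to +0.15 over the second. "patient2": the same motif on 2 seizures of
  60 s with slower rate constants (−0.45 in log) and a longer delay.
  "chirp": a gradual descending peak (fast loop → slow
  deep-pyramidal/interneuron loop via rising $g_6, g_9$ → steepening
  input). "stationary": nothing varies. Bump amplitudes sit near 2 prior
  SD of the per-window log-scaling: large enough for clear spectral
  effects, small enough that the generating trajectories are plausible
  under the model's own priors — a generator that emulates the model
  should not place truth where the priors put negligible mass. The
  endogenous drift is kept temporally distinct from the gain bumps;
  development showed that strongly collinear input-colour and gain
  trajectories make the decomposition ambiguous for *any* estimator.
* **Fast route.** `simulate_spectra()` evaluates the predicted spectrum at
  the truth and multiplies each window-frequency bin by the mean of
  n-seizures Gamma(SNR, SNR) variables — unit mean, relative variance
  $1/(\mathrm{SNR}\cdot n)$. SNR is thus defined as the per-seizure
  signal-to-noise variance ratio of the spectral estimate in each bin;
  multiplicative Gamma noise matches the sampling distribution of spectral
  estimates far better than additive Gaussian noise would.
* **Slow route.** `simulate_timeseries()` integrates the nonlinear delay
  ODEs (fixed-step RK4 at 1 ms, quadratic interpolation on the delay
  buffer) driven by per-window spectral-synthesis input cross-faded over
  100 ms, with parameters piecewise-constant per window and linearly
  ramped over 100 ms at boundaries (ramps avoid integration transients).
  The observation adds measurement noise with the model's own power-law
  density. Halving the step changes the output spectrum by ~0.01%.
* **Cross-validation.** The two routes check each other: windowed AR
  features of simulated time series agree with the fast route within 20%
  RMS per window, and stationary simulations match the analytic spectrum
  within 10-15% — closing the loop between the time-domain model, its
  linearisation, and the feature pipeline.

What the generator does **not** emulate: volume conduction and multichannel
scalp topography (the pipeline assumes an already source-reconstructed
series), artifacts, non-Gaussian or nonstationary measurement noise,
between-seizure variability in the trajectories themselves, and any
mismatch between the true cortical dynamics and the microcircuit family.
Passing the validation suite therefore demonstrates internal consistency
and estimator correctness under the model's own assumptions — not clinical
validity on real EEG.

## 9. Validation scale and reference results

The validation suite works at the reference conditions — 10 windows × 40
frequencies, 55 seizures averaged, SNR 10, ten fixed seeds; these sizes
are the package's chosen validation scale, comfortably informative for a
155-latent full model. Headline properties (all computed by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, never
asserted from memory):

* conjugate-model exactness of the optimiser and monotone accepted-F
  traces;
* forward model vs 200 s linearised simulation within 10% RMS;
* inhibitory and excitatory trajectory recovery r ≥ 0.8 with the
  inhibitory→excitatory→balance peak ordering;
* selection of the generating full model with ΔF > 3 over the runner-up,
  while on stationary data the full model never beats the null by more
  than 3 and its inferred trajectories stay within |λ| < 0.1;
* self-inversion variance explained above 0.99 (noiseless) and 0.90
  (SNR 10).

## 10. Known limitations

* Single source, auto-spectra only: no cross-spectra, no extrinsic
  connectivity, no source localisation.
* The free-energy surface is multi-modal; Gauss-Newton with deterministic
  prior-mean initialisation finds reproducible but not provably global
  optima. Free energies of nested models occasionally order within a few
  nats of each other; conclusions should rest on ΔF ≥ 3 as usual.
* Excitatory-gain and input-amplitude effects on the spectrum overlap
  (raising $g_8$ resembles raising $a_1$); recovery of their shared
  variance component depends on the priors, which is intrinsic to the
  model class, not to the optimiser.
* The positive-cone restriction on spectral innovations (section 3) limits
  free-form input-spectrum shaping.
* AR features carry a residual few-percent parametric bias even after
  resampling; the inversion's precision hyperparameter absorbs it, but
  very sharp spectral peaks will be slightly flattened in the features.
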