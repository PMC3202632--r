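---
title: "Methods: a dynamic causal model for evoked and induced spectral responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dynamic causal model for evoked and induced spectral responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdcm)
```

## The model

Event-related electrophysiological activity splits into an *evoked*
component, phase-locked to the stimulus, and an *induced* component whose
latency varies from trial to trial. The conventional subtraction view
treats the two as linearly separable; `specdcm` instead fits one generative
model to both at once, so that whatever coupling changes are needed to
explain induced activity over and above evoked activity become explicit,
estimable parameters.

The observations are frequency-mode amplitudes: each source's
time-frequency spectrum is written as a time-varying mixture of a few fixed
spectral profiles ("frequency modes"), and the vector $g(t)$ stacks the
mode coefficients of all sources. Their motion follows a bilinear state
equation

$$\tau \dot g = (A + vB)\,g + Cu(t),$$

where

* $A$ carries the coupling shared by both components. Off-diagonal entries
  within a source couple its different modes; entries between sources
  couple modes across areas. Within-mode coupling is *linear*; between-mode
  coupling is *nonlinear* (cross-frequency) interaction. The leading
  diagonal is fixed at $-1$: in isolation every mode decays back to
  baseline.
* $B$ (one matrix per condition effect) carries coupling *changes* switched
  on by the condition indicator $v$. With $v = 0$ for the evoked condition
  and $v = 1$ for the induced condition, $B$ is exactly the coupling change
  needed to explain induced spectral dynamics that the shared $A$ cannot.
* $C$ weights the exogenous, stimulus-locked input $u(t)$, a gamma-shaped
  bump in peristimulus time.
* $\tau$ sets the decay timescale (ms).

The evoked and induced "conditions" are produced by the feature pipeline
from the *same* epochs: the evoked spectrum is the Morlet transform of the
trial average, the induced spectrum the trial average of single-trial
Morlet magnitudes, both baseline-corrected and reduced to $K$ modes by a
subject-specific SVD.

## Parameters, defaults and units

| parameter | meaning | default | notes |
|---|---|---|---|
| `tau` | decay time constant | 100 ms | log-normal prior, sd 1/4 on log scale, estimable |
| `A`, `B` entries | coupling (1/`tau` units) | prior N(0, 1/8) | masked entries are not parameters |
| `C` entries | input weights | prior N(0, 1) | input drives both modes of area 1 by default |
| input shape, rate | gamma bump | 6, 0.048/ms (peak ~104 ms) | log-scale, fixed by default, estimable via `input_var` |
| wavelet number | Morlet cycles | 7 | constant over frequencies |
| band | analysis frequencies | 4–48 Hz, 1 Hz steps | configurable |
| `K` | frequency modes | 4 for empirical work; 2 in the two-area study | SVD, joint over conditions and sources |
| SNR | simulation noise | 13.8 dB | on mode-coefficient observations |

Choices the data sources leave open, decided here and fixed:

* **Epoch and step.** Simulations use −500…1000 ms at 240 Hz-equivalent
  bins (step 1000/240 ms), mirroring the empirical acquisition; the
  integrator step equals the feature bin width.
* **Integration.** The state equation is linear in $g$ for fixed $v$, so a
  zero-order-hold matrix-exponential step is exact for piecewise-constant
  input and deterministic — no adaptive ODE solver variance enters model
  comparison. A fine-step RK4 oracle (same input hold) agrees to $<10^{-6}$
  relative error in the test suite.
* **Input knowledge at inversion.** The gamma input parameters are carried
  on log scale and can be estimated (`input_var > 0`), mirroring their
  estimation from empirical data. The *default* for the simulation study
  fixes them at the generating values: with a single exogenous input the
  four state trajectories are strongly collinear, and freeing the input
  shape opens trade-off directions between input timing and coupling that
  blur the question the study asks (which couplings generated the data?).
  `tau` remains estimable throughout.
* **Magnitude vs power.** "Absolute values averaged" is read as averaging
  Morlet magnitudes for the induced condition, with evoked treated
  consistently; `measure = "power"` switches both to squared magnitudes.
* **Wavelet normalisation.** L2 by default so unit-variance broadband noise
  yields flat mid-band power; `normalisation = "l1"` preserves tone
  amplitude instead.
* **Baseline bin.** The very first time bin is used as the baseline
  reference, replicating the empirical pipeline literally even though that
  bin sits in the wavelet edge zone; `reference = "first_valid"` with a
  margin is available.
* **Per-subject normalisation.** `normalise_spectra()` divides by the
  maximum absolute baseline-corrected value, making coupling priors
  comparable across subjects.

## Variational inversion

`variational_laplace()` maximises a free-energy bound $F$ on the log model
evidence under a Gaussian observation model with Gaussian parameter priors:

* Gauss–Newton updates of the posterior mean with a central
  finite-difference Jacobian of the integrator (steps scaled to the prior
  standard deviations);
* Levenberg–Marquardt damping, escalated whenever a candidate step fails to
  increase $F$, so accepted free energies are monotone by construction;
* closed-form Laplace covariance $\Sigma = (\Sigma_0^{-1} + J^\top \Pi
  J)^{-1}$;
* an EM update of one noise log-precision per condition (evoked and induced
  features arise from different amounts of trial averaging; a Gamma
  hyperprior with shape/rate $10^{-3}$ keeps the update proper, and log
  precisions are capped at 32 so noiseless data cannot overflow);
* stopping when the free-energy gain stays below $10^{-2}$ nats for two
  accepted steps, or after 128 iterations; non-convergence flags the result
  rather than erroring.

$F$ includes the expected-residual trace terms, so on a linear-Gaussian
problem with fixed noise it equals the analytic log marginal likelihood
exactly; the test suite checks mean, covariance and $F$ against closed-form
Bayesian linear regression at $10^{-6}$.

Model evidence accounting is the point of the exercise: a parameter whose
posterior is pulled away from its prior pays a KL complexity charge, so
richer models win only when their extra coupling genuinely explains
spectral dynamics. Estimate quality is summarised by
`mse_percent()` — $100\sum_i(\hat\theta_i-\theta_i)^2 / \sum_i\theta_i^2$
over the union of free and generating $A$ off-diagonals and $B$ entries, a
normalisation anchored so that perfect estimates give 0% and all-zero
estimates exactly 100%.

## Bayesian model selection

`fixed_effects_bms()` sums log evidence over subjects (one model for the
whole group) and reports posterior model probabilities under a uniform
model prior. `random_effects_bms()` treats the model as a random effect:
subject-wise assignments and Dirichlet concentrations are updated
variationally, and exceedance probabilities — the probability that a model
is more frequent than all competitors — come from $10^6$ seeded Dirichlet
draws (the two-model case is cross-checked against the exact Beta tail).
With a single subject the hierarchical scheme does not reduce to the
fixed-effects posterior: for `prior_alpha` $\le 1$ the digamma terms make
the single assignment winner-take-all, so only the model ranking is
comparable across schemes; the regression test asserts exactly that.

## Group inference on modulation

Subject-specific $B$ blocks are back-projected to frequency space
(`coupling_to_frequency()`) — subjects' mode bases differ, frequency space
is the common currency — then smoothed with a Gaussian kernel of 8 Hz FWHM
(renormalised truncation at the band edges, so constants are preserved),
and tested element-wise with one-sample t statistics across subjects.
Excitatory (positive) and inhibitory (negative) effects get separate
one-tailed maps at an uncorrected $p < 0.005$; Bonferroni/FDR switches are
provided as clearly-labelled extensions. Smoothing operates on signed
estimates. A null simulation (i.i.d. zero-mean subject maps, 1000
replicates) verifies the suprathreshold rate is binomially compatible with
the nominal $p$.

## The synthetic study

`two_area_truth()` returns the published generating parameters of the
face-validity study: two areas with two frequency modes each, nine nonzero
$A$ off-diagonals, and — in the `er+ir` variant — two modulated connections
($B_{32} = 0.15$, $B_{42} = -0.10$, both outgoing from area 1's second
mode). The `er` variant sets $B = 0$. The printed flattened matrices are
mapped row-major with state order (area1·mode1, area1·mode2, area2·mode1,
area2·mode2); the mapping is confirmed by the positions of the published
*estimated* $B$ entries, which are unambiguous. Observation noise is
i.i.d. Gaussian on the mode coefficients at 13.8 dB, with the signal
variance taken over post-onset bins.

`identification_study()` fits all three candidate models (`er_ir`, `er1`
with the correct sparsity but no modulation, `er2` fully connected without
modulation) to both datasets over seeded replicates. At the defaults the
generating model wins on virtually every `er+ir` replicate; on `er` data
the `er1` vs `er2` race is intrinsically close — with one scalar input the
four state trajectories have effective rank ≈ 2–3, so the three extra
`er2` parameters are weakly informed and their Occam penalty is small —
and the correct-selection rate sits near 80%. The replicate *median* MSEs
reproduce the published ordering on both datasets (generating model
smallest; fully-connected model largest).

What the generator deliberately does **not** emulate: trial-level
variability (noise enters at the feature level, where the model predicts),
lead fields and sensor noise, artefacts, or between-subject variability.
Passing the identification study therefore demonstrates that the
*inversion and selection machinery* is sound at realistic SNR — not that
real MEG preprocessing is free of further confounds.

## Numerical notes and limitations

* Problem sizes: the study uses 4 states × 361 bins × 2 conditions per
  dataset and 12–15 free parameters per model; one inversion takes well
  under a second, the 20-replicate study a couple of minutes.
* Singular system matrices fall back to a pseudo-inverse in the
  zero-order-hold step; diverging trajectories raise an error naming the
  most unstable eigenvalue of $(A + vB)/\tau$.
* Zero between-subject variance in a t-map element yields $\pm\infty$ with
  a flag rather than an error.
* The published per-dataset free energies are not reproducible (they depend
  on unstated data scaling and priors) and are not targets here; model
  *ranking* and MSE *ordering* are.
* Exceedance Monte-Carlo error at $10^6$ draws is ~0.0005; seeds make all
  stochastic results reproducible.
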