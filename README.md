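# specdcm

Dynamic causal modelling of evoked and induced spectral responses.

Event-related brain oscillations have two components: an **evoked** part,
phase-locked to the stimulus (it survives trial averaging), and an
**induced** part with trial-to-trial latency jitter (it survives only when
time-frequency magnitudes are averaged). The two are usually separated by
subtraction, which silently assumes they add linearly. `specdcm` instead
fits one generative model to both at once, for researchers analysing
source-space M/EEG spectra who want to ask *which couplings, and which
condition-specific coupling changes, generated my evoked and induced
responses?*

## The model

Each source's spectrum is reduced to a few frequency modes, and the stacked
mode amplitudes `g(t)` obey a bilinear state equation

    tau * dg/dt = (A + vB) g + C u(t)

* `A` — coupling within and between sources, shared by both components;
  within-mode entries are linear coupling, between-mode entries nonlinear
  (cross-frequency) coupling; the diagonal is fixed at −1 so every mode
  decays intrinsically.
* `B` — coupling *changes* switched on by the condition indicator
  (`v = 0` evoked, `v = 1` induced): the mechanism of induced responses
  beyond the shared dynamics.
* `C u(t)` — a gamma-shaped stimulus-locked input.

The package provides the full workflow:

* **features** — Morlet transform (wavelet number 7), evoked/induced
  condition construction, baseline correction, subject-specific SVD mode
  reduction, lead-field pseudo-inverse source projection;
* **dynamics** — exact zero-order-hold matrix-exponential integration of
  the state equation;
* **inversion** — variational Laplace (`variational_laplace()`):
  Gauss–Newton with Levenberg–Marquardt damping, per-condition noise
  precisions, free energy `F` as log-evidence approximation;
* **model selection** — fixed-effects pooling and random-effects
  hierarchical BMS with exceedance probabilities;
* **group inference** — frequency-space back-projection of modulation
  matrices, 8 Hz FWHM Gaussian smoothing, one-sample t-maps at
  p < 0.005 (uncorrected), separately for excitatory and inhibitory
  effects;
* **synthetic** — the two-area, two-mode identifiability study with the
  published generating parameters.

## Worked example: can the scheme tell induced mechanisms apart?

Simulate a dataset whose induced condition is generated by genuine coupling
changes (`er+ir` variant, 13.8 dB SNR), then invert three candidate models:
the generating one, the same sparsity without modulation (`er1`), and a
fully connected linear alternative (`er2`).

```r
library(specdcm)

truth  <- two_area_truth("er+ir")
recipe <- simulation_recipe(truth$coupling, truth$graph, snr_db = 13.8, seed = 7)
data   <- simulate_dataset(recipe)
data
#> <subject_features> 4 state(s) x 361 bins x 2 condition(s) (evoked, induced)

fits <- lapply(candidate_models(), function(g) variational_laplace(data, g))
for (nm in names(fits))
  cat(sprintf("%6s  F = %9.2f   MSE = %5.2f%%\n", nm,
              free_energy(fits[[nm]]), mse_percent(fits[[nm]], truth$coupling)))
#>  er_ir  F =   5662.13   MSE =  4.31%
#>    er1  F =   5585.51   MSE = 33.55%
#>    er2  F =   5585.35   MSE = 49.11%
```

The generating model wins by ~77 nats of free energy — decisive evidence —
and also has by far the smallest normalised coupling error: precluding the
modulation (`er1`) or throwing connections at the problem (`er2`) both fit
worse *and* distort the estimated coupling. Posterior summaries are tidy:

```r
tidy(fits$er_ir)
#> # A tibble: 14 × 6
#>   term   block estimate std.error prior.mean prior.sd
#>   <chr>  <chr>    <dbl>     <dbl>      <dbl>    <dbl>
#> 1 A[2,1] A       0.0501    0.0540          0    0.354
#> 2 A[1,2] A       0.253     0.0514          0    0.354
#> 3 A[3,2] A       0.220     0.0208          0    0.354
#> ...
```

Group-level comparison works from a subjects × models evidence table. With
the published summed group evidences of three empirical architectures
(modulation of forward, backward, or both connection sets):

```r
tab <- evidence_table(matrix(c(-255490, -242540, -272900), 1, 3,
                             dimnames = list(NULL, c("F", "B", "FB"))))
fixed_effects_bms(tab)
#> <bms_fixed> best: B (relative log evidence 12950.0)
#> # A tibble: 3 × 4
#>   model summed_log_evidence relative_log_evidence posterior_probability
#>   <chr>               <dbl>                 <dbl>                 <dbl>
#> 1 F                 -255490                -12950                     0
#> 2 B                 -242540                     0                     1
#> 3 FB                -272900                -30360                     0
```

The backward-modulation model carries essentially all posterior
probability (> 0.99): induced responses are better explained by top-down
coupling changes than by feedforward ones.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/specdcm.R simulate --variant er+ir --snr-db 13.8 --seed 1 --out sim.json
Rscript inst/cli/specdcm.R invert   --data sim.json --model sim_graph.json --out posterior.json
Rscript inst/cli/specdcm.R compare  --evidence evidence.csv --out bms.json
```

## Vignette

`vignettes/spectral-dcm-methods.Rmd` documents the model and its
assumptions, every default with units and rationale, the variational
scheme's numerics, what the synthetic generator does and does not emulate,
and known limitations.
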