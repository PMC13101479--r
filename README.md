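# switchrate

Rate inference and biosensor statistics for tunable Cre-lox switching
reporters.

## The problem

Recombinase-based reporters convert cells irreversibly from a dark
(unrecombined) to a fluorescent (recombined) genotype at a low, per-hour rate
*k* set by an inducer — cumate for characterisation constructs, arsenite for a
whole-cell biosensor. Because the switch is genetic and heritable, signal
accumulates over many generations: tiny differences in inducer concentration
compound into measurable differences in the fraction of fluorescent cells,
which is what makes these circuits usable as sensitive, memory-carrying
biosensors (including exposure under anoxic conditions with delayed aerobic
readout). The catch is that *k* itself is never observed — it must be inferred
from fraction-versus-time data with care about identifiability.

`switchrate` is a tidyverse-style R package for the full analysis chain:

* **Inference** — fraction trajectories follow logistic mean dynamics

  $$f(t) = \frac{f_{\max}}{1 + (f_{\max}/f_0 - 1)e^{-kt}}$$

  with `f0` fixed to the measured time-zero fraction. Each technical
  replicate is fitted with both this model (binomial likelihood, ensemble
  MCMC, maximum-likelihood point estimate) and its small-`f` exponential
  limit `f0·exp(kt)` (one fewer parameter), and the rate is taken from the
  model with the lower AICc — flat or far-from-saturation trajectories,
  where `fmax` is degenerate, then fall to the exponential fit. Replicate
  ensembles are summarised as mean curves with min–max envelopes and
  pointwise dose–response tables.
* **Cytometry** — control-quantile gating ("exclude the dark control
  strain"), rare-fraction estimation with binomial standard errors (down to
  ~7×10⁻⁴ positives in 150,000 events), bootstrap-SE medians for
  transcription reporters, delimited-text event tables (optional FCS adapter
  via flowCore).
* **Plate reader** — blank averaging, gain-invariant relative fluorescence
  `r(t) = F'(t)/OD'(t)`, endpoint variant, sliding-window growth rates.
* **Biosensor statistics** — Welch t-tests between adjacent inducer
  concentrations combined across experiments by Fisher's method (detection
  ladder and its type-I calibration), leakage summaries, serial-passage
  generation accounting `log2(ρᵢ·D/ρᵢ₋₁)`, and reporter-stability tracking.
* **Synthetic data** — an exact stochastic jump process whose mean-field
  limit is the logistic dynamics above, log-normal single-cell cytometry
  events with an optional immature (dim) subpopulation, plate-reader series
  with blanks, and a Hill-type dose model used *only* as generator ground
  truth. Every estimator in the package is validated against this generator;
  no laboratory data are needed.

## Worked example

```r
library(switchrate)

# ground-truth dose model (generator only) and one induced condition
dm <- dose_model(k_max = 0.6, K_half = 5e-6, hill_n = 1.5, k_leak = 0)
k_true <- dose_response_rates(dm, 5e-6)$k   # 0.3 per hour

# simulate a switching population, 7 sampling times over 16 h
traj <- simulate_switching(1e5, f0 = 0.01, k = k_true,
                           t_grid = seq(0, 16, length.out = 7),
                           fmax = 0.9, seed = 11)

# fit both models, select by AICc
fit <- fit_switching_rate(traj, concentration = 5e-6, seed = 1)
fit
#> <switch_fit: logistic model>
#>   k = 0.30161 per hour, fmax = 0.8927, f0 = 0.01
#>   logLik = -2.456e+05, n_obs = 6, AICc = 4.913e+05
glance(fit)
#> # A tibble: 1 × 10
#>   model        k  fmax    f0   logLik    AICc n_obs n_params converged non_identifiable
#>   <chr>    <dbl> <dbl> <dbl>    <dbl>   <dbl> <int>    <int> <lgl>     <lgl>
#> 1 logistic 0.302 0.893  0.01 -245628. 491263.     6        2 TRUE      FALSE
```

The saturating trajectory identifies both parameters: the selected logistic
model recovers the true rate (0.302 vs 0.3 h⁻¹) and saturation fraction
(0.893 vs 0.9). A trajectory that stays far below `fmax` would instead be
assigned the exponential fit, whose single parameter is the same `k`.

Supporting calculations print equally directly:

```r
generations(1e4, n_cycles = 4)$cumulative_generations[4]
#> 53.15085          # four 10,000-fold passages ~ 53 generations
ppb_to_nM(10)
#> 133.4757          # the 10 ppb arsenic drinking-water limit in nM
```

An end-to-end synthetic run (simulate → gate → fit → report, with a manifest
of seeds and artifact hashes) is one call:

```r
manifest <- run_pipeline(pipeline_config(seed = 42), out_dir = "run1")
```

See `vignettes/switching-rate-inference.Rmd` for the model, its
identifiability issues, all numerical choices, and the chosen validation
study designs.

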