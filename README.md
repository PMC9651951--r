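# timefields

Hierarchical Bayesian analysis of hippocampal time-cell populations:
do temporal receptive fields tile a *logarithmic* time axis?

## The problem

Time cells fire at reliable latencies after a delay-initiating event;
collectively they carry a timeline of the recent past. Logarithmic
(Weber-Fechner) compression of that timeline makes two quantitative
predictions: the within-trial field width grows linearly with the peak time
(σ_w ∝ M), and the density of peaks across the population falls off as
p(M) ∝ M^-α with α = 1. Testing the first prediction honestly requires
separating within-trial width from across-trial jitter of the field
location — trial averaging otherwise inflates widths, more for late cells.

`timefields` is for computational neuroscientists who want that analysis
chain end to end, with a simulator providing ground truth for every stage:

* **simulate** — spike trains from a mixture model (Gaussian or log-normal
  field over a uniform background), per-trial field jitter, power-law peak
  distribution, behavioural event coupling, distractor and interneuron
  units (`simulate_population()`).
* **screen** — classic time-cell selection: < 5 Hz, field-vs-constant
  log-likelihood ratio > 5.66 (≈ χ²₃ at p = .01) on all, even and odd
  trials, peak inside the delay (`screen_units()`).
* **bounds** — KS grid search for the admissible peak range of the bounded
  power law (`select_bounds()`).
* **fit** — the hierarchical model and four alternatives (field shape,
  trial-varying width, exponential/Weibull population laws), fitted by an
  adaptive Metropolis-within-Gibbs sampler in C++, with split-R̂/ESS
  diagnostics and WAIC (`fit_hbm()`, `compare_waic()`).
* **analyse** — width- and jitter-versus-peak regressions with Bayes
  factors, sign-split χ², exponent posterior summaries, CDF-log-linearity,
  early/late splits, event-timing correlations (`population_report()`).
* **pipeline** — all stages with content-hash caching (`run_pipeline()`).

The model, per spike time t_j on trial i (delay length l):

    p(t_j) = a1 · N(t_j | μ_i, σ_w²) + (1 − a1)/l
    μ_i ~ N(M, σ_t²)
    M ~ τ^-α / C   on [min, max]

fitted jointly across trials, cells and the population; posterior means are
the point estimates for downstream statistics.

## Worked example

```r
library(timefields)

sim <- simulate_population(generator_config(
  n_time_cells = 131, n_distractor_cells = 0, n_interneurons = 0,
  trials_per_cell = 25, seed = 12))
fit <- fit_hbm(sim$spikes, sim$delay, bounds = c(0.35, 7.2),
               control = mcmc_control(chains = 4, warmup = 1000,
                                      samples = 500, seed = 12))
fit
#> hierarchical time-field fit (variant: main)
#>   131 cells, 3275 trials; bounds [0.35, 7.2] s; delay 8 s
#>   4 chains x 500 draws
#>   alpha: mean 0.931, 95% CI [0.738, 1.125]
#>   WAIC 103512.6 (p_waic 1933.5)

alpha_posterior_summary(fit$population$alpha)
#> # A tibble: 1 x 6
#>    mean    sd ci_lower ci_upper frac_in_window sd_from_zero
#>   <dbl> <dbl>    <dbl>    <dbl>          <dbl>        <dbl>
#> 1 0.931 0.100    0.738     1.13          0.572         9.30
```

The population was generated with α = 1 (logarithmic compression): the
posterior mean lands near 1, the 95% credible interval covers it, more than
half the posterior mass sits in [0.9, 1.1], and zero is excluded by ~9
posterior standard deviations. `stats::lm(field_width ~ M, data = fit$cells)` recovers the
generating width law to ~15% (slope 0.121 here against the generating
0.14; posterior widths are slightly attenuated near the delay boundary —
see the methods vignette), and `autoplot(fit, "cdf")` shows the
straight-in-log-time CDF that is the signature of α = 1.

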