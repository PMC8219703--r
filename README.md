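# hyporheicRT

Bayesian inversion of micropollutant breakthrough curves along hyporheic
(streambed) flowpaths.

Bedforms pump surface water through shallow sediment flowpaths that act as
biogeochemical hotspots. When a set of micropollutants is injected into a
recirculating flume, porewater samplers positioned on individual flowpaths
record breakthrough curves from which compound- and flowpath-specific fate
parameters can be inferred. This package implements that analysis end to
end for researchers in contaminant hydrology and environmental chemistry:

* a **forward model** — the 1-D advection–dispersion–retardation–decay
  equation

  *R ∂c/∂t = D_h ∂²c/∂x² − v ∂c/∂x − k c*

  solved with Crank–Nicolson finite differences (compiled tridiagonal
  core), driven by the measured time-varying surface-water concentration
  as inlet boundary condition (`solve_ade()`, verified against the exact
  constant-inlet erfc solution, `analytic_constant_bc()`);
* **DREAM inference** — 20-chain differential-evolution adaptive
  Metropolis sampling of (k, R, v, L, D_h) with uniform priors on the
  compound parameters (k: 10⁻⁵–4 h⁻¹, R: 1–49) and Gaussian priors on the
  flowpath geometry from a hydrodynamic particle-tracking model
  (`dream_sample()`, `build_prior_set()`), including the two-stage scheme
  that calibrates dispersion on a conservative reference compound and
  chains it into every other fit (`two_stage_calibration()`);
* **post-processing** — samplewise half-lives DT50 = ln 2 / k,
  detectability thresholds from the measurement precision with "Inf"
  masking of non-measurable removal, RMSE goodness of fit, and a wide
  compound × flowpath results table (`k_to_dt50()`, `dt50_threshold()`,
  `apply_inf_mask()`, `assemble_results_table()`);
* a **synthetic flume-experiment generator** with known ground truth,
  lognormal measurement noise and left-censoring at the LOQ with
  LOQ·2^(−1/2) substitution, so the full pipeline is testable without
  external data (`scenario_spec()`, `simulate_dataset()`,
  `gen_benchmark_scenario()`).

## Worked example

Simulate a non-retarded degrader on flowpath b (11.1 cm, 24.3 h median
geometry), fit it, and summarize:

```r
library(hyporheicRT)

spec <- scenario_spec(
  compounds = list(
    acesulfame_like = list(
      k_sw = 0.011, loq = 0.01,
      truth = list(b = list(k = 0.0189, R = 1)))),
  noise_rel_sd = 0.05, seed = 42)
ds <- simulate_dataset(spec)

priors <- build_prior_set(default_flowpaths()$b)
fit <- dream_sample(ds$observations$acesulfame_like$b, priors,
                    ds$boundaries$acesulfame_like,
                    dream_settings(n_generations = 5000, seed = 7))
summarize_posterior(fit)
```

```
Posterior summary (50000 pooled draws, acceptance 0.20, converged)
  parameter    median       q25       q75      iqr  rhat
1         k 0.0251600 2.200e-02 0.0299200 0.007919 1.046
2         R 1.3220000 1.152e+00 1.5880000 0.436400 1.044
3         v 0.0052720 4.773e-03 0.0058020 0.001029 1.009
4         L 0.0952800 8.252e-02 0.1078000 0.025320 1.023
5       D_h 0.0001065 8.224e-05 0.0001302 0.000048 1.008
```

The removal rate k is recovered within ~30% (truth 0.0189 h⁻¹; half-life
DT50 = ln 2 / 0.0252 ≈ 27.5 h against a truth of 36.7 h) and the
geometry/dispersion parameters sit inside their priors. The retardation
median 1.32 for a truly non-retarded solute illustrates a structural
limit, not a sampler defect: the transport equation depends on
(k, R, v, D_h) only through the ratios k/R, v/R, D_h/R, so R itself is
resolved by the velocity/dispersion priors rather than the data (see the
methods vignette, `vignettes/reactive-transport-inference.Rmd`).
Half-lives exceeding the flowpath's detectability threshold
(`dt50_threshold(0.05, 24.3)` ≈ 160 h at 5% measurement precision) are
reported as `Inf` in the results table.

A command-line surface over the same pipeline is in
`inst/cli/hyporheicrt` (subcommands `simulate`, `fit`, `report`,
`recover`; see `?rt_cli`).

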