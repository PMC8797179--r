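# pombesize

Stochastic cell-size dynamics and size-control inference for fission
yeast (*Schizosaccharomyces pombe*).

Fission yeast grows through three distinct phases in every cell cycle —
slow exponential **elongation** (rate *g*₀), a **septation** plateau, and
a brief fast **reshaping** burst (rate *g*₁ > *g*₀) as the new cell ends
round off — and its cell-size distribution along a lineage is typically
*bimodal*, unlike the unimodal distributions of exponentially growing
microbes. `pombesize` implements a piecewise deterministic Markov model
that captures this: a cell traverses *N* effective cell-cycle stages
(*N*₀ elongation, *N* − *N*₀ − *N*₁ septation, *N*₁ reshaping) with
stage-transition rate *a V*(*t*)^*α*, then divides, the tracked daughter
keeping a fraction *R* of the mother's size — fixed at *p* (model I) or
Beta(*p*ν, (1−*p*)ν)-distributed (model II). The exponent *α* is the
strength of size control: *α* → 0 timer, *α* = 1 adder, *α* → ∞ sizer
(conventional slope *β* = 2^(1−*α*)).

The package is aimed at quantitative cell biologists analysing
single-cell lineage time courses (e.g. from microfluidic "mother
machine"-style experiments) and at modellers studying size homeostasis.
It provides:

* an **exact stochastic simulator** of lineages (`simulate_lineage()`,
  `sample_timecourse()`, `generate_dataset()`), with both a fast
  phase-level sampler (gamma increments of *V^α*) and a stage-by-stage
  oracle sampler;
* **closed-form stationary distributions**: the lineage cell-size
  density and birth-size density by numerical transform inversion
  (`cellsize_density_det()`, `cellsize_density_stoch()`,
  `birth_density()`), the zero-noise limit mixture with its phase
  weights *w*₀, *w*ₛ, *w*₁ (`limit_distribution()`), and
  birth/division-size correlations (`corr_det()`, `corr_stoch()`);
* the full **five-step inference pipeline** (`infer_all()`,
  `bootstrap_estimates()`) recovering every model parameter from lineage
  data by distribution matching — a far more reliable read-out of the
  size-control strategy than the slope of the birth/division regression,
  whose *R*² on this kind of data is ~0.1;
* fitted parameter sets for **seven published growth conditions**
  (`reference_conditions()`), plain-text lineage CSV and YAML parameter
  I/O, and a thin CLI (`inst/cli/pombesize-tool`).

## Worked example

Simulate a synthetic experiment at the published EMM 28 °C (model I)
parameters and re-infer everything from the files alone:

```r
library(pombesize)

gp <- reference_params("EMM_28C", "I")
gp
#> Three-phase cell-size model parameters
#>   growth:    g0 = 0.214 /h, g1 = 0.409 /h
#>   control:   a = 0.055, alpha = 1.767
#>   stages:    N = 17.46 (elongation 11.26, septation 4.987, reshaping 1.214)
#>   division:  deterministic, partition ratio p = 0.459 (model I)

limit_distribution(gp)
#> Zero-noise limit of the lineage size distribution
#>   sizes:   v_b = 7.053, v_m = 14.22, v_d = 15.37
#>   weights: w0 = 0.7625 (elongation), ws = 0.1935 (septation atom), w1 = 0.04397 (reshaping)
```

So at these parameters a cell is born at ~7.1 µm, enters septation at
~14.2 µm and divides at ~15.4 µm, spending ~76% of the cycle elongating
and ~4.4% reshaping — the *w* weights match the published estimates for
this condition.

```r
ds  <- generate_dataset(gp, n_lineages = 300, generations = 60, seed = 1)
fit <- infer_all(ds, model = "I", seed = 2)
fit
#> Size-control fit (model I)
#>   g0         0.2146
#>   g1         0.4469
#>   a         0.04237
#>   alpha       1.846
#>   N           16.12
#>   N0          10.49
#>   N1         0.8593
#>   p          0.4663
#>   nu             NA
#>   distribution-matching objective 6.508e-05 over 100 bins
```

All parameters are recovered close to their generating values
(α 1.85 vs 1.77, *N* 16.1 vs 17.5, *g*₀ 0.215 vs 0.214 h⁻¹, ...).
Compare with the conventional regression read-out on the same data:

```r
gens <- extract_generations(ds)
conventional_beta(gens$V_b, gens$V_d)
#> Conventional size control: V_d = 0.5372 * V_b + 11.33  (n = 18000)
#>   residual sd 1.892, R^2 0.062; slope 0/1/2 ~ sizer/adder/timer
alpha_to_beta(fit$params$alpha)
#> [1] 0.5565019
```

The two routes agree (slope ≈ 0.54 vs 2^(1−α̂) ≈ 0.56, sizer-like
control), but the regression's *R*² of 0.06 shows why the
distribution-matching route is the reliable one. Bootstrap standard
errors: `bootstrap_estimates(ds, fit)`.

See `vignettes/cell-size-model.Rmd` for the model, the transform
inversions, and every numerical and design choice.

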