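---
title: "A three-phase stochastic model of cell-size homeostasis in fission yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-phase stochastic model of cell-size homeostasis in fission yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombesize)
```

## The model

Fission yeast does not grow exponentially through its cell cycle. A
lineage time course shows three phases: slow exponential *elongation* at
rate $g_0$ during G2, a *septation* plateau while the division septum is
built, and a brief, fast exponential *reshaping* burst at rate $g_1 > g_0$
as the new cell ends round off. `pombesize` models a cell as progressing
through $N$ effective cell-cycle stages — phenomenological levels of a
division-triggering regulator, not the biological cycle phases — with the
first $N_0$ stages in elongation, the middle $N - N_0 - N_1$ in septation
and the last $N_1$ in reshaping. The transition rate out of any stage at
time $t$ is $a\,V(t)^\alpha$: larger cells progress faster, and the
exponent $\alpha$ is the *strength of size control*. $\alpha \to 0$ gives
a timer, $\alpha = 1$ an adder, $\alpha \to \infty$ a sizer; under
symmetric division and small noise $\alpha$ maps onto the conventional
birth/division regression slope as $\beta = 2^{1-\alpha}$
(`alpha_to_beta()`).

Division follows the reshaping phase. The tracked daughter receives the
fraction $R$ of the mother's size: fixed at $p$ (*model I*), or drawn
from a $\mathrm{Beta}(p\nu, (1-p)\nu)$ distribution with mean $p$ and
variance $p(1-p)/(\nu+1)$ (*model II*). Deterministic partitioning is a
sentinel (`nu = NA`), not a large $\nu$, so the two model branches stay
explicit.

The analytical backbone is a scaling property: whatever $\alpha$ is, the
*generalized size* $V^\alpha$ behaves as an adder. Over the elongation
phase the increment $\Delta_0 = V_s^\alpha - V_b^\alpha$ is gamma with
shape $N_0$ and mean $M_0 = N_0 g_0 \alpha / a$, and likewise
$\Delta_1 = V_d^\alpha - V_s^\alpha$ with shape $N_1$ and mean
$M_1 = N_1 g_1 \alpha / a$, independently of the birth size. The total
added $V^\alpha$ is therefore hypoexponential, with Laplace transform
$b(\lambda) = (1 + M_0\lambda/N_0)^{-N_0}(1 + M_1\lambda/N_1)^{-N_1}$
(`laplace_b()`). $N$ controls added-size variability: as
$N \to \infty$ at fixed $M_0, M_1$ the added size becomes deterministic.

### Fractional stage counts

Stage counts are stored as real numbers. Fitted values in the literature
are fractional (e.g. $N \approx 17.5$, $N_1 \approx 1.2$), so per-phase
added sizes use gamma rather than Erlang distributions; the integer case
is recovered exactly, and the package carries a stage-by-stage sampler
(`simulate_generation_stage()`, integer shapes only) purely as an
independent cross-check of the phase-level gamma shortcut
(`simulate_generation_phase()`). The two samplers are compared by KS
tests in the test suite.

## Simulation

`simulate_lineage()` chains generations through
$V_b^{(k+1)} = R^{(k)} V_d^{(k)}$. The phase-level sampler exploits the
fact that per-phase increments of $V^\alpha$ and the partition ratios are
independent of the current size: it draws them up front and only chains
the birth sizes, which makes $10^5$ generations a matter of a second.
Septation-phase durations are gamma with shape $N - N_0 - N_1$ and rate
$a V_s^\alpha$; a parameterization with $N = N_0 + N_1$ simply has no
septation phase. The default burn-in of 50 generations precedes all
stationary statistics; seeds are explicit function arguments.
`sample_timecourse()` interpolates the deterministic within-generation
growth curves on a regular grid and optionally applies multiplicative
log-normal measurement noise of a given coefficient of variation.

## Closed-form distributions and their inversion

For deterministic partitioning the steady-state transform of the lineage
generalized size is
$$F(\lambda) = K \int_\lambda^\infty f(u) \prod_{k \ge 0} b(p^{\alpha k} u)\,du,$$
where $f$ (`f_func()`) weights the three phases and $K$ enforces
$F(0)=1$. The density itself is obtained from the Fourier form: the
characteristic function of $y\,\tilde p(y)$ (with $\tilde p$ the density
of $y = V^\alpha$) is $K f(i\lambda)\prod_k b(p^{\alpha k} i\lambda)$,
which `cellsize_density_det()` inverts by trapezoid quadrature on a
frequency grid, mapping back through
$p(x) = \alpha x^{\alpha-1} \tilde p(x^\alpha)$.

Numerical choices, all visible in the density objects' metadata:

* the infinite product is truncated at the smallest $k$ with
  $p^{\alpha k} < 10^{-12}$ (warned if more than 500 factors were
  needed);
* all powers and products are evaluated through (complex) logarithms;
  Pochhammer symbols and beta functions through `lgamma`/`lbeta`;
* the frequency grid extends until $|G|$ falls below $10^{-10}$ of its
  value at zero, with spacing at most $\pi / (8\,y_{\max})$ so the
  oscillatory factor is well resolved;
* the returned density is *not* renormalized — its raw trapezoid
  integral is reported (it should be within about $10^{-3}$ of 1, and
  the tests assert that), so inversion quality is observable;
* negative lobes beyond $10^{-3}$ of the peak raise an error, tiny ones
  are clipped to zero.

The $N \to \infty$ limit (`limit_distribution()`) collapses the
distribution onto a mixture over phases: $1/x$-shaped branches on
$[v_b, v_m]$ and $[v_m, v_d]$ with weights $w_0$, $w_1$ and a point mass
$w_s$ at the septation size $v_m$. The middle size is read as
$v_m = ((M_0 + M_1 p^\alpha)/(1-p^\alpha))^{1/\alpha}$ — the only parse
that preserves $v_m^\alpha - v_b^\alpha = M_0$ and
$v_d^\alpha - v_m^\alpha = M_1$ and reproduces the published phase
proportions — and the weights are the normalized phase durations. The
atom is reported as a (location, weight) pair and never discretized into
a density array; comparisons smooth it into the histogram bin that
contains it. These weights are also the practical estimate of the
fraction of the cell cycle spent in each phase, which is *not* $r_0 =
N_0/N$: early stages last longer because small cells progress slowly.

```{r}
limit_distribution(reference_params("EMM_28C", "I"))
```

The birth size has transform
$\prod_{n\ge 1} b(p^{\alpha n}\lambda)$ (`birth_laplace()`, inverted by
`birth_density()`). For strong control or small $p$ only the $n=1$
factor matters, giving the closed form of `birth_density_approx()` — a
generalized-gamma kernel times a confluent hypergeometric factor
${}_1F_1(N_1, N_0+N_1, (\beta_0-\beta_1)x^\alpha)$ evaluated in log
scale. Note the two exponents: $\beta_0 = N_0/(M_0 p^\alpha)$ *and*
$\beta_1 = N_1/(M_1 p^\alpha)$; with $N_1 = 0$ the factor is 1. The
truncation shifts the mean down by a factor $1-p^\alpha$, so the
approximation is positional only for genuinely large $\alpha$; the test
suite asserts that its sup-norm error shrinks as $\alpha$ grows rather
than a fixed closeness at moderate $\alpha$.

### Stochastic partitioning

With a beta partition ratio the division-size transform
$S(u) = \langle e^{-u V_d^\alpha}\rangle$ solves
$S(u) = b(u)\, \mathbb E_R[S(R^\alpha u)]$ and has the power series
$S(u) = \sum_n a_n u^n$ with $c_n = \mathbb E[R^{\alpha n}]$ (beta-moment
ratios), $b_n$ the Taylor coefficients of $b$, and the recursion
$a_n = (1-c_n)^{-1}\sum_{m<n} a_m c_m b_{n-m}$
(`series_coefficients()`). Because $S$ is the transform of a positive
variable the signs of $a_n$ and $b_n$ alternate exactly, so the
recursion is computed on log-magnitudes with no cancellation.

The series' convergence radius is $1/\max(A_0, A_1)$ — the nearest pole
of $b$ — which is smaller than the frequency range the inversion needs.
Inside 60% of the radius the series is summed directly with adaptive
truncation (an error is raised if 400 terms do not converge); outside,
$S$ is continued analytically along the required ray via the functional
equation, evaluating $\mathbb E_R$ with a 48-node Gauss–Legendre rule
under the beta weight and climbing an ascending, log-spaced modulus
ladder (about 300 rungs per $e$-fold) that interpolates previously
computed values. The continuation collapses onto the deterministic
product as $\nu \to \infty$ (asserted to TV $< 0.01$ in the tests), and
the resulting density matches million-sample simulations to TV $< 0.02$.

### Correlations

Under deterministic partitioning
$\rho(V_b^\alpha, V_d^\alpha) = p^\alpha$ exactly, independent of the
growth pattern (`corr_det()`). Under beta partitioning the added size is
still independent of the birth size, so
$\mathrm{cov} = \mathrm{Var}(V_b^\alpha)$ and
$$\rho^2 = \frac{[(2K_1+1)K_2 - K_1^2]\,(M_0+M_1)^2 + K_2 B}
                {[(2K_1+1)K_2 - K_1^2]\,(M_0+M_1)^2 + (K_2+1) B},$$
with $B = M_0^2/N_0 + M_1^2/N_1$ and
$K_j = \mathbb E[R^{j\alpha}]/(1-\mathbb E[R^{j\alpha}])$
(`corr_stoch()`). The ratio itself is $\rho^2$, not $\rho$: only the
square root has the correct $\nu \to \infty$ limit $p^\alpha$, and the
root form matches stochastic simulation to within Monte-Carlo error at
every $(\nu, \alpha)$ we probed. Partitioning noise *raises* this
correlation above $p^\alpha$ (it inflates the birth-size variance, and
$\rho = \sigma_b/\sigma_d$), approaching $p^\alpha$ from above as
$\nu \to \infty$ — the tests assert that monotone approach.

## Parameter inference

`infer_all()` runs five steps, each exposed separately:

1. **Partitioning** (`estimate_partition()`): $p$ is the mean partition
   ratio; model II fits $(p, \nu)$ by maximum likelihood in the
   $(p,\nu)$ parameterization with a method-of-moments start. A ratio
   series with zero variance returns $\nu = \infty$ with a warning
   rather than a spurious finite value.
2. **Control strength** (`estimate_alpha()`): the unique $\alpha$ at
   which the sample correlation of $(V_b^\alpha, V_d^\alpha)$ equals its
   model value ($p^\alpha$, or the model II expression above with the
   moments re-estimated at each candidate $\alpha$). Bisection on
   $[0.05, 10]$; monotonicity of the objective is checked empirically by
   bracketing, and an absent sign change (near-pure sizer data) returns
   the bracket edge, flagged, instead of extrapolating.
3. **Added-size moments** (`estimate_added_moments()`): inverts the
   closed-form birth-size moments for $S = M_0+M_1$ and
   $B = M_0^2/N_0 + M_1^2/N_1$.
4. **Growth rates** (`fit_three_stage()`): per-generation least squares
   of log size against the continuous
   exponential–constant–exponential model. For fixed change points the
   model is linear in $(\log V_b, g_0^{(k)}, g_1^{(k)})$, so change
   points are searched exhaustively on the sampling grid
   (coarse-to-fine for long generations). $g_0$ is the across-generation
   mean of $g_0^{(k)}$; the per-generation $g_1^{(k)}$ are *not* used
   for $g_1$ (the reshaping phase spans too few frames to estimate a
   rate reliably) — $g_1$ comes from the moment equations instead
   (`estimate_rates()`), choosing the root with $g_1 > g_0$.
5. **Stage numbers** (`fit_stage_numbers()`): minimizes
   $\sum_i |p(x_i) - \hat p(x_i)|^2$ between the theoretical stationary
   density and the sample histogram density at the bin centers. We use
   $M = 100$ equal-width bins spanning the observed sizes (the source
   analyses do not state a binning; the objective compares two proper
   densities, so it is invariant to the normalization convention). The
   search lattice is $N \in \{2,\dots,150\}$ step 5, $N_0$ step 3,
   $N_1$ step 1, followed by an exhaustive pass in the winning cell,
   with ties broken to the smallest $N$ then smallest $N_0$. Candidates
   whose moment equations admit no root with $g_1 > g_0 > 0$ are
   infeasible and skipped. By default a local Nelder–Mead refinement
   then polishes the triple continuously within the winning cell: stage
   counts are effective quantities and the gamma generalization makes
   fractional values meaningful — the reshaping count in particular
   typically sits between 1 and 2, where integer rounding would
   propagate a large quantization error into $g_1$ through
   $M_1 = N_1 g_1 \alpha / a$.

Change points are fitted per generation, not shared across generations:
generation durations vary several-fold, so a shared $(t_0, t_1)$ has no
natural scale. For datasets with very many generations the growth-rate
step subsamples a capped number of generations (default 2000, a design
choice: the standard error of $\bar g_0$ at that count is far below the
other error sources).

Bootstrap errors (`bootstrap_estimates()`) resample *lineages* with
replacement — the independent experimental units — 50 draws of 50
lineages by default, reporting the standard deviation of each parameter
across repetitions; each repetition searches $N$ in a ±30% window
around the point estimate with a finer lattice.

## The synthetic-data generator

`generate_dataset()` emulates the microfluidic lineage experiments the
model was built for: per growth condition, ~1500 lineages recorded every
3 minutes, each 50–70 generations, sizes (cell lengths) in micrometres,
generation times of order 2–4 h. Defaults: `dt_min = 3`,
multiplicative log-normal measurement noise with CV 0.02 (the source
data do not model measurement error; 2% is a realistic optical-segmentation
scale and small against the biological variability), burn-in 50
generations so recorded statistics are stationary. Parameter sets for
seven published growth conditions (two media by several temperatures,
both partitioning models) ship in `reference_conditions()`.

What the generator does *not* emulate: cell death and channel loss (real
lineages are censored), segmentation artifacts near division (which bias
the measured partition ratio), area-to-length conversion (the package
standardizes on length), and any within-phase growth-rate modulation
(e.g. the bilinear pre-mitotic pattern). Passing recovery tests on
synthetic data therefore demonstrates correctness of the estimator
chain, not robustness to those real-data pathologies. One visible
consequence of frame-grid sampling alone: birth sizes are read one frame
late and division sizes one frame early, which biases the measured
partition ratio slightly upward (~1%) and with it, mildly, $\alpha$;
both stay well within the tolerances asserted in the tests.

## Problem sizes used in validation

The validation suite runs stationary simulations of $10^5$ generations
for correlation checks, million-sample time-weighted histograms against
the analytic densities (TV < 0.02), and a full-pipeline recovery on a
synthetic dataset of 1500 lineages × 60 generations at the EMM 28°C
model I values, recovering $\alpha$ within ±0.15, $N$ within ±15% and
$g_1$ within ±20%; bootstrap repetitions are reduced to 6 in the test
suite (the estimates' spread, not its Monte-Carlo precision, is what is
asserted there).

## Known limitations

* Model II stage-number search re-evaluates the series/continuation
  density per candidate and is an order of magnitude slower than model
  I; use a narrowed `N_range` when the scale of $N$ is roughly known.
* The ${}_1F_1$ birth-density approximation is useful as an analytic
  form, but at $\alpha \approx 2$ it is visibly shifted relative to the
  exact inversion (its mean is low by a factor $1-p^\alpha$); prefer
  `birth_density()` for quantitative work.
* `estimate_alpha()` loses identifiability as data approach a pure
  sizer (the correlation is flat near zero in $\alpha$); the boundary
  flag reports this instead of a spurious interior root.
* The three-stage fit assumes a single exponential before septation; a
  bilinear (NETO) pre-mitotic pattern is absorbed into $g_0^{(k)}$ as an
  average rate.
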