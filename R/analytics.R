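# Closed-form transforms of the cell-size model and their numerical
# inversion. All distributional results are naturally expressed for the
# "generalized size" y = V^alpha, for which every phase contributes an
# additive gamma increment; densities of V itself are recovered by the
# change of variables p(x) = alpha * x^(alpha-1) * p_tilde(x^alpha).

# internal parameterization used by all transform code: stage counts,
# per-phase mean added sizes, partitioning
as_shape <- function(x) {
  if (inherits(x, "growth_params")) {
    dq <- derived_quantities(x)
    list(N = x$N, N0 = x$N0, N1 = x$N1, M0 = dq$M0, M1 = dq$M1,
         p = x$p, alpha = x$alpha, nu = x$nu)
  } else if (is.list(x) && all(c("N", "N0", "N1", "M0", "M1", "p", "alpha") %in% names(x))) {
    if (is.null(x$nu)) x$nu <- NA_real_
    x
  } else stop("expected a growth_params object or a shape list")
}

#' Laplace transform of the generalized added size over a cell cycle
#'
#' The increment `Delta = V_d^alpha - V_b^alpha` accumulated over one cell
#' cycle is the sum of independent gamma increments from the elongation and
#' reshaping phases, hence hypoexponential with transform
#' `b(lambda) = (1 + M0*lambda/N0)^(-N0) * (1 + M1*lambda/N1)^(-N1)`
#' (a factor with zero stages equals 1). Computed in log space; accepts
#' complex `lam` (used for Fourier inversion).
#'
#' @param lam Transform variable(s); real non-negative or complex.
#' @param dq A [derived_quantities()] object, [growth_params()] object, or
#'   list with `M0`, `M1`, `N0`, `N1`.
#' @return `b(lam)`, vectorized over `lam`.
#' @export
laplace_b <- function(lam, dq) {
  if (is.numeric(lam) && any(lam < 0)) stop("'lam' must be non-negative")
  sh <- if (inherits(dq, "derived_quantities")) dq else as_shape(dq)
  lg <- 0
  if (sh$N0 > 0) lg <- lg - sh$N0 * log(1 + sh$M0 * lam / sh$N0)
  if (sh$N1 > 0) lg <- lg - sh$N1 * log(1 + sh$M1 * lam / sh$N1)
  exp(lg)
}

# ((1 + A*lam)^k - 1) / (N*A*lam), with the lam -> 0 limit k/N
pow_diff_term <- function(lam, A, k, N) {
  out <- vector(mode = if (is.complex(lam)) "complex" else "numeric", length(lam))
  small <- Mod(lam * A) < 1e-8
  if (any(small)) {
    z <- lam[small] * A
    out[small] <- (k / N) * (1 + (k - 1) * z / 2 + (k - 1) * (k - 2) * z^2 / 6)
  }
  if (any(!small)) {
    z <- lam[!small]
    out[!small] <- (exp(k * log(1 + A * z)) - 1) / (N * A * z)
  }
  out
}

#' The weight function f of the lineage cell-size transform
#'
#' Evaluates the three-piece function that weights the added-size
#' transform in the steady-state lineage solution:
#' `f(lam) = (1+A1*lam)^N1 * [((1+A0*lam)^N0 - 1)/(N*A0*lam) +
#' (N-N0-N1)/N] + ((1+A1*lam)^N1 - 1)/(N*A1*lam)` with `A0 = M0/N0`,
#' `A1 = M1/N1`. `f(0) = 1` by taking limits, and `f` grows without bound
#' as `lam -> Inf`. With `N1 = 0` it reduces to the single-phase
#' (exponential growth) form `((1+A0*lam)^N - 1)/(N*A0*lam)`.
#'
#' @param lam Transform variable(s); real non-negative or complex.
#' @param dq As in [laplace_b()].
#' @param N Total stage count; defaults to the value carried by `dq`.
#' @return `f(lam)`, vectorized over `lam`.
#' @export
f_func <- function(lam, dq, N = NULL) {
  sh <- if (inherits(dq, "derived_quantities")) dq else as_shape(dq)
  if (is.null(N)) N <- sh$N
  if (is.numeric(lam) && any(lam < 0)) stop("'lam' must be non-negative")
  A0 <- if (sh$N0 > 0) sh$M0 / sh$N0 else NA_real_
  A1 <- if (sh$N1 > 0) sh$M1 / sh$N1 else NA_real_
  fac1 <- if (sh$N1 > 0) exp(sh$N1 * log(1 + A1 * lam)) else 1 + 0 * lam
  piece0 <- if (sh$N0 > 0) pow_diff_term(lam, A0, sh$N0, N) else 0
  piece1 <- if (sh$N1 > 0) pow_diff_term(lam, A1, sh$N1, N) else 0
  fac1 * (piece0 + (N - sh$N0 - sh$N1) / N) + piece1
}

# Pi_{k = k0}^{K} b(p^(alpha*k) * u); K is the smallest k with
# p^(alpha*k) < 1e-12 (warned if > 500). Vectorized over u, complex ok.
partition_product <- function(u, sh, k0 = 0) {
  if (sh$p >= 1) stop("infinite product requires p < 1")
  ratio <- sh$p^sh$alpha
  K <- ceiling(log(1e-12) / log(ratio))
  if (K > 500) warning("partition product truncated at k = 500 (p^alpha very close to 1)")
  K <- min(K, 500)
  lg <- 0
  for (k in k0:K) {
    z <- ratio^k * u
    if (sh$N0 > 0) lg <- lg - sh$N0 * log(1 + sh$M0 * z / sh$N0)
    if (sh$N1 > 0) lg <- lg - sh$N1 * log(1 + sh$M1 * z / sh$N1)
  }
  exp(lg)
}

# 1/K = integral_0^infty f(u) * Pi b(p^(alpha k) u) du (deterministic
# partitioning); equals the mean of V^alpha. `tail_fun` lets the
# stochastic-partitioning code reuse this with its own product term.
normalization_integral <- function(sh, tail_fun = NULL) {
  if (is.null(tail_fun)) tail_fun <- function(u) partition_product(u, sh)
  integrand <- function(u) {
    out <- Re(f_func(u, sh) * tail_fun(u))
    out[!is.finite(out)] <- 0
    out
  }
  # adaptive quadrature, with a graceful fallback onto a dense grid
  val <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-9, subdivisions = 1000L)$value,
    error = function(e) NA_real_)
  if (!is.finite(val) || val <= 0) {
    scale <- 1 / ((sh$M0 + sh$M1) / (1 - sh$p^sh$alpha))  # ~ 1/E[V^alpha]
    hi <- scale
    while (integrand(hi) > 1e-14 && hi < scale * 1e8) hi <- hi * 2
    u <- c(0, exp(seq(log(scale * 1e-7), log(hi), length.out = 4000L)))
    val <- pracma::trapz(u, integrand(u))
  }
  val
}

#' Steady-state Laplace transform of the lineage generalized cell size
#'
#' Evaluates `F(lambda) = <exp(-lambda * V^alpha)>` for a cell observed at
#' a uniformly random time along a lineage, under deterministic
#' partitioning:
#' `F(lambda) = K * integral_lambda^Inf f(u) * prod_k b(p^(alpha*k) u) du`,
#' with `K` fixed by `F(0) = 1`. The infinite product is truncated at the
#' smallest `k` with `p^(alpha*k) < 1e-12`.
#'
#' @param lam Non-negative transform values.
#' @param params A [growth_params()] object (deterministic partitioning).
#' @return `F(lam)`, vectorized.
#' @export
cellsize_laplace_det <- function(lam, params) {
  if (any(lam < 0)) stop("'lam' must be non-negative")
  sh <- as_shape(params)
  Kinv <- normalization_integral(sh)
  integrand <- function(u) f_func(u, sh) * partition_product(u, sh)
  vapply(lam, function(l) {
    if (l == 0) return(1)
    val <- tryCatch(
      integrate(integrand, l, Inf, rel.tol = 1e-9,
                subdivisions = 1000L)$value,
      error = function(e) {
        hi <- l * 2
        while (integrand(hi) > 1e-15 && hi < l * 1e9) hi <- hi * 2
        u <- exp(seq(log(l), log(hi), length.out = 6000L))
        pracma::trapz(u, integrand(u))
      })
    val / Kinv
  }, numeric(1))
}

# --- numerical inversion -------------------------------------------------

# Recover a non-negative integrable q on grid y from
# ch(lam) = integral q(y) exp(-i lam y) dy, by
# q(y) = (1/pi) integral_0^Inf Re[ch(lam) exp(i lam y)] dlam (trapezoid).
invert_cf <- function(chfun, y, tol = 1e-10, lam0 = NULL) {
  y_max <- max(y)
  lam <- if (is.null(lam0)) 0.25 / y_max else lam0
  ch_scale <- Mod(chfun(0))
  while (TRUE) {
    probe <- Mod(chfun(lam * c(1, 1.31, 1.77)))
    if (all(probe < tol * ch_scale) || lam > 1e7) break
    lam <- lam * 1.5
  }
  lam_max <- lam
  dlam <- min(pi / (8 * y_max), lam_max / 1200)
  nlam <- min(ceiling(lam_max / dlam) + 1, 2^19)
  lams <- seq(0, lam_max, length.out = nlam)
  G <- chfun(lams)
  w <- rep(diff(lams)[1], nlam); w[c(1, nlam)] <- w[1] / 2
  E <- exp(1i * outer(lams, y))
  q <- Re(colSums((w * G) * E)) / pi
  list(q = q, lam_max = lam_max, n_lam = nlam)
}

new_density_on_grid <- function(x, density, meta) {
  neg <- density < 0
  if (any(neg)) {
    worst <- -min(density) / max(density)
    if (worst > 1e-3)
      stop(sprintf("transform inversion failed: negative density lobes (%.2g of peak)", worst))
    density[neg] <- 0
  }
  structure(list(x = x, density = density,
                 integral = pracma::trapz(x, density), meta = meta),
            class = "density_on_grid")
}

#' @export
print.density_on_grid <- function(x, ...) {
  cat(sprintf("Density on grid: %d points on [%.4g, %.4g], raw integral %.6f\n",
              length(x$x), min(x$x), max(x$x), x$integral))
  cat("  formula:", x$meta$formula, "\n")
  invisible(x)
}

#' @export
as.data.frame.density_on_grid <- function(x, ...) {
  data.frame(size = x$x, density = x$density)
}

#' Write a tabulated density to a two-column CSV
#'
#' The header comment lines (prefixed `#`) record the formula and
#' truncation settings stored in the object's metadata.
#'
#' @param d A `density_on_grid` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_density <- function(d, path) {
  stopifnot(inherits(d, "density_on_grid"))
  meta <- d$meta
  hdr <- c(sprintf("# formula=%s", meta$formula),
           sprintf("# %s=%s", names(meta$settings), unlist(meta$settings)),
           sprintf("# raw_integral=%.10g", d$integral))
  writeLines(c(hdr, "size,density"), path)
  data.table::fwrite(data.frame(size = d$x, density = d$density), path,
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

# default size grid: covers the bulk of stationary mass, guided by the
# zero-noise support widened by the added-size and birth-size spreads
default_size_grid <- function(sh, n_grid) {
  lim <- limit_mixture_from_shape(sh)
  al <- sh$alpha
  B <- sh$M0^2 / max(sh$N0, 0.5) + if (sh$N1 > 0) sh$M1^2 / sh$N1 else 0
  pa <- sh$p^al
  sd_birth <- sqrt(pa^2 / (1 - pa^2) * B)
  y_lo <- max(lim$v_b^al - 5 * sd_birth, 1e-3 * lim$v_b^al)
  y_hi <- lim$v_d^al + 5 * sqrt(B)
  seq(y_lo^(1 / al), y_hi^(1 / al), length.out = n_grid)
}

#' Stationary lineage cell-size density (deterministic partitioning)
#'
#' Computes the probability density of cell size observed at a uniformly
#' random time along a lineage, by Fourier inversion of the closed-form
#' transform: `G(lambda) = K * f(i*lambda) * prod_k b(p^(alpha*k) i*lambda)`
#' is the Fourier transform of `y * p_tilde(y)` where `p_tilde` is the
#' density of `V^alpha`; the inverse transform is evaluated by trapezoid
#' quadrature on a frequency grid extended until `|G|` has decayed below
#' `1e-10`, and `p(x) = alpha * x^(alpha-1) * p_tilde(x^alpha)`.
#'
#' The returned density is not renormalized; its raw trapezoid integral is
#' reported in the object so that inversion quality can be checked (it
#' should be within about `1e-3` of 1).
#'
#' @param params A [growth_params()] object with deterministic
#'   partitioning, or an internal shape list.
#' @param grid Optional increasing grid of sizes; a default covering the
#'   bulk of the mass is constructed when omitted.
#' @param n_grid Number of grid points for the default grid.
#' @return A `density_on_grid` object.
#' @examples
#' d <- cellsize_density_det(reference_params("EMM_28C", "I"))
#' d$integral  # close to 1
#' @export
cellsize_density_det <- function(params, grid = NULL, n_grid = 400) {
  sh <- as_shape(params)
  if (is.null(grid)) grid <- default_size_grid(sh, n_grid)
  Kinv <- normalization_integral(sh)
  chfun <- function(l) f_func(1i * l, sh) * partition_product(1i * l, sh) / Kinv
  y <- grid^sh$alpha
  inv <- invert_cf(chfun, y)
  ptilde <- inv$q / y
  dens <- sh$alpha * grid^(sh$alpha - 1) * ptilde
  new_density_on_grid(grid, dens, meta = list(
    formula = "lineage size density, deterministic partitioning",
    settings = list(lam_max = inv$lam_max, n_lam = inv$n_lam,
                    product_cut = 1e-12)))
}

# --- deterministic (N -> infinity) limit --------------------------------

limit_mixture_from_shape <- function(sh) {
  al <- sh$alpha; p <- sh$p
  r0 <- sh$N0 / sh$N; r1 <- sh$N1 / sh$N
  if (r0 + r1 > 1 + 1e-12) stop("r0 + r1 exceeds 1")
  S <- sh$M0 + sh$M1
  pa <- p^al
  v_d <- (S / (1 - pa))^(1 / al)
  v_b <- p * v_d
  v_m <- ((sh$M0 + sh$M1 * pa) / (1 - pa))^(1 / al)
  T0 <- if (sh$M0 > 0) (al * r0 / sh$M0) * log(v_m / v_b) else 0
  Ts <- (1 - r0 - r1) / v_m^al
  T1 <- if (sh$M1 > 0) (al * r1 / sh$M1) * log(v_d / v_m) else 0
  tot <- T0 + Ts + T1
  structure(list(v_b = v_b, v_m = v_m, v_d = v_d,
                 T0 = T0, Ts = Ts, T1 = T1,
                 w0 = T0 / tot, ws = Ts / tot, w1 = T1 / tot,
                 alpha = al, p = p, M0 = sh$M0, M1 = sh$M1),
            class = "limit_mixture")
}

#' Zero-noise (large-N) limit of the lineage cell-size distribution
#'
#' As the number of stages grows at fixed stage fractions `r0 = N0/N`,
#' `r1 = N1/N` and fixed `M0`, `M1`, the added size becomes deterministic
#' and the stationary lineage distribution collapses onto a mixture over
#' the three growth phases: a `1/x`-shaped continuous part on
#' `[v_b, v_m]` with weight `w0` (elongation), a point mass at the
#' septation size `v_m` with weight `ws`, and a `1/x` part on `[v_m, v_d]`
#' with weight `w1` (reshaping). The sizes satisfy
#' `v_m^alpha - v_b^alpha = M0`, `v_d^alpha - v_m^alpha = M1` and
#' `v_b = p * v_d`; the weights are the phase durations `T0`, `Ts`, `T1`
#' normalized to sum 1, and estimate the fractions of the cell cycle spent
#' in each phase.
#'
#' @param params A [growth_params()] object or shape list; only
#'   `r0, r1, M0, M1, p, alpha` enter.
#' @return A `limit_mixture` object with fields `v_b`, `v_m`, `v_d`, `T0`,
#'   `Ts`, `T1`, `w0`, `ws`, `w1`.
#' @examples
#' limit_distribution(reference_params("EMM_28C", "I"))$w0  # ~0.76
#' @export
limit_distribution <- function(params) {
  limit_mixture_from_shape(as_shape(params))
}

#' @export
print.limit_mixture <- function(x, ...) {
  cat("Zero-noise limit of the lineage size distribution\n")
  cat(sprintf("  sizes:   v_b = %.4g, v_m = %.4g, v_d = %.4g\n",
              x$v_b, x$v_m, x$v_d))
  cat(sprintf("  weights: w0 = %.4g (elongation), ws = %.4g (septation atom), w1 = %.4g (reshaping)\n",
              x$w0, x$ws, x$w1))
  invisible(x)
}

#' Continuous part of the limit density
#'
#' Evaluates the two `1/x` branches of the zero-noise limit mixture. The
#' point mass at `v_m` (weight `ws`) is *not* included; it is reported as a
#' (location, weight) pair by [limit_distribution()] and must be handled
#' separately (e.g. smoothed with the comparison histogram's bin width).
#'
#' @param mix A `limit_mixture` object.
#' @param x Sizes at which to evaluate.
#' @return Density values of the continuous part.
#' @export
limit_density <- function(mix, x) {
  stopifnot(inherits(mix, "limit_mixture"))
  out <- numeric(length(x))
  in0 <- x >= mix$v_b & x <= mix$v_m
  in1 <- x >= mix$v_m & x <= mix$v_d
  out[in0] <- mix$w0 / ((log(mix$v_m) - log(mix$v_b)) * x[in0])
  out[in1] <- out[in1] + mix$w1 / ((log(mix$v_d) - log(mix$v_m)) * x[in1])
  out
}

# --- birth size ----------------------------------------------------------

#' Laplace transform of the generalized birth size
#'
#' `<exp(-lambda * V_b^alpha)> = prod_{n>=1} b(p^(alpha*n) * lambda)`
#' under deterministic partitioning, truncated like the lineage product.
#'
#' @param lam Non-negative or complex transform values.
#' @param params A [growth_params()] object or shape list.
#' @return Transform values, vectorized over `lam`.
#' @export
birth_laplace <- function(lam, params) {
  sh <- as_shape(params)
  partition_product(lam, sh, k0 = 1)
}

#' Birth-size density by transform inversion, and its closed-form
#' approximation
#'
#' `birth_density()` inverts the exact product transform of
#' `V_b^alpha` numerically (same machinery as [cellsize_density_det()]).
#' `birth_density_approx()` evaluates the closed form obtained by keeping
#' only the `n = 1` factor of the product — valid for strong size control
#' (large `alpha`) or small `p` — which is a generalized-gamma kernel
#' times a confluent hypergeometric factor:
#' `p(x) = alpha * beta0^N0 * beta1^N1 / Gamma(N0+N1) *
#' x^(alpha*(N0+N1)-1) * exp(-beta0*x^alpha) *
#' 1F1(N1, N0+N1, (beta0-beta1)*x^alpha)` with
#' `beta0 = N0/(M0*p^alpha)` and `beta1 = N1/(M1*p^alpha)`. With
#' `N1 = 0` the hypergeometric factor is 1 and the density collapses to a
#' gamma density in `x^alpha`.
#'
#' @param params A [growth_params()] object or shape list.
#' @param grid Optional increasing size grid.
#' @param n_grid Number of default grid points.
#' @param x Sizes at which to evaluate the approximation.
#' @return `birth_density()` returns a `density_on_grid`;
#'   `birth_density_approx()` returns density values.
#' @export
birth_density <- function(params, grid = NULL, n_grid = 400) {
  sh <- as_shape(params)
  al <- sh$alpha
  if (is.null(grid)) {
    mom <- birth_moments_shape(sh, model = "I")
    y_lo <- max(mom$mean - 6 * sqrt(mom$var), 1e-3 * mom$mean)
    y_hi <- mom$mean + 7 * sqrt(mom$var)
    grid <- seq(y_lo^(1 / al), y_hi^(1 / al), length.out = n_grid)
  }
  chfun <- function(l) partition_product(1i * l, sh, k0 = 1)
  y <- grid^al
  inv <- invert_cf(chfun, y)
  dens <- al * grid^(al - 1) * inv$q
  new_density_on_grid(grid, dens, meta = list(
    formula = "birth size density, deterministic partitioning",
    settings = list(lam_max = inv$lam_max, n_lam = inv$n_lam,
                    product_cut = 1e-12)))
}

#' @rdname birth_density
#' @export
birth_density_approx <- function(x, params) {
  sh <- as_shape(params)
  al <- sh$alpha; pa <- sh$p^al
  if (sh$N0 <= 0) stop("approximation requires N0 > 0")
  b0 <- sh$N0 / (sh$M0 * pa)
  if (sh$N1 > 0) {
    b1 <- sh$N1 / (sh$M1 * pa)
    y <- x^al
    lg <- log(al) + sh$N0 * log(b0) + sh$N1 * log(b1) - lgamma(sh$N0 + sh$N1) +
      (al * (sh$N0 + sh$N1) - 1) * log(x) - b0 * y +
      kummer_log(sh$N1, sh$N0 + sh$N1, (b0 - b1) * y)
    exp(lg)
  } else {
    y <- x^al
    exp(log(al) + sh$N0 * log(b0) - lgamma(sh$N0) +
          (al * sh$N0 - 1) * log(x) - b0 * y)
  }
}

# log of Kummer's confluent hypergeometric function 1F1(a, b, z) for
# a >= 0, b > 0, real z; series evaluation, Kummer transform for z < 0
kummer_log <- function(a, b, z) {
  vapply(z, function(z1) {
    aa <- a; bb <- b; shift <- 0
    if (z1 < 0) { # 1F1(a,b,z) = e^z 1F1(b-a, b, -z)
      shift <- z1; aa <- b - a; z1 <- -z1
    }
    if (aa == 0) return(shift)
    term <- 1; s <- 1; m <- 0
    repeat {
      term <- term * (aa + m) * z1 / ((bb + m) * (m + 1))
      s <- s + term
      m <- m + 1
      if (abs(term) < 1e-16 * abs(s) || m > 1e5) break
    }
    shift + log(s)
  }, numeric(1))
}

# --- moments and correlations -------------------------------------------

birth_moments_shape <- function(sh, model) {
  S <- sh$M0 + sh$M1
  B <- sh$M0^2 / sh$N0 + if (sh$N1 > 0) sh$M1^2 / sh$N1 else 0
  al <- sh$alpha
  if (model == "I") {
    pa <- sh$p^al
    list(mean = pa / (1 - pa) * S, var = pa^2 / (1 - pa^2) * B)
  } else {
    if (is.na(sh$nu)) stop("model II moments require a finite nu")
    Ks <- partition_K(sh$p, sh$nu, al)
    list(mean = Ks$K1 * S,
         var = ((2 * Ks$K1 + 1) * Ks$K2 - Ks$K1^2) * S^2 + Ks$K2 * B)
  }
}

#' Mean and variance of the generalized birth size
#'
#' Closed-form stationary moments of `V_b^alpha`. Under deterministic
#' partitioning (model I): mean `p^alpha/(1-p^alpha) * (M0+M1)`, variance
#' `p^(2*alpha)/(1-p^(2*alpha)) * (M0^2/N0 + M1^2/N1)`. Under beta
#' partitioning (model II) the same expressions with the partition-moment
#' ratios `K1`, `K2` of [corr_stoch()] replacing the powers of `p`.
#'
#' @param params A [growth_params()] object or shape list.
#' @param model `"I"` or `"II"`; defaults to the partitioning encoded in
#'   `params`.
#' @return List with `mean` and `var` of `V_b^alpha`.
#' @export
birth_moments <- function(params, model = NULL) {
  sh <- as_shape(params)
  if (is.null(model)) model <- if (is.na(sh$nu)) "I" else "II"
  birth_moments_shape(sh, model)
}

#' Birth/division correlation of generalized sizes, deterministic
#' partitioning
#'
#' Under deterministic partitioning the Pearson correlation between
#' `V_b^alpha` and `V_d^alpha` is exactly `p^alpha`, independently of the
#' growth pattern (it does not involve `g0`, `g1`, `N`, `M0` or `M1`).
#'
#' @param p Mean partition ratio in (0, 1).
#' @param alpha Size-control strength.
#' @return `p^alpha`.
#' @export
corr_det <- function(p, alpha) {
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  if (alpha <= 0) stop("'alpha' must be positive")
  p^alpha
}

partition_K <- function(p, nu, alpha) {
  lb0 <- lbeta(p * nu, (1 - p) * nu)
  t1 <- exp(lbeta(alpha + p * nu, (1 - p) * nu) - lb0)      # E[R^alpha]
  t2 <- exp(lbeta(2 * alpha + p * nu, (1 - p) * nu) - lb0)  # E[R^(2 alpha)]
  list(K1 = t1 / (1 - t1), K2 = t2 / (1 - t2))
}

#' Birth/division correlation of generalized sizes, beta partitioning
#'
#' With a beta-distributed partition ratio the correlation between
#' `V_b^alpha` and `V_d^alpha` is reduced below `p^alpha` and also depends
#' on the growth pattern:
#' `rho^2 = (((2*K1+1)*K2 - K1^2)*(M0+M1)^2 + K2*B) /
#'         (((2*K1+1)*K2 - K1^2)*(M0+M1)^2 + (K2+1)*B)`
#' where `B = M0^2/N0 + M1^2/N1`,
#' `K1 = E[R^alpha]/(1 - E[R^alpha])` and
#' `K2 = E[R^(2*alpha)]/(1 - E[R^(2*alpha)])`, the expectations being
#' beta moments `E[R^c] = B(c + p*nu, q*nu)/B(p*nu, q*nu)`.
#'
#' @param params A [growth_params()] object (model II) or shape list with
#'   finite `nu`.
#' @return List with `rho`, `K1`, `K2`.
#' @export
corr_stoch <- function(params) {
  sh <- as_shape(params)
  if (is.na(sh$nu)) stop("corr_stoch requires beta partitioning (finite nu)")
  Ks <- partition_K(sh$p, sh$nu, sh$alpha)
  S <- sh$M0 + sh$M1
  B <- sh$M0^2 / sh$N0 + if (sh$N1 > 0) sh$M1^2 / sh$N1 else 0
  A <- ((2 * Ks$K1 + 1) * Ks$K2 - Ks$K1^2) * S^2
  # A + K2*B is Var(V_b^alpha) and the added size is independent of the
  # birth size, so cov = Var(V_b^alpha) and rho is the sqrt of the
  # variance ratio
  list(rho = sqrt((A + Ks$K2 * B) / (A + (Ks$K2 + 1) * B)),
       K1 = Ks$K1, K2 = Ks$K2)
}

# --- convenience --------------------------------------------------------

#' Construct parameters for a prescribed stationary regime
#'
#' Builds a [growth_params()] object from the "shape" knobs commonly used
#' to explore the stationary distribution — total stages `N`, stage
#' fractions `r0`, `r1`, growth-rate ratio `g1/g0`, control strength,
#' partitioning — calibrating the transition constant `a` so that the mean
#' stationary lineage size equals `mean_size`. The calibration is exact:
#' at fixed stage structure the whole size distribution scales as
#' `(M0+M1)^(1/alpha)`, so a single density evaluation determines `a`.
#'
#' @param N Total effective stages.
#' @param r0,r1 Fractions of stages in elongation and reshaping.
#' @param g_ratio Ratio `g1/g0` (> 1).
#' @param alpha Size-control strength.
#' @param p Mean partition ratio.
#' @param nu Beta sample-size parameter or `NA` for deterministic
#'   partitioning. The calibration always uses the deterministic-partition
#'   mean, so that paired model I/II regimes share the same `a`.
#' @param mean_size Target mean lineage size (default 3).
#' @param g0 Elongation growth rate (default 0.01/h); only sets the time
#'   scale.
#' @return A [growth_params()] object.
#' @examples
#' gp <- regime_params(N = 30)
#' @export
regime_params <- function(N, r0 = 0.6, r1 = 0.1, g_ratio = 2, alpha = 2,
                          p = 0.5, nu = NA_real_, mean_size = 3, g0 = 0.01) {
  stopifnot(r0 > 0, r1 >= 0, r0 + r1 <= 1, g_ratio > 1, N >= 1)
  N0 <- r0 * N; N1 <- r1 * N
  # unit total added size, split per phase as M1/M0 = (N1 g1)/(N0 g0)
  w <- c(N0, N1 * g_ratio)
  sh <- list(N = N, N0 = N0, N1 = N1, M0 = w[1] / sum(w), M1 = w[2] / sum(w),
             p = p, alpha = alpha, nu = NA_real_)
  d <- cellsize_density_det(sh)
  m1 <- pracma::trapz(d$x, d$x * d$density) / d$integral
  S_target <- (mean_size / m1)^alpha  # sizes scale as (M0+M1)^(1/alpha)
  a <- alpha * g0 * (N0 + N1 * g_ratio) / S_target
  growth_params(g0 = g0, g1 = g_ratio * g0, a = a, alpha = alpha,
                N = N, N0 = N0, N1 = N1, p = p, nu = nu)
}

#' Count the modes of a tabulated density
#'
#' Local maxima whose height exceeds `prominence` times the global
#' maximum, after merging plateaus; used to classify unimodal vs bimodal
#' stationary size distributions.
#'
#' @param d A `density_on_grid` object or numeric vector of densities.
#' @param prominence Minimum relative peak height and minimum relative
#'   dip separating two peaks (default 0.05).
#' @return Integer number of modes.
#' @export
count_modes <- function(d, prominence = 0.05) {
  dens <- if (inherits(d, "density_on_grid")) d$density else d
  n <- length(dens)
  peak_idx <- which(diff(sign(diff(dens))) < 0) + 1
  peak_idx <- peak_idx[dens[peak_idx] > prominence * max(dens)]
  if (length(peak_idx) <= 1) return(length(peak_idx))
  # require a real dip between consecutive surviving peaks
  keep <- peak_idx[1]
  for (i in peak_idx[-1]) {
    prev <- keep[length(keep)]
    valley <- min(dens[prev:i])
    if (valley < (1 - prominence) * min(dens[prev], dens[i])) keep <- c(keep, i)
    else if (dens[i] > dens[prev]) keep[length(keep)] <- i
  }
  length(keep)
}

#' Total-variation distance between a tabulated density and a sample
#'
#' Bins the sample into `n_bins` equal-width bins, integrates the
#' tabulated density over the same bins (trapezoid on its grid), and
#' returns half the L1 distance between the two discrete probability
#' vectors. An optional point mass (e.g. the septation atom of the limit
#' mixture) is added to the bin containing its location.
#'
#' @param d A `density_on_grid` object.
#' @param sizes Numeric sample.
#' @param n_bins Number of histogram bins (default 60).
#' @param atom Optional `c(location, weight)` point mass carried by the
#'   density.
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(d, sizes, n_bins = 60, atom = NULL) {
  stopifnot(inherits(d, "density_on_grid"))
  lo <- min(min(sizes), min(d$x)); hi <- max(max(sizes), max(d$x))
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  emp <- tabulate(findInterval(sizes, breaks, rightmost.closed = TRUE),
                  nbins = n_bins) / length(sizes)
  xg <- d$x; cg <- c(0, cumsum(diff(xg) * (head(d$density, -1) + tail(d$density, -1)) / 2))
  cdf <- approx(xg, cg, xout = breaks, yleft = 0, yright = cg[length(cg)])$y
  th <- diff(cdf)
  if (!is.null(atom)) {
    ib <- findInterval(atom[1], breaks, rightmost.closed = TRUE)
    if (ib >= 1 && ib <= n_bins) th[ib] <- th[ib] + atom[2]
  }
  th <- pmax(th, 0); th <- th / sum(th)
  0.5 * sum(abs(emp - th))
}
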