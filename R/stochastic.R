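# Cell-size distribution under beta-distributed (stochastic) partitioning.
#
# The division-size transform S(u) = <exp(-u * V_d^alpha)> satisfies
# S(u) = b(u) * E_R[S(R^alpha * u)] and has the power-series solution
# S(u) = sum_n a_n u^n with a_0 = 1,
#   a_n = (1/(1-c_n)) * sum_{m<n} a_m c_m b_{n-m},
#   c_n = B(alpha*n + p*nu, q*nu)/B(p*nu, q*nu)  (the beta moment E[R^(alpha n)]),
#   b_n = (-1)^n sum_m (N0)_m (N1)_(n-m) A0^m A1^(n-m) / (m! (n-m)!)
# (the Taylor coefficients of the added-size transform b). Because S is a
# Laplace transform of a non-negative variable, a_n and b_n alternate in
# sign exactly, so all recursions are computed on log-magnitudes with no
# cancellation. The series converges only inside |u| < 1/max(A0, A1)
# (radius set by the nearest pole of b); outside, S is continued
# analytically along a ray via the functional equation, using Gauss
# quadrature for the beta expectation and an ascending modulus ladder.

lpoch <- function(x, m) if (m == 0) 0 else lgamma(x + m) - lgamma(x)

log_abs_b_coeffs <- function(sh, n_max) {
  A0 <- sh$M0 / sh$N0
  A1 <- if (sh$N1 > 0) sh$M1 / sh$N1 else 0
  lb <- numeric(n_max + 1)  # log|b_n|; sign is (-1)^n
  for (n in 0:n_max) {
    if (sh$N1 > 0) {
      m <- 0:n
      lt <- lpoch_vec(sh$N0, m) + lpoch_vec(sh$N1, n - m) +
        m * log(A0) + (n - m) * log(A1) - lgamma(m + 1) - lgamma(n - m + 1)
      lb[n + 1] <- logsumexp(lt)
    } else {
      lb[n + 1] <- lpoch(sh$N0, n) + n * log(A0) - lgamma(n + 1)
    }
  }
  lb
}

lpoch_vec <- function(x, m) {
  out <- numeric(length(m))
  pos <- m > 0
  if (x <= 0) { out[pos] <- -Inf; return(out) }
  out[pos] <- lgamma(x + m[pos]) - lgamma(x)
  out
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Series coefficients of the stochastic-partitioning size transform
#'
#' Computes the coefficient sequences of the power-series solution
#' `S(u) = sum_n a_n u^n` for the transform of the generalized division
#' size under beta partitioning: `c_n` are the beta moments
#' `E[R^(alpha*n)]`, `b_n` the Taylor coefficients of the added-size
#' transform (alternating Pochhammer sums over the per-stage scales `A0`,
#' `A1`), and `a_n` follows the recursion
#' `a_n = (1/(1-c_n)) * sum_{m=0}^{n-1} a_m c_m b_{n-m}` with `a_0 = 1`.
#'
#' @param params A [growth_params()] object with finite `nu`, or shape
#'   list.
#' @param n_max Highest order computed (default 120).
#' @return A data.frame with columns `n`, `a`, `b`, `c` and attribute
#'   `radius` (the convergence radius `1/max(A0, A1)` of the series).
#' @export
series_coefficients <- function(params, n_max = 120) {
  sh <- as_shape(params)
  if (is.na(sh$nu)) stop("series coefficients require beta partitioning (finite nu)")
  if (sh$N0 <= 0) stop("series solution requires N0 > 0")
  co <- series_log_coeffs(sh, n_max)
  data.frame(n = 0:n_max,
             a = co$sign_a * exp(co$la),
             b = (-1)^(0:n_max) * exp(co$lb),
             c = co$c_n) |>
    structure(radius = co$radius)
}

series_log_coeffs <- function(sh, n_max) {
  lb <- log_abs_b_coeffs(sh, n_max)
  n_seq <- 0:n_max
  c_n <- exp(lbeta(sh$alpha * n_seq + sh$p * sh$nu, (1 - sh$p) * sh$nu) -
               lbeta(sh$p * sh$nu, (1 - sh$p) * sh$nu))
  la <- numeric(n_max + 1)  # log|a_n|; sign is (-1)^n
  la[1] <- 0
  lc <- log(c_n)
  for (n in seq_len(n_max)) {
    m <- 0:(n - 1)
    la[n + 1] <- logsumexp(la[m + 1] + lc[m + 1] + lb[n - m + 1]) -
      log1p(-c_n[n + 1])
  }
  A <- max(sh$M0 / sh$N0, if (sh$N1 > 0) sh$M1 / sh$N1 else 0)
  list(la = la, lb = lb, c_n = c_n, sign_a = (-1)^n_seq, radius = 1 / A)
}

# Evaluate the series at complex u inside the convergence disc, with
# adaptive truncation; signals divergence if not converged by n_max.
series_eval <- function(u, co, n_max) {
  n_seq <- 0:n_max
  vapply(u, function(u1) {
    if (u1 == 0) return(1 + 0i)
    lt <- co$la + n_seq * log(u1 + 0i)  # complex log
    terms <- co$sign_a * exp(lt)
    s <- 0i; last_big <- 0L
    for (n in n_seq) {
      s <- s + terms[n + 1]
      if (Mod(terms[n + 1]) > 1e-12 * Mod(s)) last_big <- n
    }
    if (last_big >= n_max)
      stop("power series for the partition transform did not converge by n_max; |u| too close to the convergence radius")
    s
  }, complex(1))
}

# Gauss-Legendre nodes/weights for E_R[.] under Beta(p nu, q nu)
beta_expectation_rule <- function(p, nu, n_nodes = 48) {
  lo <- qbeta(1e-13, p * nu, (1 - p) * nu)
  hi <- qbeta(1 - 1e-13, p * nu, (1 - p) * nu)
  gl <- pracma::gaussLegendre(n_nodes, lo, hi)
  w <- gl$w * dbeta(gl$x, p * nu, (1 - p) * nu)
  list(r = gl$x, w = w / sum(w))
}

# Evaluator of S along the ray u = m * dir (dir on the unit circle),
# valid for moduli up to m_max. Uses the series inside 0.6 * radius and
# the functional equation S(u) = b(u) E_R[S(R^alpha u)] on an ascending
# log-spaced modulus ladder outside, interpolating previously computed
# rungs.
make_S_evaluator <- function(sh, dir, m_max, n_max = 400, n_nodes = 48) {
  co <- series_log_coeffs(sh, n_max)
  m0 <- 0.6 * co$radius
  ser <- function(m) series_eval(m * dir, co, n_max)
  if (m_max <= m0) return(function(m) ser(m))
  rule <- beta_expectation_rule(sh$p, sh$nu, n_nodes)
  ral <- rule$r^sh$alpha
  npts <- max(200L, ceiling(log(m_max / m0) * 300))
  ms <- exp(seq(log(m0), log(m_max), length.out = npts))
  vals <- complex(npts)
  lms <- log(ms)
  lookup <- function(m, j) {
    # values of S at moduli m, all < ms[j]
    out <- complex(length(m))
    sm <- m <= m0
    if (any(sm)) out[sm] <- ser(m[sm])
    if (any(!sm)) {
      if (j <= 2) {
        out[!sm] <- vals[1]
      } else {
        lq <- log(m[!sm])
        re <- approx(lms[1:(j - 1)], Re(vals[1:(j - 1)]), xout = lq, rule = 2)$y
        im <- approx(lms[1:(j - 1)], Im(vals[1:(j - 1)]), xout = lq, rule = 2)$y
        out[!sm] <- complex(real = re, imaginary = im)
      }
    }
    out
  }
  vals[1] <- ser(m0)
  for (j in 2:npts) {
    inner <- lookup(ral * ms[j], j)
    vals[j] <- laplace_b(ms[j] * dir, sh) * sum(rule$w * inner)
  }
  function(m) {
    out <- complex(length(m))
    sm <- m <= m0
    if (any(sm)) out[sm] <- ser(m[sm])
    if (any(!sm)) {
      lq <- pmin(log(m[!sm]), lms[npts])
      re <- approx(lms, Re(vals), xout = lq, rule = 2)$y
      im <- approx(lms, Im(vals), xout = lq, rule = 2)$y
      out[!sm] <- complex(real = re, imaginary = im)
    }
    out
  }
}

# modulus beyond which |f(u) * tail(u)| is negligible along an axis,
# estimated from the deterministic product (same mean partitioning)
decay_bound <- function(sh, axis = c("real", "imag")) {
  axis <- match.arg(axis)
  dir <- if (axis == "real") 1 + 0i else 1i
  scale0 <- (1 - sh$p^sh$alpha) / (sh$M0 + sh$M1)  # ~ 1/E[V^alpha]
  m <- scale0
  val0 <- Mod(f_func(m * dir, sh) * partition_product(m * dir, sh))
  repeat {
    m <- m * 1.6
    v <- Mod(f_func(m * dir, sh) * partition_product(m * dir, sh))
    if (v < 1e-14 * max(val0, 1) || m > scale0 * 1e9) break
  }
  m * 2
}

#' Lineage cell-size transform and density under beta partitioning
#'
#' `cellsize_laplace_stoch()` evaluates
#' `F(lambda) = K * integral_lambda^Inf f(u) * S(u) du` where
#' `S(u) = sum_n a_n u^n` is the series solution of
#' [series_coefficients()]; `cellsize_density_stoch()` inverts the
#' corresponding Fourier form exactly as [cellsize_density_det()] does for
#' deterministic partitioning. Outside its convergence radius the series
#' is continued analytically through the functional equation
#' `S(u) = b(u) * E_R[S(R^alpha u)]`.
#'
#' @param lam Non-negative transform values.
#' @param params A [growth_params()] object with finite `nu`.
#' @param grid,n_grid As in [cellsize_density_det()].
#' @return `cellsize_laplace_stoch()`: numeric vector;
#'   `cellsize_density_stoch()`: a `density_on_grid` object.
#' @export
cellsize_laplace_stoch <- function(lam, params) {
  if (any(lam < 0)) stop("'lam' must be non-negative")
  sh <- as_shape(params)
  if (is.na(sh$nu)) stop("stochastic-partitioning transform requires finite nu")
  m_max <- decay_bound(sh, "real")
  S_real <- make_S_evaluator(sh, 1 + 0i, m_max)
  tail_fun <- function(u) {
    out <- complex(length(u))
    ok <- u <= m_max
    out[ok] <- S_real(u[ok])
    out
  }
  Kinv <- normalization_integral(sh, tail_fun = tail_fun)
  integrand <- function(u) Re(f_func(u, sh) * tail_fun(u))
  vapply(lam, function(l) {
    if (l == 0) return(1)
    val <- tryCatch(
      integrate(integrand, l, m_max, rel.tol = 1e-8,
                subdivisions = 1000L)$value,
      error = function(e) {
        u <- exp(seq(log(l), log(m_max), length.out = 6000L))
        pracma::trapz(u, integrand(u))
      })
    val / Kinv
  }, numeric(1))
}

#' @rdname cellsize_laplace_stoch
#' @export
cellsize_density_stoch <- function(params, grid = NULL, n_grid = 400) {
  sh <- as_shape(params)
  if (is.na(sh$nu)) stop("stochastic-partitioning density requires finite nu")
  if (is.null(grid)) grid <- default_size_grid(sh, n_grid)
  m_max_re <- decay_bound(sh, "real")
  S_real <- make_S_evaluator(sh, 1 + 0i, m_max_re)
  Kinv <- normalization_integral(sh, tail_fun = function(u) {
    out <- complex(length(u)); ok <- u <= m_max_re
    out[ok] <- S_real(u[ok]); out
  })
  m_max_im <- decay_bound(sh, "imag")
  S_imag <- make_S_evaluator(sh, 1i, m_max_im)
  chfun <- function(l) {
    out <- complex(length(l))
    pos <- l > 0 & l <= m_max_im
    out[l == 0] <- 1 / Kinv
    out[pos] <- f_func(1i * l[pos], sh) * S_imag(l[pos]) / Kinv
    out
  }
  y <- grid^sh$alpha
  inv <- invert_cf(chfun, y)
  ptilde <- inv$q / y
  dens <- sh$alpha * grid^(sh$alpha - 1) * ptilde
  new_density_on_grid(grid, dens, meta = list(
    formula = "lineage size density, beta partitioning (series solution)",
    settings = list(lam_max = inv$lam_max, n_lam = inv$n_lam,
                    series_radius = 1 / max(sh$M0 / sh$N0,
                                            if (sh$N1 > 0) sh$M1 / sh$N1 else 0))))
}
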