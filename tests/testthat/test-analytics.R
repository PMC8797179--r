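test_that("added-size transform has the hypoexponential form", {
  dq <- derived_quantities(emm_params())
  expect_equal(laplace_b(0, dq), 1)
  sh <- list(N = 2, N0 = 1, N1 = 1, M0 = 1, M1 = 1, p = 0.5, alpha = 1)
  expect_equal(laplace_b(1, sh), 0.25)
  # N -> infinity at fixed M0 + M1: transform tends to exp(-(M0+M1) lam)
  shL <- list(N = 2e4, N0 = 1e4, N1 = 1e4, M0 = 1, M1 = 1, p = 0.5, alpha = 1)
  expect_equal(laplace_b(1, shL), exp(-2), tolerance = 1e-4)
  expect_error(laplace_b(-1, dq), "non-negative")
})

test_that("the weight function f is normalized and reduces correctly", {
  sh <- pombesize:::as_shape(emm_params())
  expect_equal(f_func(0, sh), 1)
  expect_equal(f_func(1e-12, sh), 1, tolerance = 1e-9)
  # growth without bound for large lam
  expect_gt(f_func(1e3, sh), 1e6)
  # single-phase reduction: ((1+A0 lam)^N - 1)/(N A0 lam)
  sh1 <- list(N = 12, N0 = 12, N1 = 0, M0 = 3, M1 = 0, p = 0.5, alpha = 1)
  A0 <- 3 / 12
  lam <- c(0.3, 1, 4)
  expect_equal(f_func(lam, sh1),
               ((1 + A0 * lam)^12 - 1) / (12 * A0 * lam), tolerance = 1e-12)
})

test_that("the lineage transform is a proper Laplace transform", {
  gp <- emm_params()
  expect_equal(cellsize_laplace_det(0, gp), 1)
  lam <- c(0.002, 0.01)
  Fv <- cellsize_laplace_det(lam, gp)
  expect_true(all(diff(c(1, Fv)) < 0))  # decreasing from 1
  # Monte-Carlo oracle: time-weighted lineage snapshots
  sizes <- stationary_sizes(gp, 1e4, seed = 21)
  y <- sizes^gp$alpha
  for (i in seq_along(lam)) {
    mc <- mean(exp(-lam[i] * y))
    # snapshots are autocorrelated: inflate the SE by an effective factor
    se <- sd(exp(-lam[i] * y)) / sqrt(length(y) / 80)
    expect_lt(abs(Fv[i] - mc), 3 * se)
  }
})

test_that("deterministic-partition density is accurate and normalized", {
  gp <- regime_params(N = 30)
  d <- cellsize_density_det(gp)
  expect_true(all(d$density >= 0))
  expect_equal(d$integral, 1, tolerance = 1e-3)
  sizes <- stationary_sizes(gp, 2e4, seed = 22)
  expect_lt(tv_distance(d, sizes), 0.02)
})

test_that("zero-noise limit mixture satisfies its algebraic identities", {
  for (gp in list(emm_params(), regime_params(N = 30), int_params())) {
    dq <- derived_quantities(gp)
    mx <- limit_distribution(gp)
    al <- gp$alpha
    expect_equal(mx$v_m^al - mx$v_b^al, dq$M0, tolerance = 1e-10)
    expect_equal(mx$v_d^al - mx$v_m^al, dq$M1, tolerance = 1e-10)
    expect_equal(mx$v_b, gp$p * mx$v_d, tolerance = 1e-12)
    expect_equal(mx$w0 + mx$ws + mx$w1, 1, tolerance = 1e-12)
    expect_true(mx$v_b < mx$v_m && mx$v_m < mx$v_d)
  }
  mx <- limit_distribution(int_params(p = 0.5))
  expect_equal(mx$v_b, mx$v_d / 2, tolerance = 1e-12)
})

test_that("finite-N density converges to the limit mixture as N grows", {
  tv_to_limit <- function(N) {
    gp <- regime_params(N = N)
    d <- cellsize_density_det(gp)
    mx <- limit_distribution(gp)
    # bin both on a common grid; put the atom in its bin
    breaks <- seq(min(d$x), max(d$x), length.out = 61)
    cg <- c(0, cumsum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2))
    pd <- diff(approx(d$x, cg, xout = breaks, yleft = 0, yright = max(cg))$y)
    clip <- function(v) pmin(pmax(v, breaks[1]), breaks[61])
    seg <- function(a, b, la, lb, w) {
      a2 <- clip(pmax(breaks[-61], a)); b2 <- clip(pmin(breaks[-1], b))
      w * pmax(log(pmax(b2, a2)) - log(a2), 0) / (lb - la)
    }
    pm <- seg(mx$v_b, mx$v_m, log(mx$v_b), log(mx$v_m), mx$w0) +
      seg(mx$v_m, mx$v_d, log(mx$v_m), log(mx$v_d), mx$w1)
    ib <- findInterval(mx$v_m, breaks)
    pm[ib] <- pm[ib] + mx$ws
    0.5 * sum(abs(pd / sum(pd) - pm / sum(pm)))
  }
  tvs <- vapply(c(10, 30, 100), tv_to_limit, numeric(1))
  expect_true(all(diff(tvs) < 0))
})

test_that("birth-size transform, density and moments are consistent", {
  gp <- emm_params()
  expect_equal(Re(birth_laplace(0, gp)), 1)
  bm <- birth_moments(gp, "I")
  dq <- derived_quantities(gp)
  pa <- gp$p^gp$alpha
  expect_equal(bm$mean, pa / (1 - pa) * (dq$M0 + dq$M1), tolerance = 1e-12)
  # numerical derivative of the transform gives the mean
  eps <- 1e-7
  expect_equal(-log(Re(birth_laplace(eps, gp))) / eps, bm$mean,
               tolerance = 1e-4)
  d <- birth_density(gp)
  expect_equal(d$integral, 1, tolerance = 1e-3)
  # simulated births match transform and moments
  gens <- simulate_lineage(gp, 2e4, seed = 23)
  y <- gens$V_b^gp$alpha
  lam <- 1 / mean(y)
  se <- sd(exp(-lam * y)) / sqrt(length(y) / 10)
  expect_lt(abs(Re(birth_laplace(lam, gp)) - mean(exp(-lam * y))), 3 * se)
  expect_lt(abs(mean(y) - bm$mean), 3 * sd(y) / sqrt(length(y) / 10))
})

test_that("closed-form birth approximation behaves as documented", {
  gp <- emm_params()
  # N1 -> 0: generalized gamma (gamma in x^alpha)
  sh <- pombesize:::as_shape(gp)
  sh$N1 <- 0; sh$M1 <- 0; sh$N <- sh$N0
  x <- seq(3, 12, length.out = 50)
  b0 <- sh$N0 / (sh$M0 * sh$p^sh$alpha)
  manual <- sh$alpha * x^(sh$alpha - 1) * dgamma(x^sh$alpha, shape = sh$N0, rate = b0)
  expect_equal(birth_density_approx(x, sh), manual, tolerance = 1e-10)
  # integrates to ~1 (it is a proper density by construction)
  xx <- seq(0.5, 25, length.out = 3000)
  expect_equal(pracma::trapz(xx, birth_density_approx(xx, gp)), 1,
               tolerance = 1e-3)
  # approximation error (vs full inversion) shrinks as alpha grows
  err <- vapply(c(1.767, 3, 5), function(al) {
    shx <- pombesize:::as_shape(gp); shx$alpha <- al
    d <- birth_density(shx)
    a <- birth_density_approx(d$x, shx)
    max(abs(a - d$density)) / max(d$density)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("birth/division correlations match theory", {
  expect_equal(corr_det(0.5, 1), 0.5)
  expect_equal(corr_det(0.459, 1.767), 0.459^1.767)
  expect_equal(corr_det(0.459, 1.767), 0.2526, tolerance = 1e-3)
  # beta partitioning: reduces to p^alpha as nu -> infinity ...
  gp <- int_params(nu = 1e8)
  cs <- corr_stoch(gp)
  expect_equal(cs$rho, 0.5^2, tolerance = 1e-5)
  expect_equal(cs$K1, 0.25 / (1 - 0.25), tolerance = 1e-4)
  # ... approaching it monotonically from above as the partition noise
  # shrinks (noisier partitioning inflates the birth-size variance, and
  # with it the birth/division correlation)
  for (al in c(0.8, 1.5, 2.5)) {
    rhos <- vapply(c(5, 50, 500, 1e6),
                   function(nu) corr_stoch(int_params(alpha = al, nu = nu))$rho,
                   numeric(1))
    expect_true(all(diff(rhos) < 0))
    expect_gt(rhos[4], corr_det(0.5, al) - 1e-4)
  }
  # matches simulation for a published model II condition
  gp2 <- reference_params("EMM_28C", "II")
  gens <- simulate_lineage(gp2, 1e5, seed = 24)
  al <- gp2$alpha
  rho_hat <- cor(gens$V_b^al, gens$V_d^al)
  se <- (1 - rho_hat^2) / sqrt(1e5)
  expect_lt(abs(corr_stoch(gp2)$rho - rho_hat), 3 * se + 0.005)
})

test_that("birth moments: model II collapses to model I and vars vanish", {
  gp <- int_params(nu = 1e9)
  m2 <- birth_moments(gp, "II")
  m1 <- birth_moments(gp, "I")
  expect_equal(m2$mean, m1$mean, tolerance = 1e-6)
  expect_equal(m2$var, m1$var, tolerance = 1e-4)
  # N0, N1 -> infinity at fixed M0, M1: the variance bracket vanishes
  dq <- derived_quantities(gp)
  shL <- list(N = 4e4, N0 = 3e4, N1 = 1e4, M0 = dq$M0, M1 = dq$M1,
              p = 0.5, alpha = 2, nu = NA_real_)
  expect_lt(birth_moments(shL, "I")$var, 1e-3 * birth_moments(gp, "I")$var)
})

test_that("densities export with metadata headers and round-trip", {
  d <- cellsize_density_det(regime_params(N = 10), n_grid = 80)
  tf <- withr::local_tempfile(fileext = ".csv")
  export_density(d, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^# formula=", lines)))
  tab <- utils::read.csv(tf, comment.char = "#")
  expect_equal(tab$size, d$x, tolerance = 1e-9)
  expect_equal(tab$density, d$density, tolerance = 1e-9)
})
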