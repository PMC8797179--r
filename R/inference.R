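# Five-step parameter estimation from lineage data:
#   1) partitioning (p, nu) from the partition-ratio series
#   2) size-control strength alpha from the birth/division correlation
#   3) added-size moments M0+M1 and M0^2/N0 + M1^2/N1 from birth sizes
#   4) growth rates from three-stage fits of per-generation time courses
#   5) stage numbers (N, N0, N1) by matching the theoretical stationary
#      size density to the observed size histogram

#' Estimate the partitioning parameters from partition ratios
#'
#' Model I: `p` is the mean ratio. Model II: maximum-likelihood beta fit
#' in the `(p, nu)` parameterization (`Beta(p*nu, (1-p)*nu)`), started
#' from the method-of-moments value `nu = p*(1-p)/var - 1`. A ratio series
#' with (numerically) zero variance returns `nu = Inf` with a warning.
#'
#' @param ratios Partition ratios, each strictly in (0, 1).
#' @param model `"I"` or `"II"`.
#' @return List with `p`, `nu` (`NA` for model I, possibly `Inf`), `n`.
#' @export
estimate_partition <- function(ratios, model = c("I", "II")) {
  model <- match.arg(model)
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no partition ratios supplied")
  if (any(ratios <= 0) || any(ratios >= 1))
    stop("partition ratios must lie strictly in (0, 1)")
  p <- mean(ratios)
  if (model == "I") return(list(p = p, nu = NA_real_, n = length(ratios)))
  v <- var(ratios)
  if (!is.finite(v) || v < 1e-12 * p^2) {
    warning("partition ratios have (numerically) zero variance; returning nu = Inf")
    return(list(p = p, nu = Inf, n = length(ratios)))
  }
  nu0 <- p * (1 - p) / v - 1
  nll <- function(th) {
    pp <- th[1]; nn <- exp(th[2])
    if (pp <= 0 || pp >= 1) return(1e10)
    -sum(dbeta(ratios, pp * nn, (1 - pp) * nn, log = TRUE))
  }
  opt <- optim(c(p, log(max(nu0, 1))), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 2000))
  list(p = opt$par[1], nu = exp(opt$par[2]), n = length(ratios))
}

#' Estimate the size-control strength from birth/division pairs
#'
#' Finds the `alpha` at which the sample correlation of
#' (`V_b^alpha`, `V_d^alpha`) equals its stationary model value:
#' `p^alpha` for deterministic partitioning, and for beta partitioning the
#' ratio `var(V_b^alpha) / (var(V_b^alpha) + B(alpha))`, where `B(alpha)`
#' is the added-size dispersion implied by the birth-size moments at that
#' `alpha` (see [estimate_added_moments()]). The root is bracketed on
#' `bracket` and located by bisection; if the objective does not change
#' sign, the nearest bracket edge is returned with a warning (typical for
#' near-pure sizer data, where the correlation is flat in `alpha`).
#'
#' @param V_b,V_d Matched birth and division sizes.
#' @param p Mean partition ratio (from step 1).
#' @param nu Beta sample-size parameter (model II only).
#' @param model `"I"` or `"II"`.
#' @param bracket Search interval for `alpha` (default `c(0.05, 10)`).
#' @return List with `alpha`, `at_boundary` flag, `objective` (function of
#'   alpha, for diagnostics).
#' @export
estimate_alpha <- function(V_b, V_d, p, nu = NA_real_,
                           model = c("I", "II"), bracket = c(0.05, 10)) {
  model <- match.arg(model)
  keep <- is.finite(V_b) & is.finite(V_d)
  V_b <- V_b[keep]; V_d <- V_d[keep]
  if (length(V_b) < 10) stop("need at least 10 birth/division pairs")
  h <- function(al) {
    yb <- V_b^al; yd <- V_d^al
    rho_hat <- cor(yb, yd)
    rho_th <- if (model == "I") p^al else {
      mom <- moments_to_added(mean(yb), var(yb), al, p, nu, "II")
      sqrt(var(yb) / (var(yb) + max(mom$B, 1e-12)))
    }
    rho_hat - rho_th
  }
  h_lo <- suppressWarnings(h(bracket[1])); h_hi <- suppressWarnings(h(bracket[2]))
  if (!is.finite(h_lo) || !is.finite(h_hi) || sign(h_lo) == sign(h_hi)) {
    edge <- if (is.finite(h_lo) && is.finite(h_hi) && abs(h_lo) < abs(h_hi))
      bracket[1] else bracket[2]
    warning(sprintf("no sign change on [%g, %g]; alpha reported at bracket edge %g",
                    bracket[1], bracket[2], edge))
    return(list(alpha = edge, at_boundary = TRUE, objective = h))
  }
  root <- uniroot(h, bracket, tol = 1e-5)
  list(alpha = root$root, at_boundary = FALSE, objective = h)
}

moments_to_added <- function(mean_yb, var_yb, alpha, p, nu, model) {
  if (model == "I") {
    pa <- p^alpha
    list(S = mean_yb * (1 - pa) / pa,
         B = var_yb * (1 - pa^2) / pa^2)
  } else {
    Ks <- partition_K(p, nu, alpha)
    S <- mean_yb / Ks$K1
    B <- (var_yb - ((2 * Ks$K1 + 1) * Ks$K2 - Ks$K1^2) * S^2) / Ks$K2
    list(S = S, B = B)
  }
}

#' Added-size moments from birth sizes
#'
#' Inverts the closed-form stationary birth-size moments to recover the
#' total mean generalized added size `S = M0 + M1` and the dispersion term
#' `B = M0^2/N0 + M1^2/N1` from the sample mean and variance of
#' `V_b^alpha`.
#'
#' @param V_b Birth sizes.
#' @param alpha Size-control strength.
#' @param p Mean partition ratio.
#' @param nu Beta sample-size parameter (model II).
#' @param model `"I"` or `"II"`.
#' @return List with `S` and `B`.
#' @export
estimate_added_moments <- function(V_b, alpha, p, nu = NA_real_,
                                   model = c("I", "II")) {
  model <- match.arg(model)
  yb <- V_b[is.finite(V_b)]^alpha
  moments_to_added(mean(yb), var(yb), alpha, p, nu, model)
}

#' Fit one generation's time course to the three-stage growth model
#'
#' Least squares of log size against the continuous piecewise model
#' exponential (rate `g0_k`) - constant (`V_s`) - exponential (rate
#' `g1_k`), `log V(t) = log V_b + g0_k * min(t, t0) + g1_k * max(t - t1, 0)`.
#' For fixed change points the model is linear in
#' `(log V_b, g0_k, g1_k)`, so the change points `(t0, t1)` are searched
#' exhaustively on the sampling grid (coarse-to-fine when the generation
#' is long) and the inner fit is an ordinary linear least squares.
#'
#' @param time Sample times (h), relative to any origin.
#' @param size Positive sizes at `time` (at least 6 samples).
#' @return List with `g0`, `g1`, `t0`, `t1` (absolute, same origin as
#'   `time`), `V_b`, `V_s`, `rss`.
#' @export
fit_three_stage <- function(time, size) {
  m <- length(time)
  if (m < 6) stop("generation too short: need at least 6 samples")
  if (any(size <= 0)) stop("sizes must be positive")
  t0_origin <- time[1]
  tt <- time - t0_origin
  L <- log(size)
  fit_at <- function(i, j) {
    X <- cbind(1, pmin(tt, tt[i]), pmax(tt - tt[j], 0))
    f <- .lm.fit(X, L)
    sum(f$residuals^2)
  }
  # scan change points with the latest t0 first so that ties (e.g. a
  # purely exponential generation fits exactly for many change points)
  # resolve to the longest elongation phase
  step <- max(1L, floor(m / 25))
  tol <- 1e-8 * sum((L - mean(L))^2)
  best <- c(Inf, m - 1L, m)
  for (i in seq(m - 1L, 2L, by = -step)) {
    for (j in seq(i, m, by = step)) {
      r <- fit_at(i, j)
      if (r < best[1] - tol) best <- c(r, i, j)
    }
  }
  if (step > 1L) {
    for (i in min(m - 1L, best[2] + step):max(2L, best[2] - step)) {
      for (j in max(i, best[3] - step):min(m, best[3] + step)) {
        r <- fit_at(i, j)
        if (r < best[1] - tol) best <- c(r, i, j)
      }
    }
  }
  i <- best[2]; j <- best[3]
  X <- cbind(1, pmin(tt, tt[i]), pmax(tt - tt[j], 0))
  f <- .lm.fit(X, L)
  cf <- f$coefficients
  list(g0 = cf[2], g1 = cf[3], t0 = tt[i] + t0_origin, t1 = tt[j] + t0_origin,
       V_b = exp(cf[1]), V_s = exp(cf[1] + cf[2] * tt[i]), rss = best[1])
}

#' Solve for the transition constant and reshaping rate
#'
#' Given the added-size moments `S = M0 + M1` and
#' `B = M0^2/N0 + M1^2/N1`, candidate stage counts `N0`, `N1`, the control
#' strength and the elongation rate `g0`, solves the two moment equations
#' `S = alpha*(N0*g0/a + N1*g1/a)` and
#' `B = alpha^2*(N0*(g0/a)^2 + N1*(g1/a)^2)` for the scaled rates
#' `g0/a` and `g1/a`, keeping the root with `g1 > g0`; `a = g0/(g0/a)` and
#' `g1` follow. With `N1 = 0` the single unknown is read off the first
#' equation. Returns `feasible = FALSE` (with NA rates) when no real root
#' with positive rates and `g1 > g0` exists, which prunes impossible
#' `(N0, N1)` candidates.
#'
#' @param S,B Added-size moments (see [estimate_added_moments()]).
#' @param N0,N1 Candidate stage counts.
#' @param alpha Size-control strength.
#' @param g0 Elongation growth rate (1/h), from the three-stage fits.
#' @return List with `a`, `g1`, `g0_scaled`, `g1_scaled`, `M0`, `M1`,
#'   `feasible`.
#' @export
estimate_rates <- function(S, B, N0, N1, alpha, g0) {
  bad <- list(a = NA_real_, g1 = NA_real_, g0_scaled = NA_real_,
              g1_scaled = NA_real_, M0 = NA_real_, M1 = NA_real_,
              feasible = FALSE)
  if (S <= 0 || B <= 0 || N0 <= 0 || N1 < 0) return(bad)
  s <- S / alpha; q <- B / alpha^2
  if (N1 == 0) {
    x <- s / N0
    if (abs(N0 * x^2 - q) > 0.5 * q)  # moments inconsistent with N1 = 0
      return(bad)
    a <- g0 / x
    return(list(a = a, g1 = NA_real_, g0_scaled = x, g1_scaled = NA_real_,
                M0 = alpha * N0 * x, M1 = 0, feasible = TRUE))
  }
  # (N1^2 + N0*N1) y^2 - 2 s N1 y + (s^2 - q N0) = 0
  A2 <- N1^2 + N0 * N1
  disc <- 4 * N0 * N1 * (q * (N0 + N1) - s^2)
  if (disc < 0) return(bad)
  y <- (2 * s * N1 + sqrt(disc)) / (2 * A2)   # larger root gives g1 > g0
  x <- (s - N1 * y) / N0
  if (!is.finite(x) || x <= 0 || y <= x) return(bad)
  a <- g0 / x
  list(a = a, g1 = a * y, g0_scaled = x, g1_scaled = y,
       M0 = alpha * N0 * x, M1 = alpha * N1 * y, feasible = TRUE)
}

#' Estimate stage numbers by matching the stationary size distribution
#'
#' Minimizes the squared distance between the theoretical stationary
#' lineage size density and the sample histogram density over a grid of
#' candidate stage triples `(N, N0, N1)`: `sum_i |p(x_i) - phat(x_i)|^2`
#' at the `M` histogram bin centers `x_i`. For every candidate the
#' dependent parameters are re-derived through [estimate_rates()], and
#' infeasible candidates are skipped. The search is coarse-to-fine:
#' lattice steps `steps` over `N in N_range`, `N0 in 1..N-1`,
#' `N1 in 0..N-N0`, then an exhaustive pass in the best lattice cell.
#' Ties break to the smallest `N`, then the smallest `N0`.
#'
#' @param sizes All lineage size samples (the stationary sample).
#' @param p,nu,alpha,S,B,g0 Parameters estimated in the earlier steps.
#' @param model `"I"` (density via [cellsize_density_det()]) or `"II"`
#'   ([cellsize_density_stoch()]).
#' @param M Number of histogram bins (default 100).
#' @param N_range Range of total stage numbers searched (default 2-150).
#' @param steps Coarse lattice steps for `(N, N0, N1)`.
#' @param polish If `TRUE` (default), after the integer search a local
#'   continuous (Nelder-Mead) refinement of the triple is run within the
#'   winning lattice cell: stage counts are effective quantities, and the
#'   gamma generalization of the per-phase added sizes makes fractional
#'   values meaningful (the reshaping count in particular is often
#'   genuinely between 1 and 2).
#' @return List with `N`, `N0`, `N1`, `objective`, `rates` (the
#'   [estimate_rates()] result at the optimum), `n_evaluated`, `bins`.
#' @export
fit_stage_numbers <- function(sizes, p, nu = NA_real_, alpha, S, B, g0,
                              model = c("I", "II"), M = 100,
                              N_range = c(2, 150), steps = c(5, 3, 1),
                              polish = TRUE) {
  model <- match.arg(model)
  sizes <- sizes[is.finite(sizes) & sizes > 0]
  breaks <- seq(min(sizes), max(sizes), length.out = M + 1)
  centers <- (breaks[-1] + breaks[-(M + 1)]) / 2
  wbin <- diff(breaks)[1]
  phat <- tabulate(findInterval(sizes, breaks, rightmost.closed = TRUE),
                   nbins = M) / (length(sizes) * wbin)

  dens_fun <- if (model == "I") cellsize_density_det else cellsize_density_stoch
  objective <- function(N, N0, N1) {
    rt <- estimate_rates(S, B, N0, N1, alpha, g0)
    if (!rt$feasible) return(NULL)
    sh <- list(N = N, N0 = N0, N1 = N1, M0 = rt$M0, M1 = rt$M1,
               p = p, alpha = alpha, nu = if (model == "I") NA_real_ else nu)
    d <- tryCatch(dens_fun(sh, grid = centers), error = function(e) NULL)
    if (is.null(d)) return(NULL)
    list(obj = sum((d$density - phat)^2), rates = rt)
  }

  best <- list(obj = Inf, N = NA, N0 = NA, N1 = NA, rates = NULL)
  n_eval <- 0L
  consider <- function(N, N0, N1) {
    res <- objective(N, N0, N1)
    n_eval <<- n_eval + 1L
    if (!is.null(res) && res$obj < best$obj - 1e-15)
      best <<- list(obj = res$obj, N = N, N0 = N0, N1 = N1, rates = res$rates)
    invisible(NULL)
  }
  lo <- max(2L, ceiling(N_range[1])); hi <- floor(N_range[2])
  for (N in seq(lo, hi, by = steps[1]))
    for (N0 in seq(1L, N - 1L, by = steps[2]))
      for (N1 in seq(0L, N - N0, by = steps[3]))
        consider(N, N0, N1)
  if (!is.finite(best$obj))
    stop("no feasible stage-number candidate in the search range")
  # exhaustive pass in the winning lattice cell
  for (N in max(lo, best$N - steps[1] + 1L):min(hi, best$N + steps[1] - 1L))
    for (N0 in max(1L, best$N0 - steps[2] + 1L):min(N - 1L, best$N0 + steps[2] - 1L))
      for (N1 in max(0L, best$N1 - steps[3]):min(N - N0, best$N1 + steps[3]))
        if (!(N == best$N && N0 == best$N0 && N1 == best$N1))
          consider(N, N0, N1)
  if (polish) {
    # gamma-shape relaxation: stage counts are effective (real) quantities,
    # so refine the integer optimum continuously within its lattice cell
    pen <- function(th) {
      N <- th[1]; N0 <- th[2]; N1 <- th[3]
      if (N < max(lo, 1.5) || N > hi || N0 < 0.5 || N1 < 0 ||
          N0 + N1 > N) return(1e6)
      res <- objective(N, N0, N1)
      if (is.null(res)) return(1e6)
      res$obj
    }
    opt <- optim(c(best$N, best$N0, best$N1), pen, method = "Nelder-Mead",
                 control = list(reltol = 1e-4, maxit = 250))
    if (opt$value < best$obj) {
      rt <- estimate_rates(S, B, opt$par[2], opt$par[3], alpha, g0)
      best <- list(obj = opt$value, N = opt$par[1], N0 = opt$par[2],
                   N1 = opt$par[3], rates = rt)
    }
  }
  list(N = best$N, N0 = best$N0, N1 = best$N1, objective = best$obj,
       rates = best$rates, n_evaluated = n_eval,
       bins = list(M = M, breaks = breaks))
}

#' Full parameter inference from a lineage dataset
#'
#' Runs the five estimation steps in sequence on a lineage dataset and
#' assembles the complete parameter vector: partitioning from the ratio
#' series, control strength from the birth/division correlation,
#' added-size moments from birth sizes, elongation rate from three-stage
#' time-course fits (averaged across generations), and stage numbers by
#' distribution matching, from which the transition constant and
#' reshaping rate follow.
#'
#' @param dataset A `lineage_dataset` (see [generate_dataset()],
#'   [read_lineages()]).
#' @param model `"I"` or `"II"`.
#' @param control Optional list overriding search settings:
#'   `N_range`, `steps`, `M` (passed to [fit_stage_numbers()]),
#'   `max_fit_generations` (cap on generations given to the three-stage
#'   fits, default 2000), `alpha_bracket`.
#' @param seed Optional seed (affects only the subsampling of generations
#'   for the growth-rate fits).
#' @return An object of class `size_control_fit`: list with `params` (a
#'   [growth_params()] object), `model`, `se` (bootstrap SEs, NA until
#'   [bootstrap_estimates()] is run), and `diagnostics`.
#' @export
infer_all <- function(dataset, model = c("I", "II"), control = list(),
                      seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "lineage_dataset"))
  if (!is.null(seed)) set.seed(seed)
  ctl <- modifyList(list(N_range = c(2, 150), steps = c(5, 3, 1), M = 100,
                         max_fit_generations = 2000, polish = TRUE,
                         alpha_bracket = c(0.05, 10)), control)
  gens <- extract_generations(dataset)

  part <- estimate_partition(gens$R[!is.na(gens$R)], model)
  al <- estimate_alpha(gens$V_b, gens$V_d, p = part$p, nu = part$nu,
                       model = model, bracket = ctl$alpha_bracket)
  mom <- estimate_added_moments(gens$V_b, al$alpha, part$p, part$nu, model)

  g0 <- mean_g0_from_timecourses(dataset, ctl$max_fit_generations)

  stage <- fit_stage_numbers(dataset$data$size_um, p = part$p, nu = part$nu,
                             alpha = al$alpha, S = mom$S, B = mom$B,
                             g0 = g0$g0, model = model, M = ctl$M,
                             N_range = ctl$N_range, steps = ctl$steps,
                             polish = ctl$polish)
  rt <- stage$rates
  g1 <- if (is.na(rt$g1)) g0$g0 * 1.0001 else rt$g1  # N1 = 0 degenerate case
  params <- growth_params(g0 = g0$g0, g1 = g1, a = rt$a, alpha = al$alpha,
                          N = stage$N, N0 = stage$N0, N1 = max(stage$N1, 0),
                          p = part$p,
                          nu = if (model == "I") NA_real_ else part$nu)
  structure(list(
    params = params, model = model,
    se = setNames(rep(NA_real_, 9),
                  c("g0", "g1", "a", "alpha", "N", "N0", "N1", "p", "nu")),
    diagnostics = list(objective = stage$objective, bins = stage$bins$M,
                       n_candidates = stage$n_evaluated,
                       alpha_at_boundary = al$at_boundary,
                       added_moments = mom, n_generations = nrow(gens),
                       g0_fit = g0[c("n_fit", "sd_g0")])
  ), class = "size_control_fit")
}

mean_g0_from_timecourses <- function(dataset, max_gens) {
  data <- dataset$data
  lineage_id <- generation_index <- time_h <- size_um <- NULL
  cnt <- data[, .N, by = .(lineage_id, generation_index)]
  keys <- cnt[cnt$N >= 6, .(lineage_id, generation_index)]
  if (nrow(keys) > max_gens)
    keys <- keys[sample.int(nrow(keys), max_gens)]
  sub <- data[keys, on = c("lineage_id", "generation_index")]
  g0s <- sub[, {
    f <- tryCatch(fit_three_stage(time_h, size_um), error = function(e) NULL)
    list(g0 = if (is.null(f)) NA_real_ else f$g0)
  }, by = .(lineage_id, generation_index)]$g0
  g0s <- g0s[is.finite(g0s) & g0s > 0]
  list(g0 = mean(g0s), sd_g0 = sd(g0s), n_fit = length(g0s))
}

#' @export
print.size_control_fit <- function(x, ...) {
  cat(sprintf("Size-control fit (model %s)\n", x$model))
  pe <- x$params
  fields <- c(g0 = pe$g0, g1 = pe$g1, a = pe$a, alpha = pe$alpha,
              N = pe$N, N0 = pe$N0, N1 = pe$N1, p = pe$p, nu = pe$nu)
  for (nm in names(fields)) {
    se <- x$se[[nm]]
    cat(sprintf("  %-6s %10.4g%s\n", nm, fields[[nm]],
                if (is.finite(se)) sprintf("  (SE %.3g)", se) else ""))
  }
  cat(sprintf("  distribution-matching objective %.4g over %d bins\n",
              x$diagnostics$objective, x$diagnostics$bins))
  invisible(x)
}

#' Bootstrap standard errors by lineage resampling
#'
#' Repeats the full inference `reps` times, each time on
#' `lineages_per_rep` lineages drawn with replacement from the dataset,
#' and reports the standard deviation of every parameter across
#' repetitions. Resampling is at the lineage level (lineages are the
#' independent units of the experiment). To keep repeated stage-number
#' searches affordable, each repetition searches `N` in a window around
#' the point estimate (`N_window`, default +/-30%) with a finer lattice.
#'
#' @param dataset A `lineage_dataset`.
#' @param fit A `size_control_fit` from [infer_all()] on the same data;
#'   computed if omitted.
#' @param reps Number of bootstrap repetitions (default 50).
#' @param lineages_per_rep Lineages drawn per repetition (default 50).
#' @param seed Optional seed.
#' @param N_window Relative half-width of the `N` search window.
#' @param control Passed to [infer_all()] for each repetition (the `N`
#'   window and steps are set from the point estimate unless given).
#' @return The input `fit` with `se` filled in and an `estimates`
#'   data.frame (one row per repetition) attached to `diagnostics`.
#' @export
bootstrap_estimates <- function(dataset, fit = NULL, reps = 50,
                                lineages_per_rep = 50, seed = NULL,
                                N_window = 0.3, control = list()) {
  stopifnot(inherits(dataset, "lineage_dataset"))
  if (is.null(fit)) fit <- infer_all(dataset, control = control)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(dataset$data$lineage_id)
  Nhat <- fit$params$N
  ctl <- modifyList(list(
    N_range = c(max(2, floor(Nhat * (1 - N_window))),
                ceiling(Nhat * (1 + N_window))),
    steps = c(2, 2, 1), max_fit_generations = 500), control)
  rows <- vector("list", reps)
  lineage_id <- NULL
  for (r in seq_len(reps)) {
    pick <- sample(ids, lineages_per_rep, replace = TRUE)
    # keep duplicated lineages as distinct resampled units
    pieces <- lapply(seq_along(pick), function(i) {
      d <- dataset$data[lineage_id == pick[i]]
      d$lineage_id <- i
      d
    })
    sub <- new_lineage_dataset(data.table::rbindlist(pieces), dataset$meta)
    est <- tryCatch(infer_all(sub, model = fit$model, control = ctl),
                    error = function(e) NULL)
    if (is.null(est)) next
    pe <- est$params
    rows[[r]] <- data.frame(g0 = pe$g0, g1 = pe$g1, a = pe$a,
                            alpha = pe$alpha, N = pe$N, N0 = pe$N0,
                            N1 = pe$N1, p = pe$p, nu = pe$nu)
  }
  est_df <- do.call(rbind, rows)
  if (is.null(est_df) || nrow(est_df) < 2)
    stop("bootstrap failed: fewer than 2 successful repetitions")
  fit$se <- vapply(est_df, sd, numeric(1))
  fit$diagnostics$bootstrap <- list(reps_done = nrow(est_df),
                                    estimates = est_df)
  fit
}

#' Ordinary least-squares summary of a scatter
#'
#' Minimal regression helper used to relate fitted parameters across
#' growth conditions (e.g. the reshaping rate `g1` against the elongation
#' rate `g0`).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regression_summary <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points")
  if (diff(range(x)) < .Machine$double.eps^0.5 * max(abs(x), 1))
    stop("degenerate input: x is constant")
  f <- lm(y ~ x)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r_squared = 1 - sum(f$residuals^2) / sum((y - mean(y))^2),
       n = length(x))
}
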