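#' Simulate complete generations by phase-level sampling
#'
#' Exact sampling of one cell cycle per element of `V_b`, using the fact
#' that the increment of `V^alpha` accumulated while the stage-transition
#' hazard `a*V^alpha` fires `N0` (resp. `N1`) times during exponential
#' growth is gamma distributed with shape `N0` (resp. `N1`) and mean
#' `M0 = N0*g0*alpha/a` (resp. `M1 = N1*g1*alpha/a`). The septation phase
#' holds size constant at `V_s`, so its duration is gamma with shape
#' `N - N0 - N1` and rate `a*V_s^alpha`. The partition ratio `R` applied at
#' the division closing the generation is fixed at `p` (model I) or drawn
#' from `Beta(p*nu, (1-p)*nu)` (model II).
#'
#' @param params A [growth_params()] object.
#' @param V_b Vector of positive birth sizes; one generation is simulated
#'   per element, independently.
#' @return A data.frame of generation summaries with columns `V_b`, `V_s`,
#'   `V_d`, `T_elong`, `T_sept`, `T_reshape`, `T` (total duration, h),
#'   `Delta0 = V_s^alpha - V_b^alpha`, `Delta1 = V_d^alpha - V_s^alpha`,
#'   and `R`.
#' @seealso [simulate_generation_stage()] for the stage-by-stage sampler
#'   used as a cross-check, [simulate_lineage()] for chained generations.
#' @export
simulate_generation_phase <- function(params, V_b) {
  stopifnot(inherits(params, "growth_params"))
  if (any(V_b <= 0)) stop("'V_b' must be positive")
  n <- length(V_b)
  dq <- derived_quantities(params)
  al <- params$alpha
  Ns <- params$N - params$N0 - params$N1
  if (Ns < -1e-9) stop("N - N0 - N1 is negative")
  Ns <- max(Ns, 0)

  u_b <- V_b^al
  D0 <- if (params$N0 > 0) rgamma(n, shape = params$N0, scale = dq$M0 / params$N0) else numeric(n)
  u_s <- u_b + D0
  D1 <- if (params$N1 > 0) rgamma(n, shape = params$N1, scale = dq$M1 / params$N1) else numeric(n)
  u_d <- u_s + D1

  V_s <- u_s^(1 / al)
  V_d <- u_d^(1 / al)
  T_elong <- log(V_s / V_b) / params$g0
  T_sept <- if (Ns > 0) rgamma(n, shape = Ns, rate = params$a * u_s) else numeric(n)
  T_reshape <- log(V_d / V_s) / params$g1
  R <- draw_partition_ratio(n, params)

  data.frame(V_b = V_b, V_s = V_s, V_d = V_d,
             T_elong = T_elong, T_sept = T_sept, T_reshape = T_reshape,
             T = T_elong + T_sept + T_reshape,
             Delta0 = D0, Delta1 = D1, R = R)
}

draw_partition_ratio <- function(n, params) {
  if (is.na(params$nu)) rep(params$p, n)
  else rbeta(n, params$p * params$nu, (1 - params$p) * params$nu)
}

#' Simulate complete generations stage by stage
#'
#' Brute-force sampler that walks through each of the `N` effective
#' cell-cycle stages individually; it requires integer stage counts. Within
#' a growing stage with rate `g`, the waiting time `tau` to the next stage
#' solves `(a*x^alpha/(alpha*g)) * (exp(alpha*g*tau) - 1) = E` with
#' `E ~ Exp(1)` and `x` the size at stage entry; within a septation stage,
#' `tau = E/(a*V_s^alpha)`. The marginal law of the generation summary is
#' identical to [simulate_generation_phase()]; this sampler exists as an
#' independent cross-check of the phase-level shortcut.
#'
#' @inheritParams simulate_generation_phase
#' @return A generation-summary data.frame as in
#'   [simulate_generation_phase()].
#' @export
simulate_generation_stage <- function(params, V_b) {
  stopifnot(inherits(params, "growth_params"))
  if (any(V_b <= 0)) stop("'V_b' must be positive")
  shapes <- c(params$N, params$N0, params$N1)
  if (any(abs(shapes - round(shapes)) > 1e-8))
    stop("stage-level sampling requires integer N, N0, N1")
  N0 <- round(params$N0); N1 <- round(params$N1)
  Ns <- round(params$N) - N0 - N1
  if (Ns < 0) stop("N - N0 - N1 is negative")
  n <- length(V_b)
  al <- params$alpha
  a <- params$a

  grow_stage <- function(u, g) {
    # u: V^alpha at stage entry; returns list(u, tau)
    E <- rexp(n)
    u_new <- u + (al * g / a) * E
    tau <- log(u_new / u) / (al * g)
    list(u = u_new, tau = tau)
  }

  u <- V_b^al
  T_elong <- numeric(n)
  if (N0 > 0) for (j in seq_len(N0)) {
    st <- grow_stage(u, params$g0)
    u <- st$u; T_elong <- T_elong + st$tau
  }
  u_s <- u
  T_sept <- numeric(n)
  if (Ns > 0) for (j in seq_len(Ns)) T_sept <- T_sept + rexp(n) / (a * u_s)
  T_reshape <- numeric(n)
  if (N1 > 0) for (j in seq_len(N1)) {
    st <- grow_stage(u, params$g1)
    u <- st$u; T_reshape <- T_reshape + st$tau
  }
  u_d <- u
  V_s <- u_s^(1 / al)
  V_d <- u_d^(1 / al)
  R <- draw_partition_ratio(n, params)

  data.frame(V_b = V_b, V_s = V_s, V_d = V_d,
             T_elong = T_elong, T_sept = T_sept, T_reshape = T_reshape,
             T = T_elong + T_sept + T_reshape,
             Delta0 = u_s - V_b^al, Delta1 = u_d - u_s, R = R)
}

#' Simulate a cell lineage over many generations
#'
#' Chains generations by tracking one daughter after every division:
#' the next birth size is `R * V_d` with `R` the sampled partition ratio.
#' The first `burn_in` generations are discarded so the returned summaries
#' are (approximately) stationary.
#'
#' @inheritParams simulate_generation_phase
#' @param n_generations Number of generations to return after burn-in.
#' @param burn_in Generations discarded before recording (default 50).
#' @param V_b0 Initial birth size; defaults to the zero-noise limit birth
#'   size implied by the parameters.
#' @param seed Optional integer seed for reproducibility.
#' @param sampler `"phase"` (default, works for fractional stage counts) or
#'   `"stage"` (integer stage counts only).
#' @return A generation-summary data.frame (see
#'   [simulate_generation_phase()]) with `n_generations` rows; successive
#'   rows satisfy `V_b[k+1] = R[k] * V_d[k]`.
#' @examples
#' gens <- simulate_lineage(reference_params("EMM_28C", "I"),
#'                          n_generations = 200, seed = 1)
#' cor(gens$V_b, gens$V_d)
#' @export
simulate_lineage <- function(params, n_generations, seed = NULL,
                             burn_in = 50, V_b0 = NULL,
                             sampler = c("phase", "stage")) {
  stopifnot(inherits(params, "growth_params"), n_generations >= 1)
  sampler <- match.arg(sampler)
  if (!is.null(seed)) set.seed(seed)
  dq <- derived_quantities(params)
  al <- params$alpha
  n <- burn_in + n_generations
  if (is.null(V_b0)) {
    # zero-noise stationary birth size as a sensible starting point
    V_b0 <- params$p * ((dq$M0 + dq$M1) / (1 - params$p^al))^(1 / al)
  }

  if (sampler == "stage") {
    out <- vector("list", n)
    V_b <- V_b0
    for (k in seq_len(n)) {
      g <- simulate_generation_stage(params, V_b)
      out[[k]] <- g
      V_b <- g$R * g$V_d
    }
    gens <- do.call(rbind, out)
    return(gens[(burn_in + 1):n, , drop = FALSE])
  }

  # phase-level: per-phase added sizes and partition ratios do not depend
  # on the current size, so draw them up front and only chain u_b
  D0 <- if (params$N0 > 0) rgamma(n, shape = params$N0, scale = dq$M0 / params$N0) else numeric(n)
  D1 <- if (params$N1 > 0) rgamma(n, shape = params$N1, scale = dq$M1 / params$N1) else numeric(n)
  R <- draw_partition_ratio(n, params)
  Ral <- R^al
  u_b <- numeric(n)
  u <- V_b0^al
  D <- D0 + D1
  for (k in seq_len(n)) {
    u_b[k] <- u
    u <- Ral[k] * (u + D[k])
  }
  u_s <- u_b + D0
  u_d <- u_s + D1
  Ns <- max(params$N - params$N0 - params$N1, 0)
  T_sept <- if (Ns > 0) rgamma(n, shape = Ns, rate = params$a * u_s) else numeric(n)
  T_elong <- (log(u_s) - log(u_b)) / (al * params$g0)
  T_reshape <- (log(u_d) - log(u_s)) / (al * params$g1)
  gens <- data.frame(V_b = u_b^(1 / al), V_s = u_s^(1 / al), V_d = u_d^(1 / al),
                     T_elong = T_elong, T_sept = T_sept, T_reshape = T_reshape,
                     T = T_elong + T_sept + T_reshape,
                     Delta0 = D0, Delta1 = D1, R = R)
  rownames(gens) <- NULL
  gens[(burn_in + 1):n, , drop = FALSE]
}

#' Sample a lineage time course on a regular grid
#'
#' Interpolates the deterministic within-generation growth curves of a
#' chain of generation summaries on a regular time grid (emulating
#' microscopy frames taken every few minutes), optionally corrupted by
#' multiplicative log-normal measurement noise.
#'
#' @param generations Generation-summary data.frame from
#'   [simulate_lineage()]; rows must be consecutive generations.
#' @param dt Sampling interval in hours (e.g. 0.05 for 3 min).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   measurement noise (0 = noiseless).
#' @return A data.frame with columns `time_h`, `size_um`,
#'   `generation_index` (1-based row of `generations`) and
#'   `is_division_sample` (TRUE on the last sample of each generation).
#' @export
sample_timecourse <- function(generations, dt, noise_cv = 0) {
  if (dt <= 0) stop("'dt' must be positive")
  stopifnot(all(c("V_b", "V_s", "T_elong", "T_sept", "T_reshape", "T") %in%
                  names(generations)))
  n <- nrow(generations)
  ends <- cumsum(generations$T)
  starts <- c(0, ends[-n])
  tgrid <- seq(0, ends[n] - 1e-12, by = dt)
  gen <- findInterval(tgrid, starts)
  s <- tgrid - starts[gen]

  Vb <- generations$V_b[gen]
  Vs <- generations$V_s[gen]
  Te <- generations$T_elong[gen]
  Tsp <- generations$T_sept[gen]
  # growth rates are implied by the summaries themselves
  size <- ifelse(s < Te,
                 Vb * exp(log(Vs / Vb) * s / Te),
                 ifelse(s < Te + Tsp,
                        Vs,
                        Vs * exp(log(generations$V_d[gen] / Vs) *
                                   pmin((s - Te - Tsp) / generations$T_reshape[gen], 1))))
  # degenerate phases (zero duration) fall through the branches safely
  size[!is.finite(size)] <- Vs[!is.finite(size)]
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    size <- size * exp(rnorm(length(size), mean = -sdlog^2 / 2, sd = sdlog))
  }
  last <- c(gen[-1] != gen[-length(gen)], TRUE)
  data.frame(time_h = tgrid, size_um = size,
             generation_index = gen, is_division_sample = last)
}
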