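#' Model parameters for three-phase cell-size dynamics
#'
#' Bundles the full parameter vector of the stochastic cell-size model:
#' a cell progresses through `N` effective cell-cycle stages at a
#' size-dependent rate `a * V(t)^alpha`; it grows exponentially at rate
#' `g0` during the first `N0` stages (elongation), does not grow during the
#' middle `N - N0 - N1` stages (septation), grows exponentially at the
#' faster rate `g1` during the last `N1` stages (reshaping), and then
#' divides. The tracked daughter receives a fraction `R` of the mother's
#' size, with `R = p` fixed (deterministic partitioning, model I) or
#' `R ~ Beta(p*nu, (1-p)*nu)` (stochastic partitioning, model II).
#'
#' Stage counts `N`, `N0`, `N1` may be non-integer: per-phase added sizes
#' then follow gamma rather than Erlang distributions, which coincide when
#' the shapes are integers. Sizes are in micrometres and rates in 1/h.
#'
#' @param g0 Exponential growth rate in the elongation phase (1/h).
#' @param g1 Exponential growth rate in the reshaping phase (1/h); must
#'   exceed `g0`.
#' @param a Proportionality constant of the stage-transition rate
#'   (units size^(-alpha)/h).
#' @param alpha Size-control strength (dimensionless): `alpha -> 0` timer,
#'   `alpha = 1` adder, `alpha -> Inf` sizer.
#' @param N Total number of effective cell-cycle stages (real, >= 1).
#' @param N0,N1 Stages in the elongation and reshaping phases (real, >= 0,
#'   `N0 + N1 <= N`).
#' @param p Mean partition ratio of the tracked daughter, in (0, 1).
#' @param nu Beta sample-size parameter (positive real) for stochastic
#'   partitioning, or `NA` (the default) for deterministic partitioning.
#'
#' @return An object of class `growth_params`.
#' @examples
#' gp <- growth_params(g0 = 0.214, g1 = 0.409, a = 0.055, alpha = 1.767,
#'                     N = 17.463, N0 = 11.262, N1 = 1.214, p = 0.459)
#' partition_model(gp)  # "I"
#' @export
growth_params <- function(g0, g1, a, alpha, N, N0, N1, p, nu = NA_real_) {
  stopifnot(length(g0) == 1, length(g1) == 1, length(a) == 1,
            length(alpha) == 1, length(N) == 1, length(N0) == 1,
            length(N1) == 1, length(p) == 1, length(nu) == 1)
  if (!is.finite(g0) || g0 <= 0) stop("'g0' must be positive")
  if (!is.finite(g1) || g1 <= g0) stop("'g1' must exceed 'g0'")
  if (!is.finite(a) || a <= 0) stop("'a' must be positive")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(N) || N < 1) stop("'N' must be >= 1")
  if (!is.finite(N0) || N0 < 0 || !is.finite(N1) || N1 < 0)
    stop("'N0' and 'N1' must be non-negative")
  if (N0 + N1 > N + 1e-9)
    stop("'N' must be at least N0 + N1")
  if (!is.finite(p) || p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  if (!is.na(nu) && (!is.finite(nu) || nu <= 0))
    stop("'nu' must be positive (or NA for deterministic partitioning)")
  structure(list(g0 = g0, g1 = g1, a = a, alpha = alpha,
                 N = N, N0 = N0, N1 = N1, p = p, nu = as.numeric(nu)),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Three-phase cell-size model parameters\n")
  cat(sprintf("  growth:    g0 = %.4g /h, g1 = %.4g /h\n", x$g0, x$g1))
  cat(sprintf("  control:   a = %.4g, alpha = %.4g\n", x$a, x$alpha))
  cat(sprintf("  stages:    N = %.4g (elongation %.4g, septation %.4g, reshaping %.4g)\n",
              x$N, x$N0, x$N - x$N0 - x$N1, x$N1))
  if (is.na(x$nu)) {
    cat(sprintf("  division:  deterministic, partition ratio p = %.4g (model I)\n", x$p))
  } else {
    cat(sprintf("  division:  Beta(p*nu, q*nu) with p = %.4g, nu = %.4g (model II)\n",
                x$p, x$nu))
  }
  invisible(x)
}

#' Which partitioning model do the parameters encode?
#'
#' @param params A [growth_params()] object.
#' @return `"I"` for deterministic partitioning (`nu` is `NA`), `"II"` for
#'   beta-distributed partitioning.
#' @export
partition_model <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  if (is.na(params$nu)) "I" else "II"
}

#' Derived quantities of the growth model
#'
#' Computes the mean generalized added sizes per phase and related ratios:
#' `M0 = N0*g0*alpha/a` and `M1 = N1*g1*alpha/a` are the means of the
#' gamma-distributed increments of `V^alpha` over the elongation and
#' reshaping phases, `A0 = M0/N0` and `A1 = M1/N1` the per-stage scales,
#' `r0 = N0/N` and `r1 = N1/N` the stage fractions, and `q = 1 - p`.
#' `A0`/`A1` are undefined when the corresponding phase has no stages;
#' they are stored as `NA` and the accessor [phase_scale()] raises an
#' error when they are requested.
#'
#' @param params A [growth_params()] object.
#' @return An object of class `derived_quantities`: a list with elements
#'   `M0`, `M1`, `A0`, `A1`, `r0`, `r1`, `q`, `N`, `N0`, `N1`, `alpha`, `p`,
#'   `nu`.
#' @examples
#' gp <- growth_params(g0 = 0.01, g1 = 0.02, a = 1, alpha = 2,
#'                     N = 25, N0 = 18, N1 = 3, p = 0.5)
#' derived_quantities(gp)$M0  # 18 * 0.01 * 2 / 1 = 0.36
#' @export
derived_quantities <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  M0 <- params$N0 * params$g0 * params$alpha / params$a
  M1 <- params$N1 * params$g1 * params$alpha / params$a
  structure(list(
    M0 = M0, M1 = M1,
    A0 = if (params$N0 > 0) M0 / params$N0 else NA_real_,
    A1 = if (params$N1 > 0) M1 / params$N1 else NA_real_,
    r0 = params$N0 / params$N, r1 = params$N1 / params$N,
    q = 1 - params$p,
    N = params$N, N0 = params$N0, N1 = params$N1,
    alpha = params$alpha, p = params$p, nu = params$nu
  ), class = "derived_quantities")
}

#' Per-stage added-size scale of a growth phase
#'
#' @param dq A [derived_quantities()] object.
#' @param phase `0` for elongation (`A0`), `1` for reshaping (`A1`).
#' @return The per-stage scale `A0` or `A1`; raises an error when the
#'   requested phase has zero stages so the scale is undefined.
#' @export
phase_scale <- function(dq, phase) {
  stopifnot(inherits(dq, "derived_quantities"), phase %in% c(0, 1))
  val <- if (phase == 0) dq$A0 else dq$A1
  if (is.na(val))
    stop(sprintf("per-stage scale A%d is undefined: phase has zero stages", phase))
  val
}

#' Beta density of the division partition ratio
#'
#' Density of the tracked daughter's partition ratio
#' `R ~ Beta(p*nu, (1-p)*nu)`, which has mean `p` and variance
#' `p*(1-p)/(nu + 1)`. As `nu -> Inf` the mass concentrates at `r = p`
#' (deterministic partitioning).
#'
#' @param r Ratio values, each in (0, 1).
#' @param p Mean partition ratio in (0, 1).
#' @param nu Positive sample-size parameter.
#' @return Density values `h(r)`.
#' @examples
#' partition_density(0.3, p = 0.5, nu = 2)  # Beta(1, 1): uniform, = 1
#' @export
partition_density <- function(r, p, nu) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1))
    stop("'r' must lie strictly in (0, 1)")
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be positive")
  dbeta(r, p * nu, (1 - p) * nu)
}

#' Map size-control strength to the conventional regression slope
#'
#' Under symmetric division and small size variability, the size-control
#' strength `alpha` of the stage-transition rate `a*V^alpha` maps onto the
#' slope `beta` of the linear birth-size/division-size relation
#' `V_d = beta*V_b + gamma + eps` as `beta = 2^(1 - alpha)`:
#' `alpha = 0` gives `beta = 2` (timer), `alpha = 1` gives `beta = 1`
#' (adder), and `alpha -> Inf` gives `beta -> 0` (sizer). The mapping is
#' only an interpretation aid outside that regime.
#'
#' @param alpha Non-negative size-control strength.
#' @return The conventional slope `2^(1 - alpha)`.
#' @export
alpha_to_beta <- function(alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  2^(1 - alpha)
}

#' Conventional size-control slope from birth/division size pairs
#'
#' Ordinary least squares of the division size on the birth size,
#' `V_d = beta*V_b + gamma + eps`. `beta = 0`, `1`, `2` correspond to the
#' sizer, adder and timer strategies. Values outside `[0, 2]` are reported
#' with a warning, not rejected.
#'
#' @param V_b,V_d Positive birth and division sizes of matched generations
#'   (at least 3 pairs).
#' @return An object of class `conventional_control`: list with `beta`
#'   (slope), `gamma` (intercept), `residual_sd`, `r_squared` and `n`.
#' @export
conventional_beta <- function(V_b, V_d) {
  keep <- is.finite(V_b) & is.finite(V_d)
  V_b <- V_b[keep]; V_d <- V_d[keep]
  if (length(V_b) < 3) stop("need at least 3 birth/division pairs")
  if (any(V_b <= 0) || any(V_d <= 0)) stop("sizes must be positive")
  if (diff(range(V_b)) < .Machine$double.eps^0.5 * mean(V_b))
    stop("degenerate input: all birth sizes are (numerically) equal")
  fit <- lm(V_d ~ V_b)
  beta <- unname(coef(fit)[2])
  if (beta < 0 || beta > 2)
    warning(sprintf("fitted slope %.3f lies outside [0, 2]; interpretation as a size-control strength is doubtful", beta))
  rss <- sum(fit$residuals^2)
  structure(list(
    beta = beta,
    gamma = unname(coef(fit)[1]),
    residual_sd = sqrt(rss / fit$df.residual),
    r_squared = 1 - rss / sum((V_d - mean(V_d))^2),
    n = length(V_b)
  ), class = "conventional_control")
}

#' @export
print.conventional_control <- function(x, ...) {
  cat(sprintf("Conventional size control: V_d = %.4g * V_b + %.4g  (n = %d)\n",
              x$beta, x$gamma, x$n))
  cat(sprintf("  residual sd %.4g, R^2 %.3f; slope 0/1/2 ~ sizer/adder/timer\n",
              x$residual_sd, x$r_squared))
  invisible(x)
}

#' Read and write model parameters as a flat YAML config
#'
#' Serializes a [growth_params()] object to a flat key:value file with keys
#' `g0, g1, a, alpha, N, N0, N1, p, nu`. Deterministic partitioning is
#' written as the sentinel string `"deterministic"` for `nu`.
#'
#' @param params A [growth_params()] object.
#' @param path File path.
#' @return `read_params()` returns a [growth_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "growth_params"))
  x <- unclass(params)
  if (is.na(x$nu)) x$nu <- "deterministic"
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("g0", "g1", "a", "alpha", "N", "N0", "N1", "p", "nu")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("parameter config is missing keys: ", paste(missing, collapse = ", "))
  nu <- x$nu
  if (identical(nu, "deterministic")) nu <- NA_real_
  growth_params(g0 = x$g0, g1 = x$g1, a = x$a, alpha = x$alpha,
                N = x$N, N0 = x$N0, N1 = x$N1, p = x$p, nu = as.numeric(nu))
}
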