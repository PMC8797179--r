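#' Published parameter estimates for fission yeast in seven growth conditions
#'
#' Model parameters previously estimated from microfluidic single-cell
#' lineage data of haploid fission yeast cultured in Edinburgh minimal
#' medium (EMM, 28/30/32/34 deg C) or yeast extract medium (YE, 28/30/34
#' deg C), for the deterministic-partitioning model (I) and the
#' beta-partitioning model (II). The mean partition ratio `p` and the
#' elongation growth rate `g0` are common to both models. Sizes refer to
#' cell length in micrometres and rates are per hour.
#'
#' These serve as realistic reference points for simulation studies and as
#' defaults for the synthetic-data generator.
#'
#' @param condition One of `"EMM_28C"`, `"EMM_30C"`, `"EMM_32C"`,
#'   `"EMM_34C"`, `"YE_28C"`, `"YE_30C"`, `"YE_34C"`.
#' @param model `"I"` (deterministic partitioning) or `"II"` (beta
#'   partitioning).
#' @return `reference_conditions()` returns a data.frame with one row per
#'   condition and model; `reference_params()` returns the corresponding
#'   [growth_params()] object.
#' @examples
#' reference_params("EMM_28C", "I")
#' @export
reference_conditions <- function() {
  cond <- c("EMM_28C", "EMM_30C", "EMM_32C", "EMM_34C",
            "YE_28C", "YE_30C", "YE_34C")
  m1 <- data.frame(
    condition = cond, model = "I",
    p     = c(0.459, 0.459, 0.468, 0.470, 0.466, 0.468, 0.475),
    alpha = c(1.767, 1.695, 1.726, 1.692, 1.139, 1.371, 1.245),
    N     = c(17.463, 20.727, 20.002, 21.010, 32.369, 45.713, 55.315),
    N0    = c(11.262, 13.646, 13.071, 14.623, 22.950, 29.759, 35.092),
    N1    = c(1.214, 0.817, 0.906, 0.714, 1.201, 1.870, 1.864),
    a     = c(0.055, 0.097, 0.085, 0.096, 0.755, 0.682, 1.258),
    g0    = c(0.214, 0.278, 0.280, 0.252, 0.328, 0.396, 0.468),
    g1    = c(0.409, 0.738, 0.767, 0.720, 0.618, 1.240, 1.674),
    nu    = NA_real_
  )
  m2 <- data.frame(
    condition = cond, model = "II",
    p     = m1$p,
    alpha = c(2.068, 1.936, 2.068, 1.990, 1.419, 1.622, 1.518),
    N     = c(16.387, 19.051, 18.609, 19.499, 30.137, 43.905, 50.067),
    N0    = c(10.406, 12.250, 11.984, 13.357, 21.156, 28.099, 30.741),
    N1    = c(1.458, 1.124, 1.005, 0.956, 2.170, 3.161, 3.405),
    a     = c(0.025, 0.049, 0.034, 0.043, 0.367, 0.357, 0.574),
    g0    = m1$g0,
    g1    = c(0.376, 0.528, 0.713, 0.558, 0.438, 0.796, 0.931),
    nu    = c(225.97, 257.01, 201.98, 206.33, 198.97, 272.09, 270.18)
  )
  rbind(m1, m2)
}

#' @rdname reference_conditions
#' @export
reference_params <- function(condition, model = c("I", "II")) {
  model <- match.arg(model)
  tab <- reference_conditions()
  row <- tab[tab$condition == condition & tab$model == model, ]
  if (nrow(row) != 1)
    stop("unknown condition '", condition, "'; see reference_conditions()")
  growth_params(g0 = row$g0, g1 = row$g1, a = row$a, alpha = row$alpha,
                N = row$N, N0 = row$N0, N1 = row$N1, p = row$p,
                nu = row$nu)
}
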