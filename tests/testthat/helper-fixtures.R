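# Shared fixtures: a fractional-shape parameter set matching a published
# EMM condition, a small integer-shape set convenient for stage-level
# sampling, and a generic adder.

emm_params <- function() reference_params("EMM_28C", "I")

int_params <- function(p = 0.5, alpha = 2, nu = NA_real_) {
  growth_params(g0 = 0.2, g1 = 0.5, a = 0.1, alpha = alpha,
                N = 20, N0 = 14, N1 = 2, p = p, nu = nu)
}

adder_params <- function() {
  growth_params(g0 = 0.2, g1 = 0.5, a = 0.3, alpha = 1,
                N = 15, N0 = 11, N1 = 2, p = 0.5)
}

# TV distance between two densities tabulated on one grid
tv_between <- function(x, d1, d2) 0.5 * pracma::trapz(x, abs(d1 - d2))

# time-weighted stationary size sample from a simulated lineage
stationary_sizes <- function(params, n_generations, seed, samples_per_gen = 50) {
  gens <- simulate_lineage(params, n_generations, seed = seed)
  dt <- mean(gens$T) / samples_per_gen
  sample_timecourse(gens, dt = dt)$size_um
}
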