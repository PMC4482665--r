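# Shared fixtures: toy libraries built in code and quick MCMC settings.

# 2-source, 1-tracer toy with well separated means.
toy_lib_2x1 <- function(sa = 1, sb = 1) {
  source_library(
    mean = matrix(c(0, 10), 1, 2, dimnames = list("t1", c("A", "B"))),
    sd = matrix(c(sa, sb), 1, 2, dimnames = list("t1", c("A", "B"))),
    kind = "si_delta"
  )
}

# 3-source, 2-tracer toy distinct from the packaged fixture.
toy_lib_3x2 <- function() {
  m <- matrix(c(-20, 4, -14, 9, -17, 1), 2, 3,
              dimnames = list(c("c", "n"), c("A", "B", "C")))
  s <- matrix(c(1.5, 1, 2, 1.2, 1.8, 1.4), 2, 3, dimnames = dimnames(m))
  source_library(m, s, kind = "si_delta")
}

si_fixture <- function() phytoplankton_si_library()

# Quick sampler settings for tests that only need rough posteriors.
quick_cfg <- function(seed = 1L, ...) {
  mcmc_config(iterations = 4000, burn_in = 2000, thin = 4, seed = seed, ...)
}

# Medium settings when quantiles are compared against the grid oracle.
oracle_cfg <- function(seed = 1L, ...) {
  mcmc_config(iterations = 40000, burn_in = 15000, thin = 10, seed = seed, ...)
}

# Wrap a draws matrix so posterior_summary/density_curve accept it.
fake_posterior <- function(draws) {
  structure(list(draws = draws, groups = colnames(draws),
                 consumer_id = "fake"), class = "diet_posterior")
}
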