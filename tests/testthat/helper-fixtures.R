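# Shared fixtures: all generated in code, deterministic via explicit seeds.

# a handy interior parameter point used across model-core tests
fixture_params <- function(k4 = NULL) {
  model_params(k1_mag = 1, k3 = 150, beta = 0.04, C = 0.1,
               alpha = 1.5, delta = 40, k4 = k4)
}

# random valid parameter vectors over physiologically sensible ranges,
# used by property-style loops
random_params <- function(n, seed = 7, k4 = FALSE) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      model_params(
        k1_mag = exp(stats::runif(1, log(1e-3), log(5))),
        k3 = stats::runif(1, 120, 400),
        beta = exp(stats::runif(1, log(0.005), log(0.2))),
        C = stats::runif(1, 0.01, 0.5),
        alpha = stats::runif(1, 0.5, 5),
        delta = stats::runif(1, 20, 80),
        k4 = if (k4) stats::runif(1, 0.05, 0.9) else NULL)
    })
  })
}

# small noiseless beat series from a known truth
noiseless_beats <- function(n = 60, truth = default_truth(), seed = 11) {
  simulate_beats(n = n, truth = truth, noise_sd = 0, seed = seed)
}
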