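# Recovery-study fits are the expensive part of the suite; they are computed
# once per session and shared between the blocks that assess them.

.recovery_cache <- new.env(parent = emptyenv())

# the scaled-down sampler budget used for the recovery study
recovery_config <- function() pt_config(n_chains = 8, n_sweeps = 2e5)

# 10 AF replicates (n = 800, truth beta = 0.04, sigma = 12), simple-model fits
af_recovery <- function() {
  if (!is.null(.recovery_cache$af)) return(.recovery_cache$af)
  cfg <- recovery_config()
  cfg_em <- pt_config(n_chains = 8, n_sweeps = 1e5)
  out <- purrr::map_dfr(1:10, function(i) {
    seed <- 100 + i
    beats <- simulate_beats(n = 800, seed = seed)
    sm <- suppressWarnings(
      fit_stiffness(beats, "simple", config = cfg, seed = seed,
                    uncertainty = FALSE))
    em <- suppressWarnings(
      fit_stiffness(beats, "expanded", config = cfg_em, seed = seed,
                    uncertainty = FALSE))
    tibble::tibble(replicate = i, beta_sm = sm$params[["beta"]],
                   fve_sm = sm$fve, fve_em = em$fve,
                   loglik_sm = sm$loglik)
  })
  .recovery_cache$af <- out
  out
}

# 10 SR replicates, identical truth, sinus-rhythm RR statistics
sr_contrast <- function() {
  if (!is.null(.recovery_cache$sr)) return(.recovery_cache$sr)
  cfg <- pt_config(n_chains = 6, n_sweeps = 5e4)
  out <- purrr::map_dfr(1:10, function(i) {
    seed <- 200 + i
    beats <- simulate_beats(n = 800, rhythm = "sr", seed = seed)
    f <- suppressWarnings(
      fit_stiffness(beats, "simple", config = cfg, seed = seed,
                    uncertainty = FALSE))
    tibble::tibble(replicate = i, fve = f$fve,
                   low_fve = "LOW_FVE" %in% f$flags)
  })
  .recovery_cache$sr <- out
  out
}
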