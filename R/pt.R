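#' Parallel-tempering configuration
#'
#' Bundles every tunable of the replica-exchange Metropolis optimizer.
#' Defaults follow the estimation setup the package implements: 24 chains on
#' an exponential temperature ladder with base 6, a diagonal Gaussian
#' proposal, box constraint `]0, 400[` for every parameter, random
#' initialization on wide intervals (log-space `]-40, 4[` for `k1_mag`,
#' `beta` and `C`; `]120, 400[` for `k3`; `]0, 5[` for `alpha`; `]20, 80[`
#' for `delta`; `]0, 1[` for `k4`), and rejection of starting points whose
#' log-likelihood does not exceed -5208.  The full-scale analysis runs tens
#' of millions of sweeps; the default `n_sweeps` here is a practical working
#' value — raise it for production-quality estimates.
#'
#' @param n_chains Number of tempered chains (default 24).
#' @param ladder_base Base of the exponential temperature ladder (default 6).
#' @param n_sweeps Number of sweeps; each sweep updates every chain once
#'   (default 2e5; the full-scale reference configuration uses 4e7).
#' @param proposal_scales Optional named numeric vector overriding the
#'   per-parameter proposal SDs.  Log-initialized parameters are proposed in
#'   log space (default SD 0.05 log units); linear parameters default to 1%
#'   of their initialization interval width.
#' @param init_loglik_threshold Starting points are redrawn until their
#'   log-likelihood exceeds this value (default -5208, i.e. SSE
#'   1,500,000 mmHg^2 at sigma = 12).
#' @param init_max_draws Cap on initialization draws before giving up
#'   (default 20000); exceeding it signals data incompatible with the
#'   model's support (e.g. sinus-rhythm-like input with an unreachable
#'   threshold).
#' @param constraint_low,constraint_high Open box constraint applied to
#'   every parameter (defaults 0 and 400).
#' @param swap_interval Sweeps between replica-exchange attempts on
#'   alternating even/odd adjacent chain pairs (default 10).
#' @return An object of class `pt_config` (a list).
#' @export
pt_config <- function(n_chains = 24, ladder_base = 6, n_sweeps = 2e5,
                      proposal_scales = NULL,
                      init_loglik_threshold = -5208, init_max_draws = 20000,
                      constraint_low = 0, constraint_high = 400,
                      swap_interval = 10) {
  stopifnot(n_chains >= 1, ladder_base > 0, n_sweeps >= 1,
            is.finite(init_loglik_threshold),
            constraint_low < constraint_high, swap_interval >= 1)
  structure(list(n_chains = as.integer(n_chains), ladder_base = ladder_base,
                 n_sweeps = as.integer(n_sweeps),
                 proposal_scales = proposal_scales,
                 init_loglik_threshold = init_loglik_threshold,
                 init_max_draws = as.integer(init_max_draws),
                 constraint_low = constraint_low,
                 constraint_high = constraint_high,
                 swap_interval = as.integer(swap_interval)),
            class = "pt_config")
}

#' Exponential temperature ladder
#'
#' `T_k = base^k` for `k = 0, ..., n_chains - 1`; the cold chain (`T = 1`)
#' samples the untempered likelihood.
#'
#' @param n_chains Number of chains.
#' @param base Ladder base (default 6).
#' @return Numeric vector of temperatures, increasing, first element 1.
#' @export
temperature_ladder <- function(n_chains, base = 6) {
  stopifnot(n_chains >= 1, base > 0)
  base^(seq_len(n_chains) - 1)
}

# Per-parameter sampling metadata: initialization interval, whether the
# parameter is handled in log space, and the default proposal SD (log-space
# parameters: 0.05 log units; linear: 1% of the initialization interval).
param_table <- function(model = c("simple", "expanded")) {
  model <- match.arg(model)
  tb <- tibble::tibble(
    term      = c("k1_mag", "k3", "beta", "C", "alpha", "delta", "k4"),
    log_scale = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    init_low  = c(-40, 120, -40, -40, 0, 20, 0),
    init_high = c(4, 400, 4, 4, 5, 80, 1),
    prop_sd   = c(0.05, 2.8, 0.05, 0.05, 0.05, 0.6, 0.01)
  )
  if (model == "simple") tb[tb$term != "k4", ] else tb
}

#' Draw a random starting point on the support of the likelihood
#'
#' Draws candidate parameter vectors from the initialization distribution
#' (`k1_mag`, `beta`, `C` as `exp(u)` with `u` uniform on `]-40, 4[`; `k3`
#' uniform on `]120, 400[`; `alpha` on `]0, 5[`; `delta` on `]20, 80[`;
#' `k4` on `]0, 1[`) and rejects them until the log-likelihood exceeds
#' `config$init_loglik_threshold`.  Deterministic given the R RNG state.
#'
#' @param data A beat series.
#' @param model `"simple"` or `"expanded"`.
#' @param sigma Pulse-pressure measurement-error SD (mmHg).
#' @param config A [pt_config()].
#' @param fixed Optional named numeric vector of parameters to hold at a
#'   fixed value instead of drawing them.
#' @return An [model_params()] object whose log-likelihood exceeds the
#'   threshold.
#' @export
sample_initial_point <- function(data, model = c("simple", "expanded"),
                                 sigma = 12, config = pt_config(),
                                 fixed = NULL) {
  model <- match.arg(model)
  tb <- param_table(model)
  obj <- build_objective(data, model, sigma)
  drawn <- 0L
  batch <- 64L
  while (drawn < config$init_max_draws) {
    n <- min(batch, config$init_max_draws - drawn)
    cand <- vapply(seq_len(nrow(tb)), function(j) {
      if (!is.null(fixed) && tb$term[j] %in% names(fixed)) {
        rep(fixed[[tb$term[j]]], n)
      } else {
        u <- stats::runif(n, tb$init_low[j], tb$init_high[j])
        if (tb$log_scale[j]) exp(u) else u
      }
    }, numeric(n))
    cand <- matrix(cand, nrow = n)
    drawn <- drawn + n
    for (i in seq_len(n)) {
      ll <- obj_loglik_cpp(obj, cand[i, ])
      if (ll > config$init_loglik_threshold) {
        return(as_lv_params(stats::setNames(cand[i, ], tb$term)))
      }
    }
  }
  stop("no starting point exceeded the initialization log-likelihood ",
       "threshold after ", config$init_max_draws, " draws; the data appear ",
       "incompatible with the model's support (or the threshold is too high)")
}

# internal: assemble sampler inputs and run the compiled core
run_pt <- function(objective, init, config, seed, n_sweeps,
                   tb, thin_cold = 0L) {
  prop_sd <- tb$prop_sd
  if (!is.null(config$proposal_scales)) {
    ov <- config$proposal_scales
    idx <- match(names(ov), tb$term)
    prop_sd[idx[!is.na(idx)]] <- ov[!is.na(idx)]
  }
  temps <- temperature_ladder(config$n_chains, config$ladder_base)
  pt_core(init, temps, prop_sd, tb$log_scale,
          config$constraint_low, config$constraint_high,
          as.integer(n_sweeps), config$swap_interval,
          objective, as.integer(seed), as.integer(thin_cold))
}

#' Advance a parallel-tempering ensemble
#'
#' Runs `n_sweeps` sweeps of the replica-exchange Metropolis sampler from a
#' given ensemble state and returns the updated state plus acceptance
#' bookkeeping.  Each sweep performs one diagonal-Gaussian Metropolis update
#' of `logL / T_k` per chain (proposals outside the box are rejected), and
#' every `config$swap_interval` sweeps adjacent chain pairs attempt a
#' replica-exchange swap with the standard acceptance ratio.  This is the
#' same compiled kernel [fit_stiffness()] uses; it is exposed for sampler
#' validation (e.g. against analytic test objectives).
#'
#' @param state Numeric matrix of chain states, `n_chains` x d, natural
#'   parameter scale; one row per chain, coldest first.
#' @param data Beat series defining the likelihood (ignored when
#'   `objective` is supplied).
#' @param model `"simple"` or `"expanded"`.
#' @param sigma Measurement-error SD (mmHg).
#' @param config A [pt_config()]; `n_chains` must equal `nrow(state)`.
#' @param n_sweeps Number of sweeps to run (default 1).
#' @param seed Integer seed for the sampler's internal streams.
#' @param objective Optional explicit objective: a list
#'   `list(kind = 2L, A = <curvature matrix>, center = <optimum>)` defines
#'   the quadratic test objective `logL = -(p - center)' A (p - center) / 2`.
#' @param thin_cold If positive, record the cold chain every `thin_cold`
#'   sweeps and return the samples.
#' @return A list with `state`, `state_loglik`, `best_p`, `best_loglik`,
#'   per-chain `accept`/`proposals`, per-pair `swap_accept`/`swap_attempts`,
#'   and `cold_samples`.
#' @export
pt_step <- function(state, data = NULL, model = c("simple", "expanded"),
                    sigma = 12, config = pt_config(), n_sweeps = 1,
                    seed = 1, objective = NULL, thin_cold = 0) {
  model <- match.arg(model)
  state <- as.matrix(state)
  stopifnot(nrow(state) == config$n_chains)
  if (is.null(objective)) {
    objective <- build_objective(data, model, sigma)
    tb <- param_table(model)
  } else {
    d <- ncol(state)
    tb <- tibble::tibble(term = paste0("p", seq_len(d)),
                         log_scale = rep(FALSE, d),
                         init_low = rep(0, d), init_high = rep(400, d),
                         prop_sd = rep(1, d))
  }
  run_pt(objective, state, config, seed, n_sweeps, tb, thin_cold)
}
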