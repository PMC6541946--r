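#' Fit the diastolic stiffness model to a beat series
#'
#' Box-constrained maximum-likelihood estimation of the pulse-pressure model
#' by parallel tempering.  Each chain is initialized independently on the
#' support of the likelihood (see [sample_initial_point()]), the ensemble is
#' advanced for `config$n_sweeps` sweeps, and the maximum *untempered*
#' log-likelihood over every evaluated point is returned as the best
#' likelihood vector (BLV).  Goodness of fit (Pearson-R^2 fraction of
#' variation explained), regularized Hessian-based uncertainty, residual
#' trend summaries, and advisory failure flags are attached to the result.
#'
#' The run is fully reproducible: all randomness derives from `seed`
#' (initialization through the R RNG, the sampler through per-chain internal
#' streams), and the cold chain's stream does not depend on the number of
#' chains.
#'
#' @param data A beat series: data frame with columns `t_dia` (filling
#'   interval, s), `pp` (pulse pressure, mmHg) and, for the expanded model,
#'   `t_dia_prev` (prepreceding RR interval, s; `NA` on the first beat).
#' @param model `"simple"` (6 parameters) or `"expanded"` (7 parameters,
#'   adds the prepreceding-interval weight `k4`).
#' @param sigma Assumed pulse-pressure measurement-error SD (mmHg),
#'   default 12.
#' @param config A [pt_config()].
#' @param seed Integer master seed.
#' @param uncertainty Compute the regularized Hessian covariance and
#'   per-parameter error estimates (default `TRUE`).
#' @param fixed Optional named numeric vector of parameters held fixed
#'   (not initialized randomly, proposal SD forced to 0); e.g.
#'   `c(k4 = 1e-9)` reduces the expanded model to the simple one while
#'   keeping the sampler's random streams for the free parameters
#'   unchanged.
#' @return An object of class `lvstiff_fit` with components `params` (the
#'   BLV as [model_params()]), `loglik`, `fve`, `model`, `sigma`, `n_used`,
#'   `covariance`, `errors`, `weak`, `flags`, `accept_rate`, `swap_rate`,
#'   `config`, `seed` and the input `data`.  Methods: [tidy.lvstiff_fit()],
#'   [glance.lvstiff_fit()], [augment.lvstiff_fit()],
#'   [autoplot.lvstiff_fit()], [residual_diagnostics()].
#' @examples
#' \donttest{
#' beats <- simulate_beats(n = 200, seed = 1)
#' fit <- fit_stiffness(beats, model = "simple",
#'                      config = pt_config(n_chains = 6, n_sweeps = 2e4),
#'                      seed = 1)
#' glance(fit)
#' }
#' @export
fit_stiffness <- function(data, model = c("simple", "expanded"), sigma = 12,
                          config = pt_config(), seed = 1,
                          uncertainty = TRUE, fixed = NULL) {
  model <- match.arg(model)
  data <- validate_beat_series(data, model = model)
  if (nrow(data) < 10) {
    warning("fewer than 10 beats: estimates will be poorly constrained")
  }
  tb <- param_table(model)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), tb$term)
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
    tb$prop_sd[tb$term %in% names(fixed)] <- 0
  }

  init <- withr::with_seed(seed, {
    t(vapply(seq_len(config$n_chains), function(k) {
      as.numeric(sample_initial_point(data, model, sigma, config,
                                      fixed = fixed))
    }, numeric(nrow(tb))))
  })

  obj <- build_objective(data, model, sigma)
  res <- run_pt(obj, init, config, seed, config$n_sweeps, tb)

  p <- stats::setNames(res$best_p, tb$term)
  lo <- config$constraint_low
  hi <- config$constraint_high
  if (any(p > hi - 1e-3 * (hi - lo)) || any(p < 1e-12)) {
    warning("best likelihood vector lies on or near a constraint boundary")
  }
  params <- as_lv_params(p)

  pred <- predict_pp(data, params)
  ok <- !is.na(pred$.pred)
  fve <- fraction_variation_explained(pred$pp[ok], pred$.pred[ok])

  fit <- structure(list(
    params = params, loglik = res$best_loglik, model = model, sigma = sigma,
    fve = fve, n_used = sum(ok), data = data,
    covariance = NULL, errors = NULL, weak = NULL,
    accept_rate = as.numeric(res$accept) / as.numeric(res$proposals),
    swap_rate = ifelse(res$swap_attempts > 0,
                       res$swap_accept / pmax(res$swap_attempts, 1), NA_real_),
    config = config, seed = seed, fixed = fixed, flags = character(0)
  ), class = "lvstiff_fit")

  if (uncertainty) {
    unc <- tryCatch(
      hessian_covariance(params, data, sigma = sigma, fixed = names(fixed)),
      error = function(e) {
        warning("uncertainty quantification failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(unc)) {
      fit$covariance <- unc$covariance
      fit$errors <- unc$errors
      fit$weak <- unc$weak_params
    }
  }
  fit$flags <- classify_inference_failure(fit)
  fit
}

#' @export
print.lvstiff_fit <- function(x, ...) {
  cat(sprintf("<lvstiff_fit: %s model, %d beats>\n", x$model, x$n_used))
  cat(sprintf("  log-likelihood (BLV): %.2f   FVE: %.3f\n", x$loglik, x$fve))
  est <- sprintf("%.4g", as.numeric(x$params))
  if (!is.null(x$errors)) {
    est <- paste0(est, " ± ", sprintf("%.3g", x$errors[names(x$params)]))
  }
  cat(paste0("  ", format(names(x$params), width = 7), est, collapse = "\n"),
      "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy per-parameter summary of a stiffness fit
#'
#' @param x An `lvstiff_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (regularized-Hessian error estimate, `NA` if uncertainty
#'   was not computed) and `weakly_identified`.
#' @export
tidy.lvstiff_fit <- function(x, ...) {
  nm <- names(x$params)
  tibble::tibble(
    term = nm,
    estimate = as.numeric(x$params),
    std.error = if (is.null(x$errors)) NA_real_ else
      as.numeric(x$errors[nm]),
    weakly_identified = if (is.null(x$weak)) NA else as.logical(x$weak[nm])
  )
}

#' One-row summary of a stiffness fit
#'
#' @param x An `lvstiff_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n_beats`, `logLik`, `fve`, `beta`,
#'   `beta_error`, `alpha`, `alpha_error`, `flags` (comma-separated), `seed`.
#' @export
glance.lvstiff_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_beats = x$n_used, logLik = x$loglik, fve = x$fve,
    beta = x$params[["beta"]],
    beta_error = if (is.null(x$errors)) NA_real_ else x$errors[["beta"]],
    alpha = x$params[["alpha"]],
    alpha_error = if (is.null(x$errors)) NA_real_ else x$errors[["alpha"]],
    flags = paste(x$flags, collapse = ","), seed = x$seed
  )
}

#' Per-beat predictions and residuals of a stiffness fit
#'
#' @param x An `lvstiff_fit`.
#' @param ... Unused.
#' @return The fitted beat series with `.pred` and `.resid` columns.
#' @export
augment.lvstiff_fit <- function(x, ...) {
  out <- predict_pp(x$data, x$params)
  dplyr::mutate(out, .resid = .data$pp - .data$.pred)
}
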