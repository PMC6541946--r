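#' Regularize an observed-information matrix into a covariance
#'
#' The Hessian of the log-likelihood at the maximum-likelihood point is, for
#' ill-posed problems, routinely indefinite or rank deficient and therefore
#' not invertible to a classical covariance.  This routine forms a
#' generalized-inverse covariance by eigendecomposing the negative Hessian,
#' flooring eigenvalues at `eps` times the largest one, and inverting on
#' that regularized spectrum.  Directions whose eigenvalue was floored are
#' reported as weakly identified.
#'
#' @param hessian Square numeric matrix: the Hessian of the log-likelihood
#'   (not its negative) at the optimum.
#' @param eps Relative eigenvalue floor (default 1e-10).
#' @return A list: `covariance` (symmetric positive semi-definite),
#'   `errors` (square roots of the diagonal), `weak_directions` (indices of
#'   floored eigendirections), `weak_params` (logical per parameter: does
#'   the parameter load mainly on floored directions?), `eigenvalues` (of
#'   the negative Hessian, before flooring).
#' @export
regularized_covariance <- function(hessian, eps = 1e-10) {
  if (any(!is.finite(hessian))) {
    bad <- which(!is.finite(hessian), arr.ind = TRUE)[1, ]
    nm <- rownames(hessian)
    lab <- if (is.null(nm)) paste(bad, collapse = ",") else
      paste(nm[bad[1]], nm[bad[2]], sep = ", ")
    stop("non-finite Hessian entry for parameter pair (", lab, ")")
  }
  nh <- -(hessian + t(hessian)) / 2
  eg <- eigen(nh, symmetric = TRUE)
  lmax <- max(eg$values)
  if (lmax <= 0) {
    stop("no direction of negative curvature at the optimum; ",
         "covariance is undefined")
  }
  floor_at <- eps * lmax
  weak <- which(eg$values < floor_at)
  lam <- pmax(eg$values, floor_at)
  cov <- eg$vectors %*% (t(eg$vectors) / lam)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- dimnames(hessian)
  load_weak <- if (length(weak)) {
    rowSums(eg$vectors[, weak, drop = FALSE]^2)
  } else {
    rep(0, nrow(cov))
  }
  list(covariance = cov,
       errors = stats::setNames(sqrt(pmax(diag(cov), 0)), rownames(cov)),
       weak_directions = weak,
       weak_params = stats::setNames(load_weak > 0.5, rownames(cov)),
       eigenvalues = eg$values)
}

#' Hessian-based uncertainty of a fitted parameter vector
#'
#' Differentiates the beat-series log-likelihood numerically at the best
#' likelihood vector and converts the (possibly indefinite) Hessian into a
#' regularized covariance via [regularized_covariance()].
#'
#' @param params The parameter vector (interior to the constraints).
#' @param data The fitted beat series.
#' @param sigma Measurement-error SD (mmHg).
#' @param eps Relative eigenvalue floor.
#' @param fixed Character vector of parameter names held fixed during
#'   fitting; they are excluded from differentiation and reported with zero
#'   error.
#' @return As [regularized_covariance()], with `errors` and `weak_params`
#'   covering every parameter (fixed ones at 0 / FALSE).
#' @export
hessian_covariance <- function(params, data, sigma = 12, eps = 1e-10,
                               fixed = NULL) {
  nm <- names(params)
  free <- setdiff(nm, fixed)
  model <- model_kind(params)
  obj <- build_objective(data, model, sigma)
  p0 <- as.numeric(params)
  names(p0) <- nm
  fn <- function(pf) {
    p <- p0
    p[free] <- pf
    obj_loglik_cpp(obj, as.numeric(p[nm]))
  }
  H <- numDeriv::hessian(fn, p0[free])
  dimnames(H) <- list(free, free)
  out <- regularized_covariance(H, eps = eps)
  errors <- stats::setNames(numeric(length(nm)), nm)
  weak <- stats::setNames(logical(length(nm)), nm)
  errors[free] <- out$errors
  weak[free] <- out$weak_params
  out$errors <- errors
  out$weak_params <- weak
  out
}

#' Residual trends against filling interval, prepreceding interval and
#' observed pulse pressure
#'
#' Pairs the fit residuals with the three covariates used to judge model
#' adequacy and summarizes each pairing by the slope of a least-squares line
#' and the Pearson correlation.  A systematic trend of simple-model
#' residuals against the prepreceding interval is the signature that
#' motivates the expanded model; after refitting with the expanded model the
#' trend should vanish.
#'
#' @param fit An `lvstiff_fit`, or a beat series (then `params` must be
#'   given).
#' @param params Parameter vector when `fit` is a data frame.
#' @return A tibble with one row per pairing: `pairing` (`"t_dia"`,
#'   `"t_dia_prev"`, `"pp"`), `slope`, `correlation`, `p.value`, and a
#'   list-column `residual_data` holding `(x, resid)` pairs.
#' @export
residual_diagnostics <- function(fit, params = NULL) {
  if (inherits(fit, "lvstiff_fit")) {
    aug <- augment(fit)
  } else {
    aug <- predict_pp(fit, params)
    aug$.resid <- aug$pp - aug$.pred
  }
  covars <- list(t_dia = aug$t_dia, pp = aug$pp)
  if ("t_dia_prev" %in% names(aug)) {
    covars <- c(covars[1], list(t_dia_prev = aug$t_dia_prev), covars[2])
  }
  purrr::map_dfr(names(covars), function(nm) {
    x <- covars[[nm]]
    r <- aug$.resid
    keep <- !is.na(x) & !is.na(r)
    x <- x[keep]; r <- r[keep]
    if (stats::sd(r) == 0 || stats::sd(x) == 0) {
      slope <- 0; rho <- 0; pv <- 1
    } else {
      fit_lm <- stats::lm(r ~ x)
      slope <- unname(stats::coef(fit_lm)[2])
      ct <- stats::cor.test(x, r)
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    tibble::tibble(pairing = nm, slope = slope, correlation = rho,
                   p.value = pv,
                   residual_data = list(tibble::tibble(x = x, resid = r)))
  })
}

#' Advisory classification of inference failure
#'
#' Applies the two documented failure signatures plus a plausibility bound:
#' `LOW_FVE` when the fraction of variation explained falls below `fve_min`
#' (nonstationary data — e.g. a drifting pulse-pressure baseline — leave
#' most variation unexplained); `IMPLAUSIBLE_BETA` when the estimated
#' stiffness falls an order of magnitude below the physiological range
#' (`beta < beta_floor`) or above `beta_ceiling`;
#' `DEGENERATE_LINEAR` when a straight-line fit of pulse pressure against
#' filling time explains essentially as much variation as the nonlinear
#' model (within `linear_delta`), indicating the record never reaches the
#' filling plateau and the stiffness is unidentified.  Flags are advisory,
#' never fatal.
#'
#' @param fit An `lvstiff_fit` (or a list with `fve`, `params`, `data`).
#' @param fve_min Minimum acceptable FVE (default 0.15).
#' @param beta_floor,beta_ceiling Plausible stiffness range (1/ml), defaults
#'   0.01 and 0.2.
#' @param linear_delta FVE margin for the reduced linear model
#'   (default 0.02).
#' @return Character vector of zero or more flags.
#' @export
classify_inference_failure <- function(fit, fve_min = 0.15,
                                       beta_floor = 0.01, beta_ceiling = 0.2,
                                       linear_delta = 0.02) {
  flags <- character(0)
  if (fit$fve < fve_min) flags <- c(flags, "LOW_FVE")
  beta <- fit$params[["beta"]]
  if (beta < beta_floor || beta > beta_ceiling) {
    flags <- c(flags, "IMPLAUSIBLE_BETA")
  }
  lin <- stats::lm(pp ~ t_dia, data = fit$data)
  lin_fve <- fraction_variation_explained(fit$data$pp, stats::fitted(lin))
  if (fit$fve - lin_fve <= linear_delta) {
    flags <- c(flags, "DEGENERATE_LINEAR")
  }
  flags
}
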