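#' Unnormalized Gaussian log-likelihood of a beat series
#'
#' Assumes independent, normally distributed pulse-pressure measurement
#' error with standard deviation `sigma` and returns
#' `-SSE / (2 * sigma^2)`, where `SSE` is the sum of squared differences
#' between observed and predicted pulse pressures.  The additive Gaussian
#' normalization constant is deliberately omitted: the statistic is then 0
#' for a perfect fit and directly comparable with the initialization
#' threshold (an SSE of 1,500,000 mmHg^2 at `sigma = 12` gives -5208).
#'
#' For the expanded model the first recorded beat (which has no prepreceding
#' interval) is excluded.  Parameters outside the open box `]0, 400[` or
#' producing non-finite predictions score `-Inf`.
#'
#' @param params An [model_params()] object or named vector.
#' @param data A beat series (columns `t_dia`, `pp`, optionally
#'   `t_dia_prev`).
#' @param sigma Measurement-error SD of pulse pressure (mmHg), default 12.
#' @return A single number, larger is better, at most 0.
#' @export
log_likelihood <- function(params, data, sigma = 12) {
  stopifnot(sigma > 0, nrow(data) >= 1)
  p <- unclass(unlist(params))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 400)) return(-Inf)
  pred <- tryCatch(predict_pp(data, as_lv_params(p))$.pred,
                   error = function(e) NA_real_)
  ok <- !is.na(pred)
  if (!any(ok) || any(!is.finite(pred[ok]))) return(-Inf)
  sse <- sum((data$pp[ok] - pred[ok])^2)
  ll <- -sse / (2 * sigma^2)
  if (!is.finite(ll)) -Inf else ll
}

#' Pearson fraction of variation explained
#'
#' The square of the Pearson correlation between observed and predicted
#' pulse pressures, used as the goodness-of-fit measure (FVE).  Invariant
#' under affine rescaling of the predictions.
#'
#' @param observed,predicted Numeric vectors of equal length (at least 3).
#' @return A number in `[0, 1]`.
#' @export
fraction_variation_explained <- function(observed, predicted) {
  keep <- !is.na(observed) & !is.na(predicted)
  observed <- observed[keep]
  predicted <- predicted[keep]
  if (length(observed) < 3 || length(observed) != length(predicted)) {
    stop("need at least 3 paired finite observations")
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("fraction of variation explained is undefined for zero-variance input")
  }
  stats::cor(observed, predicted)^2
}

# internal: objective descriptor consumed by the C++ sampler
build_objective <- function(data, model, sigma) {
  if (model == "expanded") {
    d <- data[!is.na(data$t_dia_prev), , drop = FALSE]
    list(kind = 1L, t_dia = as.numeric(d$t_dia),
         t_dia_prev = as.numeric(d$t_dia_prev),
         pp = as.numeric(d$pp), sigma = sigma)
  } else {
    list(kind = 0L, t_dia = as.numeric(data$t_dia),
         pp = as.numeric(data$pp), sigma = sigma)
  }
}
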