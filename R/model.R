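#' Model parameters of the diastolic filling / pulse-pressure model
#'
#' Constructs the parameter vector of the beat-to-beat pulse-pressure model.
#' The closed-form filling model predicts end-diastolic volume from the
#' diastolic filling interval through the combined inflow parameters `k1` and
#' `k3`, the exponential diastolic stiffness `beta` and a time shift `C`.  A
#' linear aortic observation model (compliance `alpha`, zero-offset `delta`)
#' maps volume to pulse pressure.  The expanded model adds `k4`, a weight on
#' the prepreceding RR interval that absorbs beat-to-beat inotropic effects.
#'
#' The physical `k1` is strictly negative; it is stored as the positive
#' magnitude `k1_mag` so that all parameters live in the open box
#' `]0, 400[` used by the constrained optimizer.
#'
#' @param k1_mag Magnitude of the combined inflow parameter `k1` (ml/s); the
#'   physical `k1` equals `-k1_mag`.
#' @param k3 Combined inflow parameter (ml/s).
#' @param beta Exponential diastolic stiffness (1/ml).
#' @param C Time shift constant (s) aligning the filling clock with measured
#'   RR intervals (absorbs, e.g., systolic duration).
#' @param alpha Aortic compliance (ml/mmHg).
#' @param delta Pressure zero-offset (mmHg).
#' @param k4 Weight of the prepreceding RR interval (dimensionless).  Supply
#'   it to obtain the expanded 7-parameter model; leave `NULL` for the simple
#'   6-parameter model.
#'
#' @return An object of class `lv_params`: a named numeric vector with
#'   attribute `model` (`"simple"` or `"expanded"`).
#' @examples
#' p <- model_params(k1_mag = 1, k3 = 150, beta = 0.04, C = 0.1,
#'                   alpha = 1.5, delta = 40)
#' filling_asymptote(p)
#' @export
model_params <- function(k1_mag, k3, beta, C, alpha, delta, k4 = NULL) {
  x <- c(k1_mag = k1_mag, k3 = k3, beta = beta, C = C,
         alpha = alpha, delta = delta)
  if (!is.null(k4)) x <- c(x, k4 = k4)
  if (!all(is.finite(x))) stop("all model parameters must be finite")
  if (any(x <= 0) || any(x >= 400)) {
    stop("all model parameters must lie strictly inside ]0, 400[")
  }
  structure(x, class = "lv_params",
            model = if (is.null(k4)) "simple" else "expanded")
}

#' @export
print.lv_params <- function(x, ...) {
  cat(sprintf("<lv_params: %s model>\n", attr(x, "model")))
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Coerce a named vector or list to `lv_params`
#'
#' @param x Named numeric vector or list with elements `k1_mag`, `k3`,
#'   `beta`, `C`, `alpha`, `delta` and optionally `k4`.
#' @return An `lv_params` object.
#' @export
as_lv_params <- function(x) {
  x <- unlist(x)
  k4 <- if ("k4" %in% names(x)) unname(x[["k4"]]) else NULL
  model_params(x[["k1_mag"]], x[["k3"]], x[["beta"]], x[["C"]],
               x[["alpha"]], x[["delta"]], k4 = k4)
}

#' Which observation model does a parameter vector belong to?
#'
#' @param params An `lv_params` object or named vector.
#' @return `"simple"` or `"expanded"`.
#' @export
model_kind <- function(params) {
  if (!is.null(attr(params, "model"))) return(attr(params, "model"))
  if ("k4" %in% names(params)) "expanded" else "simple"
}

#' Underlying physiology of the diastolic pressure-volume relation
#'
#' Bundles the physiological constants behind the combined inflow
#' parameters: the pressure scaling factor and unstressed volume of the
#' exponential end-diastolic pressure-volume relation, the mitral valve
#' resistance, and the (central venous) filling pressure.
#'
#' @param p_lv0 Pressure scaling factor (mmHg).
#' @param v_ed0 Unstressed volume (ml).
#' @param r_valve Mitral valve resistance (mmHg s/ml).
#' @param p_cvp Filling pressure (mmHg).
#' @return An object of class `lv_physiology` (named numeric vector).
#' @export
physiology_params <- function(p_lv0, v_ed0, r_valve, p_cvp) {
  x <- c(p_lv0 = p_lv0, v_ed0 = v_ed0, r_valve = r_valve, p_cvp = p_cvp)
  if (!all(is.finite(x)) || any(x <= 0)) {
    stop("all physiology parameters must be finite and strictly positive")
  }
  structure(x, class = "lv_physiology")
}

#' Diastolic left-ventricular pressure at a given volume
#'
#' Evaluates the exponential end-diastolic pressure-volume relation
#' `P(V) = P_LV0 * (exp(beta * (V - V_ED0)) - 1)`.
#'
#' @param volume Ventricular volume (ml); vectorized.
#' @param phys An [physiology_params()] object.
#' @param beta Exponential diastolic stiffness (1/ml).
#' @return Pressure (mmHg), same length as `volume`.
#' @export
lv_diastolic_pressure <- function(volume, phys, beta) {
  stopifnot(inherits(phys, "lv_physiology"), is.numeric(beta), beta > 0)
  z <- beta * (volume - phys[["v_ed0"]])
  if (any(z > 700)) {
    stop("beta * (volume - v_ed0) exceeds 700: nonphysical input would overflow")
  }
  phys[["p_lv0"]] * (exp(z) - 1)
}

#' Combined inflow parameters from physiology
#'
#' Maps the underlying physiology and stiffness to the combined inflow
#' parameters of the closed-form filling model:
#' `k1 = -(P_LV0 / R_valve) * exp(-beta * V_ED0)` (always negative) and
#' `k3 = (P_LV0 + P_cvp) / R_valve` (always positive).
#'
#' @inheritParams lv_diastolic_pressure
#' @return A list with elements `k1` (signed, negative) and `k3`.
#' @export
params_from_physiology <- function(phys, beta) {
  stopifnot(inherits(phys, "lv_physiology"), is.numeric(beta), beta > 0)
  list(
    k1 = -(phys[["p_lv0"]] / phys[["r_valve"]]) * exp(-beta * phys[["v_ed0"]]),
    k3 = (phys[["p_lv0"]] + phys[["p_cvp"]]) / phys[["r_valve"]]
  )
}

## Stable evaluation of the closed-form filling curve.
## V(t) = k3*(t + C) - (1/beta) * log(1 + (k1_mag/k3) * exp(beta*k3*(t + C)))
## written with log1p(exp(w)) = softplus(w), w = log(k1_mag/k3) + beta*k3*(t+C),
## which reduces to the large-argument asymptotic form automatically and has
## no overflow anywhere inside the search box.
ved_closed_form <- function(td, k1_mag, k3, beta, C) {
  tt <- td + C
  a <- beta * k3 * tt
  w <- log(k1_mag / k3) + a
  sp <- ifelse(w > 33, w, log1p(exp(pmin(w, 33))))
  k3 * tt - sp / beta
}

#' End-diastolic volume predicted from the filling interval
#'
#' Closed-form solution of the diastolic filling ODE
#' `dV/dt = k3 + k1 * exp(beta * V)` (with `k1 = -k1_mag`):
#' `V(t) = k3*(t + C) - (1/beta) * log(1 - (k1/k3) * exp(beta*k3*(t + C)))`.
#' The curve is strictly increasing and saturates at
#' [filling_asymptote()].  Evaluation uses a softplus formulation that is
#' overflow-safe for any parameters inside the constraint box; near-zero
#' stiffness is handled by the same expression, which degrades gracefully to
#' the linear filling limit.
#'
#' @param t_dia Filling interval (s); vectorized.
#' @param params An [model_params()] object (or named vector).
#' @return End-diastolic volume (ml).
#' @export
end_diastolic_volume <- function(t_dia, params) {
  if (any(t_dia < 0)) stop("t_dia must be non-negative")
  v <- ved_closed_form(t_dia, params[["k1_mag"]], params[["k3"]],
                       params[["beta"]], params[["C"]])
  if (any(!is.finite(v))) stop("end-diastolic volume is non-finite")
  v
}

#' Plateau volume of the filling curve
#'
#' The stationary point of `dV/dt = k3 - k1_mag * exp(beta * V)`, i.e.
#' `(1/beta) * log(k3 / k1_mag)`.  [end_diastolic_volume()] approaches this
#' value from below as the filling interval grows.
#'
#' @inheritParams end_diastolic_volume
#' @return Volume (ml).
#' @export
filling_asymptote <- function(params) {
  log(params[["k3"]] / params[["k1_mag"]]) / params[["beta"]]
}

#' Predicted pulse pressure, simple (6-parameter) model
#'
#' `PP = V_ED(t_dia) / alpha + delta`.
#'
#' @inheritParams end_diastolic_volume
#' @return Pulse pressure (mmHg).
#' @export
predict_pp_simple <- function(t_dia, params) {
  end_diastolic_volume(t_dia, params) / params[["alpha"]] + params[["delta"]]
}

#' Predicted pulse pressure, expanded (7-parameter) model
#'
#' `PP = V_ED(t_dia + k4 * t_dia_prev) / alpha + delta`, where `t_dia_prev`
#' is the RR interval preceding the filling interval.
#'
#' @inheritParams end_diastolic_volume
#' @param t_dia_prev Prepreceding RR interval (s); vectorized.
#' @return Pulse pressure (mmHg).
#' @export
predict_pp_expanded <- function(t_dia, t_dia_prev, params) {
  if (!"k4" %in% names(params)) stop("expanded model requires k4")
  if (any(t_dia_prev < 0)) stop("t_dia_prev must be non-negative")
  end_diastolic_volume(t_dia + params[["k4"]] * t_dia_prev, params) /
    params[["alpha"]] + params[["delta"]]
}

#' Predict pulse pressures for a beat series
#'
#' Data-frame-first prediction: takes a beat series (columns `t_dia`, `pp`
#' and, for the expanded model, `t_dia_prev`) and appends the model
#' prediction as `.pred`.  The model kind is taken from the parameter vector
#' (presence of `k4`).  For the expanded model, beats whose `t_dia_prev` is
#' missing (the first recorded beat) receive `NA`.
#'
#' @param data A beat-series data frame; see [read_beat_series()].
#' @param params An [model_params()] object.
#' @return The input as a tibble with an added `.pred` column (mmHg).
#' @export
predict_pp <- function(data, params) {
  data <- tibble::as_tibble(data)
  if (model_kind(params) == "simple") {
    pred <- predict_pp_simple(data$t_dia, params)
  } else {
    ok <- !is.na(data$t_dia_prev)
    pred <- rep(NA_real_, nrow(data))
    pred[ok] <- predict_pp_expanded(data$t_dia[ok], data$t_dia_prev[ok], params)
  }
  dplyr::mutate(data, .pred = pred)
}
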