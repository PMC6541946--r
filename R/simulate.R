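#' Default generating truth for synthetic beat series
#'
#' A physiologically anchored parameter vector used throughout examples and
#' recovery studies: stiffness `beta = 0.04` /ml (mid physiological range),
#' aortic compliance `alpha = 1.5` ml/mmHg (inside the reported
#' 0.8-2.2 ml/mmHg range), zero-offset `delta = 40` mmHg, and inflow
#' parameters (`k3`, `k1_mag`) and time shift `C` chosen so that the filling
#' curve saturates within the span of atrial-fibrillation RR intervals —
#' i.e. the pulse-pressure-vs-filling-time scatter shows the rising limb
#' *and* the plateau that make the stiffness identifiable.  The expanded
#' variant adds a prepreceding-interval weight `k4 = 0.25`.
#'
#' @param model `"simple"` or `"expanded"`.
#' @return An [model_params()] object.
#' @export
default_truth <- function(model = c("simple", "expanded")) {
  model <- match.arg(model)
  model_params(k1_mag = 0.025, k3 = 340, beta = 0.04, C = 0.02,
               alpha = 1.5, delta = 40,
               k4 = if (model == "expanded") 0.25 else NULL)
}

#' Truth vector for the degenerate linear regime
#'
#' A parameter vector whose filling curve stays far from its plateau over
#' observed RR intervals, so pulse pressure is effectively linear in filling
#' time and the stiffness is unidentifiable — the documented
#' degenerate-linear failure mode.
#'
#' @return An [model_params()] object (simple model).
#' @export
linear_regime_truth <- function() {
  model_params(k1_mag = 1e-3, k3 = 180, beta = 0.004, C = 0.1,
               alpha = 1.5, delta = 40)
}

#' Simulate RR-interval series with AF or SR statistics
#'
#' Draws independent RR intervals from a gamma distribution matched by
#' moments to the requested mean and SD, resampling any draw below `floor`
#' (0.25 s).  Defaults emulate the beat statistics of the two rhythm
#' groups: atrial fibrillation (mean 0.68 s, SD 0.12 s) and sinus rhythm
#' (mean 0.76 s, SD 0.024 s).  Serial correlation is not modeled.
#'
#' @param n Number of intervals.
#' @param rhythm `"af"` or `"sr"` (sets default mean/SD).
#' @param mean,sd Interval mean and SD (s); override the rhythm defaults.
#' @param floor Minimum physiological interval (s, default 0.25).
#' @return Numeric vector of `n` intervals (s).
#' @export
simulate_rri <- function(n, rhythm = c("af", "sr"), mean = NULL, sd = NULL,
                         floor = 0.25) {
  rhythm <- match.arg(rhythm)
  if (is.null(mean)) mean <- if (rhythm == "af") 0.68 else 0.76
  if (is.null(sd)) sd <- if (rhythm == "af") 0.12 else 0.024
  if (mean <= floor) stop("rri mean must exceed the ", floor, " s floor")
  if (sd < 0) stop("rri sd must be non-negative")
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  x <- stats::rgamma(n, shape = shape, rate = rate)
  for (i in 1:100) {
    low <- x < floor
    if (!any(low)) break
    x[low] <- stats::rgamma(sum(low), shape = shape, rate = rate)
  }
  if (any(x < floor)) stop("could not draw intervals above the floor; ",
                           "mean/sd combination infeasible")
  x
}

#' Forward-simulate pulse pressures for an RR-interval series
#'
#' Evaluates the filling + observation model at `truth` for each beat and
#' adds independent Gaussian measurement noise.  The first element of `rri`
#' provides the prepreceding interval of the first returned beat, so every
#' returned beat has a complete `(t_dia, t_dia_prev, pp)` record.
#'
#' @param rri RR-interval series (s), length `n + 1` for `n` beats.
#' @param truth An [model_params()] object (its kind decides whether the
#'   prepreceding interval enters the prediction).
#' @param noise_sd Measurement-noise SD (mmHg), default 12.
#' @return A beat-series tibble with columns `beat`, `t_dia`, `t_dia_prev`,
#'   `pp`.
#' @export
simulate_pp <- function(rri, truth, noise_sd = 12) {
  stopifnot(length(rri) >= 2, noise_sd >= 0)
  t_dia <- rri[-1]
  t_dia_prev <- rri[-length(rri)]
  mu <- if (model_kind(truth) == "expanded") {
    predict_pp_expanded(t_dia, t_dia_prev, truth)
  } else {
    predict_pp_simple(t_dia, truth)
  }
  tibble::tibble(beat = seq_along(t_dia), t_dia = t_dia,
                 t_dia_prev = t_dia_prev,
                 pp = mu + stats::rnorm(length(mu), 0, noise_sd))
}

#' Inject a documented failure mode into a beat series
#'
#' `"nonstationary_drift"` adds a monotone ramp of `magnitude` mmHg across
#' the record, violating the stationarity the model assumes (a drifting
#' pulse-pressure baseline).  `"linear_regime"` regenerates the pulse
#' pressures from [linear_regime_truth()] (plus noise), producing a record
#' without the nonlinear plateau, in which the stiffness collapses to a
#' degenerate linear fit.  `"none"` returns the series unchanged.
#'
#' @param data A beat-series tibble.
#' @param mode One of `"none"`, `"nonstationary_drift"`, `"linear_regime"`.
#' @param magnitude Ramp height in mmHg over the whole record
#'   (default 130; drift mode only).
#' @param truth Replacement truth for `"linear_regime"`
#'   (default [linear_regime_truth()]).
#' @param noise_sd Noise SD for regenerated pulse pressures (mmHg).
#' @return The modified beat series.
#' @export
inject_failure_mode <- function(data,
                                mode = c("none", "nonstationary_drift",
                                         "linear_regime"),
                                magnitude = 130,
                                truth = linear_regime_truth(),
                                noise_sd = 12) {
  mode <- match.arg(mode)
  n <- nrow(data)
  switch(mode,
    none = data,
    nonstationary_drift =
      dplyr::mutate(data, pp = .data$pp +
                      seq(0, magnitude, length.out = n)),
    linear_regime = {
      mu <- if (model_kind(truth) == "expanded") {
        predict_pp_expanded(data$t_dia, data$t_dia_prev, truth)
      } else {
        predict_pp_simple(data$t_dia, truth)
      }
      dplyr::mutate(data, pp = mu + stats::rnorm(n, 0, noise_sd))
    })
}

#' Simulate a complete synthetic beat series
#'
#' Convenience wrapper: RR intervals with the requested rhythm statistics,
#' model-generated pulse pressures at `truth` with Gaussian noise, and an
#' optional failure mode.  All randomness is drawn from `seed` when given.
#'
#' @param n Number of beats (default 800).
#' @param rhythm `"af"` or `"sr"`.
#' @param truth Generating parameter vector (default [default_truth()]
#'   of `model`).
#' @param model Truth kind when `truth` is not supplied.
#' @param noise_sd Measurement-noise SD (mmHg), default 12.
#' @param rri_mean,rri_sd Override the rhythm's RR-interval statistics (s).
#' @param failure_mode,drift_magnitude Passed to [inject_failure_mode()].
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return A beat-series tibble with attribute `truth`.
#' @examples
#' beats <- simulate_beats(n = 100, seed = 42)
#' head(beats)
#' @export
simulate_beats <- function(n = 800, rhythm = c("af", "sr"),
                           truth = NULL, model = c("simple", "expanded"),
                           noise_sd = 12, rri_mean = NULL, rri_sd = NULL,
                           failure_mode = "none", drift_magnitude = 130,
                           seed = NULL) {
  rhythm <- match.arg(rhythm)
  model <- match.arg(model)
  if (is.null(truth)) truth <- default_truth(model)
  gen <- function() {
    rri <- simulate_rri(n + 1, rhythm, mean = rri_mean, sd = rri_sd)
    out <- simulate_pp(rri, truth, noise_sd = noise_sd)
    inject_failure_mode(out, failure_mode, magnitude = drift_magnitude,
                        noise_sd = noise_sd)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "truth") <- truth
  out
}

#' Render a beat series as sampled ECG and arterial-pressure waveforms
#'
#' Builds ground-truth fixtures for the beat-detection pipeline: a QRS-like
#' template at every R-peak time (with a small T wave), and an arterial
#' pulse per beat whose amplitude equals that beat's pulse pressure above a
#' constant diastolic baseline.  Optional additive Gaussian noise and 8-bit
#' quantization emulate the reference corpus' recording quality.
#'
#' @param data A beat-series tibble (`t_dia`, `t_dia_prev`, `pp`).
#' @param fs Sampling rate (Hz, default 360; at least 100).
#' @param dbp Diastolic baseline pressure (mmHg, default 60).
#' @param noise_sd Additive noise SD on both signals (ECG in signal units,
#'   ABP in mmHg), default 0.
#' @param quantize Emulate 8-bit quantization (default `FALSE`).
#' @return An object of class `waveform_record`: list with `ecg`, `abp`,
#'   `fs` and the ground-truth `beat_times` (s; the first element is the
#'   lead-in beat opening the first RR interval).
#' @export
simulate_waveforms <- function(data, fs = 360, dbp = 60, noise_sd = 0,
                               quantize = FALSE) {
  stopifnot(fs >= 100)
  n <- nrow(data)
  if (n == 0) {
    return(structure(list(ecg = numeric(0), abp = numeric(0), fs = fs,
                          beat_times = numeric(0)),
                     class = "waveform_record"))
  }
  lead_in <- 0.5
  beat_times <- lead_in + c(0, cumsum(data$t_dia))  # n + 1 R peaks
  total <- max(beat_times) + 1.0
  t <- seq(0, total, by = 1 / fs)
  ns <- length(t)

  ecg <- numeric(ns)
  for (bt in beat_times) {
    ecg <- ecg + exp(-((t - bt) / 0.008)^2) -
      0.25 * exp(-((t - bt - 0.025) / 0.012)^2) +
      0.12 * exp(-((t - bt - 0.25) / 0.05)^2)
  }

  abp <- rep(dbp, ns)
  pulse_shape <- function(phi) {
    ifelse(phi < 0.3, sin(pi * phi / 0.6)^2,
           cos(pi * (phi - 0.3) / 1.4)^2)
  }
  # the lead-in beat gets a pulse too (amplitude of the first beat) so that
  # beat-quality filtering does not discard the first real pair downstream
  amp <- c(data$pp[1], data$pp)
  for (i in seq_len(n + 1)) {
    t0 <- beat_times[i]
    t1 <- if (i <= n) beat_times[i + 1] else t0 + 0.9 * data$t_dia[n]
    win <- which(t >= t0 & t < t1)
    phi <- (t[win] - t0) / (t1 - t0)
    abp[win] <- dbp + amp[i] * pulse_shape(phi)
  }

  if (noise_sd > 0) {
    ecg <- ecg + stats::rnorm(ns, 0, noise_sd)
    abp <- abp + stats::rnorm(ns, 0, noise_sd)
  }
  if (quantize) {
    q8 <- function(x) {
      rng <- range(x)
      lev <- (rng[2] - rng[1]) / 255
      if (lev == 0) x else rng[1] + round((x - rng[1]) / lev) * lev
    }
    ecg <- q8(ecg)
    abp <- q8(abp)
  }
  structure(list(ecg = ecg, abp = abp, fs = fs, beat_times = beat_times),
            class = "waveform_record")
}
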