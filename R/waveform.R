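#' Detect R peaks in a sampled ECG
#'
#' A compact single-lead QRS detector: band-pass the signal (default
#' 5-20 Hz), square its first difference to emphasize the steep QRS slopes,
#' threshold the resulting energy at a fraction of a block-wise running
#' percentile, enforce a refractory period, and refine each detection to the
#' local maximum of the raw signal.  This is a deliberately simplified
#' detector tuned for the clean-to-moderately-noisy records the package's
#' pipeline processes; no claim of fidelity to any published reference
#' detector is made.
#'
#' @param ecg Numeric vector, sampled ECG (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param band Pass band (Hz), default `c(5, 20)`.
#' @param refractory Minimum inter-peak distance (s), default 0.25.
#' @param threshold_frac Fraction of the running 98th-percentile energy used
#'   as detection threshold, default 0.3.
#' @param block Length of the percentile blocks (s), default 2.
#' @return Increasing vector of peak times (s); empty (with a message) for
#'   flat or low-amplitude input.
#' @export
detect_r_peaks <- function(ecg, fs, band = c(5, 20), refractory = 0.25,
                           threshold_frac = 0.3, block = 2) {
  stopifnot(fs > 0)
  if (length(ecg) < 2 * fs) stop("need at least 2 s of signal")
  if (max(abs(ecg - stats::median(ecg))) < 1e-6) {
    message("flat or low-amplitude ECG: no peaks detected")
    return(numeric(0))
  }
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, ecg)
  energy <- c(0, diff(filt))^2

  # block-wise running percentile, linearly interpolated between blocks
  bl <- max(1L, as.integer(block * fs))
  starts <- seq(1L, length(energy), by = bl)
  q <- vapply(starts, function(s) {
    stats::quantile(energy[s:min(s + bl - 1L, length(energy))], 0.98,
                    names = FALSE)
  }, numeric(1))
  centers <- pmin(starts + bl / 2, length(energy))
  run_q <- if (length(q) > 1) {
    stats::approx(centers, q, xout = seq_along(energy), rule = 2)$y
  } else {
    rep(q, length(energy))
  }
  thr <- threshold_frac * pmax(run_q, 1e-12)

  above <- energy > thr
  if (!any(above)) {
    message("no threshold crossings: no peaks detected")
    return(numeric(0))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts_r <- ends - runs$lengths + 1L
  cand <- purrr::map_int(which(runs$values), function(i) {
    seg <- starts_r[i]:ends[i]
    seg[which.max(energy[seg])]
  })

  # refractory: keep the stronger of any two candidates closer than the limit
  cand <- sort(cand)
  keep <- integer(0)
  for (ix in cand) {
    if (length(keep) && (ix - keep[length(keep)]) < refractory * fs) {
      if (energy[ix] > energy[keep[length(keep)]]) keep[length(keep)] <- ix
    } else {
      keep <- c(keep, ix)
    }
  }

  # refine to the local maximum of the raw signal
  half <- as.integer(0.05 * fs)
  refined <- vapply(keep, function(ix) {
    lo <- max(1L, ix - half)
    hi <- min(length(ecg), ix + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  (sort(unique(refined)) - 1) / fs
}

#' Per-beat pulse pressures from an arterial-pressure waveform
#'
#' For each detected beat, searches the window from its R peak to the next
#' (or to the end of the signal) for the systolic maximum and the preceding
#' diastolic minimum; the pulse pressure is their difference.  Beats whose
#' pulse pressure falls outside `pp_range` — or whose window has no
#' preceding minimum — are marked as dropped.
#'
#' @param abp Sampled arterial pressure (mmHg).
#' @param fs Sampling rate (Hz).
#' @param beat_times R-peak times (s) from [detect_r_peaks()].
#' @param pp_range Plausible pulse-pressure range (mmHg),
#'   default `c(5, 250)`.
#' @return A tibble with columns `beat_time`, `pp` (`NA` when dropped) and
#'   `dropped`; attribute `n_dropped`.
#' @export
detect_pulse_pressures <- function(abp, fs, beat_times,
                                   pp_range = c(5, 250)) {
  n <- length(beat_times)
  idx <- pmin(pmax(round(beat_times * fs) + 1L, 1L), length(abp))
  pp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- idx[i]
    hi <- if (i < n) idx[i + 1] - 1L else length(abp)
    if (hi <= lo + 2L) next
    win <- abp[lo:hi]
    imax <- which.max(win)
    if (imax <= 1L) next  # no samples before the systolic maximum
    v <- max(win) - min(win[1:imax])
    if (v >= pp_range[1] && v <= pp_range[2]) pp[i] <- v
  }
  out <- tibble::tibble(beat_time = beat_times, pp = pp,
                        dropped = is.na(pp))
  attr(out, "n_dropped") <- sum(is.na(pp))
  out
}

#' Pair RR intervals with the pulse pressures that follow them
#'
#' Builds the beat series the model consumes: the RR interval ending at beat
#' `i` becomes the filling interval paired with beat `i`'s pulse pressure,
#' and the previous RR interval is recorded as the prepreceding interval for
#' the expanded model.  A dropped beat invalidates both RR intervals it
#' borders — intervals are never spliced across dropped beats.  The first
#' `n` valid pairs are returned; if fewer exist, all are returned with a
#' warning.
#'
#' @param beat_times R-peak times (s).
#' @param pps Per-beat pulse pressures aligned with `beat_times` (`NA` =
#'   dropped), e.g. the `pp` column of [detect_pulse_pressures()].
#' @param n Number of pairs to return (default 800).
#' @return A beat-series tibble (`t_dia`, `t_dia_prev`, `pp`) with
#'   attributes `n_beats_in`, `n_excluded` (RR intervals invalidated by
#'   dropped beats or missing pulse pressures).
#' @export
pair_beats <- function(beat_times, pps, n = 800) {
  stopifnot(length(beat_times) == length(pps))
  nb <- length(beat_times)
  if (nb < 2) stop("need at least two beats to form an RR interval")
  ok <- !is.na(pps)
  # the opening beat only anchors the first interval; no pulse pressure is
  # required of it
  ok[1] <- TRUE
  rri <- diff(beat_times)                    # rri[i] ends at beat i + 1
  pair_ok <- ok[-1] & ok[-nb]                # both bordering beats intact
  t_dia <- rri
  pp <- pps[-1]
  t_dia_prev <- c(NA_real_, rri[-length(rri)])
  prev_ok <- c(FALSE, pair_ok[-length(pair_ok)])
  t_dia_prev[!prev_ok] <- NA_real_
  out <- tibble::tibble(t_dia = t_dia, t_dia_prev = t_dia_prev, pp = pp)
  out <- out[pair_ok, , drop = FALSE]
  n_excluded <- sum(!pair_ok)
  if (nrow(out) < n) {
    warning("only ", nrow(out), " valid pairs available (requested ", n, ")")
  } else {
    out <- out[seq_len(n), , drop = FALSE]
  }
  attr(out, "n_beats_in") <- nb
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Extract a beat series from a waveform record
#'
#' Convenience pipeline: R-peak detection, pulse-pressure detection, and
#' pairing.
#'
#' @param record A `waveform_record` (list with `ecg`, `abp`, `fs`).
#' @param n Number of pairs to return (default 800).
#' @param ... Passed to [detect_r_peaks()].
#' @return A beat-series tibble; see [pair_beats()].
#' @export
extract_beats <- function(record, n = 800, ...) {
  bt <- detect_r_peaks(record$ecg, record$fs, ...)
  pp <- detect_pulse_pressures(record$abp, record$fs, bt)
  pair_beats(bt, pp$pp, n = n)
}

#' Select the most stationary window of a beat series
#'
#' Automated surrogate for manual low-noise interval selection: slides a
#' window of `length` beats, scores each by the fraction of physiologically
#' implausible pulse pressures plus the absolute linear pulse-pressure trend
#' across the window (in mmHg over the window, penalizing the
#' nonstationarity of a drifting baseline), and returns the best-scoring
#' window.  Ties resolve to the earliest window.
#'
#' @param data A beat-series tibble.
#' @param length Window length in beats.
#' @param pp_range Plausible pulse-pressure range (mmHg).
#' @param trend_weight Weight of the trend term relative to the
#'   implausibility fraction (default 0.01 per mmHg of drift).
#' @return Integer vector `c(start, end)` (row indices), with attribute
#'   `trend` (fitted drift over the window, mmHg).
#' @export
select_stationary_window <- function(data, length, pp_range = c(5, 250),
                                     trend_weight = 0.01) {
  n <- nrow(data)
  stopifnot(length >= 2, n >= length)
  pp <- data$pp
  bad <- as.numeric(is.na(pp) | pp < pp_range[1] | pp > pp_range[2])
  pp0 <- ifelse(is.na(pp), 0, pp)
  x <- seq_len(n)
  L <- length
  # rolling least-squares slope via cumulative sums
  cs_y <- c(0, cumsum(pp0)); cs_xy <- c(0, cumsum(x * pp0))
  cs_bad <- c(0, cumsum(bad))
  starts <- seq_len(n - L + 1L)
  sy <- cs_y[starts + L] - cs_y[starts]
  sxy <- cs_xy[starts + L] - cs_xy[starts]
  nbad <- cs_bad[starts + L] - cs_bad[starts]
  sx <- L * (starts + (L - 1) / 2)
  sxx_c <- L * (L^2 - 1) / 12               # centered sum of squares of x
  slope <- (sxy - sx * sy / L) / sxx_c
  drift <- abs(slope) * (L - 1)
  score <- nbad / L + trend_weight * drift
  best <- which.min(score)                   # earliest on ties
  structure(c(start = starts[best], end = starts[best] + L - 1L),
            trend = unname(slope[best] * (L - 1)))
}
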