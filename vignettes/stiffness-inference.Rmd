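---
title: "Inferring diastolic stiffness from beat-to-beat monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring diastolic stiffness from beat-to-beat monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvstiff)
```

## The problem

Left-ventricular diastolic function is hard to quantify at the bedside.
The end-diastolic pressure-volume relation is well described by an
exponential,

$$P_{LV}(V) = P_{LV0}\left(e^{\beta (V - V_{ED0})} - 1\right),$$

whose exponent $\beta$ (units ml$^{-1}$) is the *diastolic stiffness* — a
direct quantitative measure of how compliant the relaxing ventricle is.
Measuring $\beta$ normally requires invasive pressure-volume loops under
preload variation.  In atrial fibrillation (AF), however, the heart varies
its own preload continuously: filling times fluctuate strongly from beat
to beat, and each filling time maps through the diastolic properties of
the ventricle into an end-diastolic volume and hence (via the
Frank-Starling mechanism and a compliant aorta) into an observable
arterial pulse pressure.  That natural broadband perturbation makes the
inverse problem — recover $\beta$ from routine ECG plus invasive arterial
pressure — tractable in AF, and intractable in regular sinus rhythm (SR),
where filling times barely vary.

`lvstiff` implements this inverse problem end to end: the mechanistic
filling model, constrained maximum-likelihood estimation by parallel
tempering, uncertainty quantification, residual diagnostics, automated
failure flagging, beat detection from sampled waveforms, and a synthetic
data generator that emulates AF and SR beat statistics together with the
documented failure modes.

## The forward model

Diastolic filling follows the ODE $dV/dt = k_3 + k_1 e^{\beta V}$, where
$k_1 = -(P_{LV0}/R_{valve})\,e^{-\beta V_{ED0}} < 0$ and
$k_3 = (P_{LV0} + P_{cvp})/R_{valve} > 0$ combine the underlying
physiology (valve resistance, filling pressure, P-V scale constants; see
`params_from_physiology()`).  Its closed-form solution gives end-diastolic
volume as a function of the filling interval $t$:

$$V_{ED}(t) = k_3 (t + C) - \frac{1}{\beta}
  \ln\!\left(1 - \frac{k_1}{k_3} e^{\beta k_3 (t + C)}\right),$$

a strictly increasing, concave curve that saturates at the plateau
$V_\infty = \ln(k_3/|k_1|)/\beta$ (`filling_asymptote()`).  The time shift
$C$ aligns the model's filling clock with measured RR intervals: the
package pairs each beat's *full* preceding RR interval with the following
pulse pressure, and $C$ absorbs the (unobserved) systolic duration offset.

A linear aortic observation model converts volume to pulse pressure.  The
**simple model** (SM, 6 parameters) is
$PP_i = V_{ED}(t_i)/\alpha + \delta$ with aortic compliance $\alpha$
(ml/mmHg) and zero-offset $\delta$ (mmHg).  The **expanded model** (EM,
7 parameters) adds a weight $k_4$ on the prepreceding RR interval,
$PP_i = V_{ED}(t_i + k_4 t_{i-1})/\alpha + \delta$, absorbing beat-to-beat
inotropic carry-over that otherwise leaves a systematic residual trend
against the prepreceding interval.

Because the physical $k_1$ is negative while the optimizer works on an
all-positive box, the package estimates its magnitude `k1_mag` and fixes
the sign internally.

### Numerical evaluation

The closed form is evaluated as
$V = k_3(t+C) - \mathrm{softplus}\!\big(\ln(k_{1m}/k_3) + \beta k_3 (t+C)\big)/\beta$
with $\mathrm{softplus}(w) = \log(1+e^w)$ computed via `log1p` below
$w = 33$ and as $w$ itself above.  This single expression is exact, cannot
overflow anywhere inside the constraint box (it reduces analytically to
the large-argument asymptotic form), and degrades gracefully in the two
delicate corners: vanishing `k1_mag` (linear filling $V \to k_3(t+C)$) and
near-zero $\beta$ (the softplus argument becomes the small quantity whose
ratio with $\beta$ reproduces the series limit).  Non-finite intermediate
values — reachable only for extreme sampler proposals — are mapped to a
log-likelihood of $-\infty$, i.e. certain rejection.  Tests verify the
closed form against independent Runge-Kutta integration of the filling
ODE (`deSolve`) to below $10^{-6}$ ml across 100 random parameter vectors.

## Estimation

The likelihood assumes independent Gaussian pulse-pressure measurement
error with SD $\sigma = 12$ mmHg (configurable).  The package uses the
*unnormalized* form $\log L = -\mathrm{SSE}/(2\sigma^2)$: the additive
Gaussian constant is omitted so that a perfect fit scores 0 and the
initialization threshold of $-5208$ corresponds exactly to an SSE of
1,500,000 mmHg$^2$ at $\sigma = 12$.

Local optimizers fail on this surface, so estimation is by **parallel
tempering** used as a global optimizer (`fit_stiffness()`):

* all parameters constrained to the open box $]0, 400[$;
* chains initialized independently at random points drawn from wide
  intervals — `k1_mag`, `beta`, `C` as $e^u$, $u \sim U(-40, 4)$; `k3`
  $\sim U(120, 400)$; `alpha` $\sim U(0, 5)$; `delta` $\sim U(20, 80)$ —
  and redrawn until the log-likelihood exceeds $-5208$, which places every
  chain on the support of the likelihood;
* an exponential temperature ladder $T_k = 6^k$ over 24 chains (defaults);
* a diagonal Gaussian random-walk proposal.  `k1_mag`, `beta` and `C` are
  proposed in log space (default SD 0.05 log units, matching their
  log-space initialization); linear-scale parameters default to 1% of
  their initialization interval.  The published analysis this design
  follows used an empirically tuned, unpublished proposal covariance, so
  these defaults are deliberately conservative and fully user-tunable
  (`pt_config(proposal_scales = ...)`);
* adjacent-pair replica exchange on alternating even/odd pairs every 10
  sweeps (the standard acceptance ratio; the interval is configurable);
* the reported estimate is the **best likelihood vector** (BLV): the
  maximum *untempered* log-likelihood over every evaluated point,
  accepted or not, across all chains.

Design choices worth making explicit, since the estimation setup leaves
them open:

* **Sweeps, not per-chain updates.**  A "sample" is one sweep updating all
  chains; the full-scale reference configuration is $4\times10^7$ sweeps
  on 24 chains.  The package default (`n_sweeps = 2e5`) is a practical
  working budget; the recovery studies in the test suite use 8 chains and
  $2\times10^5$ sweeps.
* **Detailed balance on log-scale coordinates.**  Random-walking
  $u = \log p$ changes the reference measure, so the Metropolis ratio
  includes the change-of-variables term $e^{\sum \Delta u}$; the cold
  chain then samples exactly $\exp(\log L)\,dp$, which the test suite
  verifies against an analytic Gaussian target.  The recorded BLV is
  unaffected by the sampling measure.
* **Reproducibility.**  A single master seed drives initialization (R's
  RNG) and per-chain internal streams (derived deterministically from the
  seed and the chain index), so results are bit-reproducible and the cold
  chain's stream does not depend on the chain count.  Fixing a parameter
  (`fixed =`) suppresses its proposal draws entirely, so an expanded-model
  run with $k_4$ pinned at its lower bound consumes the identical random
  stream as a simple-model run — and reproduces its estimates exactly, a
  nesting property the tests exploit.
* **Initialization failure is a signal.**  If no candidate exceeds the
  threshold within `init_max_draws`, the data cannot support the model at
  the assumed noise level (the error message says so); this is the
  expected behaviour for pathologically incompatible inputs rather than a
  numerical defect.

### Identifiability: what can and cannot be learned

The model carries two *exact* degeneracies.  A shift along
$C \to C - \Delta$, $k_{1m} \to k_{1m} e^{\beta k_3 \Delta}$,
$\delta \to \delta + k_3\Delta/\alpha$ leaves every prediction unchanged,
as does the scaling $(k_{1m}, k_3, \alpha) \to c\,(k_{1m}, k_3, \alpha)$,
$\beta \to \beta/c$.  The likelihood maximum is therefore a ridge, not a
point: $C$ routinely collapses towards zero (triggering the near-boundary
warning, which is informative rather than alarming), and the recovered
$\beta$ is constrained only as well as the box, the initialization
distribution and the finite sampler budget pin down the scaling direction.
This is the structural reason the problem is ill-posed, why the Hessian at
the BLV is singular, and why recovered stiffness values scatter more than
their formal error estimates suggest.  The recovery study in the test
suite quantifies the practical consequence: over 10 synthetic AF datasets
(800 beats, $\sigma = 12$, true $\beta = 0.04$) the *median* relative
error of the recovered $\beta$ stays within 30% at the scaled-down
sampler budget, with individual replicates drifting further along the
ridge.

## Uncertainty and diagnostics

`hessian_covariance()` differentiates the log-likelihood numerically
(`numDeriv`) at the BLV and converts the generally indefinite Hessian to a
covariance by eigendecomposing $-H$, flooring eigenvalues at
$\varepsilon \lambda_{max}$ (default $\varepsilon = 10^{-10}$), and
pseudo-inverting — a generalized-inverse reading of the standard
regularization advice for non-invertible observed information.  Floored
directions are reported as *weakly identified*, and parameters loading
mainly on them are flagged in `tidy()`.  Because of the exact degeneracies
above, error estimates for the full model are honest about, not a cure
for, ill-posedness; on well-posed reduced problems (degenerate directions
held fixed) the $\pm 1$SE interval achieves near-nominal 68% coverage in
the test suite's Monte-Carlo check.

Goodness of fit is the Pearson-$R^2$ **fraction of variation explained**
(FVE) between observed and predicted pulse pressures — invariant under
affine miscalibration of the prediction scale, which is exactly the
freedom the degeneracies leave.  `residual_diagnostics()` summarizes
residual trends against filling interval, prepreceding interval and
observed pulse pressure; a positive prepreceding-interval trend under the
SM that vanishes under the EM is the signature motivating the expanded
model.

`classify_inference_failure()` applies three advisory flags:

* `LOW_FVE` (default threshold 0.15): the model explains almost nothing,
  typically because the record violates stationarity (e.g. a drifting
  pulse-pressure baseline) or carries SR-like variability;
* `IMPLAUSIBLE_BETA` (defaults 0.01-0.2 ml$^{-1}$): the estimate falls an
  order of magnitude below the physiological range (reported invasive
  values centre around 0.044 ml$^{-1}$) or unreasonably above it;
* `DEGENERATE_LINEAR` (default margin 0.02): a straight-line fit of pulse
  pressure on filling time explains essentially as much variation as the
  nonlinear model, meaning the record never reaches the filling plateau
  and the stiffness is not identified.

The thresholds are defaults, not constants of nature; both the
thresholding route and the reduced-linear-model comparison are
implemented because neither alone captures every failure.

## The synthetic data generator

`simulate_beats()` is the package's test bed and negative control, built
to reproduce the statistical structure the inference assumes:

* **RR intervals**: independent draws from a moment-matched gamma
  distribution with a 0.25 s floor.  AF defaults: mean 0.68 s, SD 0.12 s;
  SR defaults: mean 0.76 s, SD 0.024 s — the beat statistics of the two
  rhythm groups.  The gamma family and the independence of successive
  intervals are modelling choices of the generator (only means and SDs
  are anchored); real AF series show serial structure the generator does
  not emulate, so passing recovery tests demonstrate identifiability
  under the model's own assumptions, not robustness to every property of
  real recordings.
* **Pulse pressures**: exact forward model at a generating truth plus
  i.i.d. Gaussian noise, default $\sigma = 12$ mmHg (the same value the
  likelihood assumes).
* **The default truth** is $\beta = 0.04$ ml$^{-1}$ (mid physiological
  range), $\alpha = 1.5$ ml/mmHg (inside the reported 0.8-2.2 ml/mmHg
  range), $\delta = 40$ mmHg, and $k_3 = 340$ ml/s, $k_{1m} = 0.025$
  ml/s, $C = 0.02$ s.  The last three are free knobs of the generator;
  they were calibrated once, before any recovery experiment, so that the
  synthetic records reproduce the descriptive statistics the method is
  known to operate under: the pulse-pressure/filling-time scatter shows
  both the rising limb and the plateau (slope at the 90th RRI percentile
  below 20% of the slope at the 10th), the noiseless curve explains
  roughly 55% of total variance at $\sigma = 12$ (inside the reported AF
  goodness-of-fit band), the straight-line fit trails the nonlinear model
  by a clear margin, and the identical truth under SR interval statistics
  collapses to FVE $\approx$ 0.01.  The resulting synthetic pulse-pressure
  *level* (~180 mmHg mean) is higher than typical clinical pulse
  pressures — with $\alpha$ and $\delta$ anchored to physiological values,
  the variance needed for identifiability forces a high plateau; the
  variability structure, not the absolute level, is what the inference
  consumes.  The expanded-model truth adds $k_4 = 0.25$, a moderate
  carry-over that produces a detectable prepreceding-interval residual
  trend under the SM.
* **Failure modes** mirror the two documented real-data failures:
  `nonstationary_drift` adds a monotone ramp (default 130 mmHg across the
  record — strong nonstationarity chosen inside the window where the
  initialization threshold remains attainable yet the fitted FVE falls
  clearly below the 0.15 flag); `linear_regime` regenerates pulse
  pressures from `linear_regime_truth()`, whose curve stays far from its
  plateau over observed intervals, so the fit degenerates to an
  effectively linear model with an implausibly small stiffness estimate.
* **Waveform rendering** (`simulate_waveforms()`) draws a QRS-plus-T-wave
  template at every R time and an arterial pulse of the requested
  amplitude per beat (360 Hz default, optional noise and 8-bit
  quantization emulating the reference corpus format), providing ground
  truth for the detection pipeline.

## Beat detection

`detect_r_peaks()` is a compact single-lead detector (5-20 Hz band-pass
via `signal::butter`/`filtfilt`, squared first difference, block-wise
98th-percentile adaptive threshold at fraction 0.3, 250 ms refractory
period, refinement to the raw-signal maximum).  It is a simplified
reimplementation in the spirit of standard QRS detectors, not a
bit-compatible port of any published one; all tuning constants are
arguments.  `detect_pulse_pressures()` takes, per beat window, the
systolic maximum minus the preceding diastolic minimum and drops beats
outside 5-250 mmHg.  `pair_beats()` pairs each RR interval with the pulse
pressure of the beat that terminates it and *never splices across dropped
beats*: a dropped beat invalidates both intervals it borders, because a
spliced interval would corrupt exactly the filling-time/pulse-pressure
relation the model fits.  `select_stationary_window()` is the automated
surrogate for manual low-noise interval selection (the manual step of the
original workflow is not reproducible): it slides a fixed-length window
scored by implausible-beat fraction plus absolute pulse-pressure trend,
with ties broken towards the earliest window.

## Problem sizes used in the shipped studies

The package's own studies (test suite and `scripts/acceptance.R`) run at
a deliberately scaled-down sampler budget — 8 chains, $2\times10^5$
sweeps for recovery fits; smaller for negative controls, whose FVE
stabilizes much earlier than the parameter estimates — with 800-beat
records matching the canonical input length, 10 replicates per condition
in the tests and 5 in the acceptance script, and 300-beat records for the
waveform round trip.  These sizes were chosen so a full run remains an
interactive-scale computation; production estimates should raise
`n_sweeps` (the reference configuration is $4\times10^7$ sweeps on 24
chains).

## Known limitations

* $\beta$ is identified only up to the box/initialization-limited scaling
  ridge described above; interpret single-record estimates together with
  their flags, FVE and the residual panels.
* The generator does not model serial RRI correlation, respiratory or
  baroreflex pulse-pressure modulation, ectopy or pacemaker spikes.
* The waveform module targets clean-to-moderately-noisy signals; it is
  not an arrhythmia-robust clinical detector.
* Group-level statistics (e.g. rank-sum comparisons between rhythm
  groups) are delegated to standard routines (`stats::wilcox.test`) in
  the reporting layer; the package adds no inferential machinery there.
* Full Bayesian posterior quantification is out of scope; the sampler is
  used as a global optimizer, and the covariance is a local, regularized
  approximation at the BLV.
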