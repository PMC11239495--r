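---
title: "Methods: temporal glucose tracking, encoding models and cell classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal glucose tracking, encoding models and cell classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotrack)
```

## The scientific question

A sensor can relay the current value of its input (proportional
tracking) or its rate of change (derivative tracking). For blood
glucose sensed by hypothalamic neurons these two hypotheses make
opposite temporal predictions: a proportional (inhibitory) tracker is
maximally suppressed *after* the glucose peak, with a monotonic
activity–glucose relationship; a derivative tracker is maximally
suppressed during the *rise*, minutes before the peak, and its
activity–glucose plot opens into a hysteresis loop. This package
implements the analyses that separate the two regimes — and a synthetic
data generator that produces multichannel sessions with known
ground-truth coupling, so each analysis can be validated by parameter
recovery rather than by eyeballing.

## The synthetic session generator

`simulate_session()` produces, from a single `sim_config()` seed, a
1-Hz master-grid session (glucose, population activity, running, VO2,
VCO2, body temperature), a 5-Hz single-cell trace matrix with
ground-truth labels, and a raw bleached photometry trace.

**Glucose transient.** The study it emulates *measures* rather than
models glucose, so the generator needs only the simplest shape with
distinct rising and falling phases: bi-exponential absorption/clearance
kinetics,

$$G(t) = b + A\,k\left(e^{-(t-t_0)/\tau_c} - e^{-(t-t_0)/\tau_a}\right),$$

with $k$ fixed so the noiseless peak is exactly $A$ above baseline $b$.
Defaults ($b = 7.3$ mM, $A = 5.5$ mM, $\tau_a = 6$ min IP / 9 min IG,
$\tau_c = 30$ min) put the peak ~12 min post-infusion and keep the
realized baseline, peak and maximal rate of change inside the
physiological ranges reported for glucose-infused mice (baseline
3.5–11.1 mM, peak 11.1–34.9 mM, max rate 0.12–1.45 mM/min); the
generator warns post hoc when a configuration leaves those ranges.
Intragastric delivery differs from intraperitoneal only by slower
absorption, since the activity–glucose relationship is reported to be
route-independent. Measurement noise is white noise low-pass filtered
with a 30-s time constant and rescaled to `noise_sd` (default 0.1 mM):
an electrochemical telemetry sensor yields slowly varying errors, and
white 1-Hz noise would make the measured derivative meaningless.

**Locomotion.** Bout start times are a Poisson process (default 1
bout/min); each bout lasts a minimum 1 s plus an exponential excess
(mean 2 s) at a lognormal speed above the 18 cm/s detection threshold.
Between bouts the speed is exactly zero, as on a stationary wheel.

**Cells.** Each cell's 5-Hz trace is

`slow_gain * class_waveform + running_gain * indicator_filtered_speed +
bleach_trend + white noise`,

where the class waveform is the z-scored 1.5-min-smoothed session
glucose (class G), its re-smoothed derivative (dG), or their negatives
(iG, idG); `N/A` cells have zero glucose coupling. Locomotor input is
filtered by a single-exponential calcium-indicator kernel
(`indicator_tau` = 1.5 s, a slow indicator); the glucose waveform is
already slow and gets no extra filtering. Default class prevalences are
the reported single-cell proportions (25% G, 11% dG, 33% iG, 31% idG,
2% N/A, scaled to sum to 1); default `slow_gain` is |N(3, 0.5)| z-units
against unit noise. A triple-exponential bleach trend (shared shape,
per-cell amplitude ~|N(0, 0.2)| z) is added to cell traces, and the
same triple exponential multiplies the raw population photometry trace,
so the detrending module faces exactly the structure it assumes.

**Metabolics.** No quantitative gas-exchange model is available to
emulate, so couplings are placeholders tuned only for direction: VO2
rises with (lagged) running, RER = VCO2/VO2 drifts upward after the
glucose transient, temperature rises slowly post-infusion, all with
small multiplicative-scale noise and strictly positive values.

**What the generator does not emulate.** Pharmacokinetic realism beyond
the printed ranges; counter-regulatory under/overshoot; movement
artifacts in the photometry channel (no artifact-regression procedure
is implemented, and the control-channel machinery is omitted);
glucose-driven suppression of locomotion (running is generated
independently of glucose, deliberately, so encoding-model recovery
tests have orthogonal ground truth). Passing recovery tests therefore
demonstrates correctness of the analysis code under the stated
generative model, not robustness to every pathology of real recordings.

## Fluorescence detrending

`preprocess_photometry()` chains four steps: (1) the lower convex hull
of the trace (monotone chain on (t, y); collinear points retained, with
a relative tolerance of 1e-12 on the cross product so exactly-linear
segments survive floating-point rounding) — the hull is the local-minima
envelope that tracks photobleaching because activity transients are
upward deflections; (2) a least-squares non-negative triple exponential
with offset through the hull points, via variable projection (for fixed
time constants the amplitudes are a non-negative least-squares solve;
the time constants are multi-started on a fixed 27-point log-spaced grid
over 0.01, 0.1 and 1 times the trace duration, and the best four starts
are polished by Nelder–Mead on log-tau to a relative tolerance of
1e-14). The multi-start list is deterministic — no RNG anywhere in the
fit. With fewer than 8 support points the model degrades to a double
(≥ 6) or single (≥ 4 points) exponential, recorded in `n_components`;
(3) `(F − fit)/fit`; (4) z-scoring against the 20-min pre-infusion
window. The hull is computed on raw values (whether the original
procedure lightly smoothed first is unstated; raw is the stricter
choice). Inhibitory deflections that dip below the bleach envelope
violate the hull assumption mildly; with the default population mixture
the bias is small but it is a known limitation for strongly inhibited
populations.

## Temporal analyses: conventions and numerical choices

* **Derivatives** are central differences (one-sided at edges) scaled to
  per-minute units. Derivatives of measured glucose are taken after
  1.5-min moving-mean smoothing; differentiation amplifies noise, and
  the mM/min signal scale would otherwise drown.
* **Lagged cross-correlation** computes per-lag Pearson r on the
  overlapping segments (the normalization convention was open; per-lag
  Pearson keeps every lag on the same [-1, 1] scale). Positive lag
  means the second signal is delayed. The peak is the extremum of |r|.
  For derivative-coupled activity the diagnostic feature is that the
  most negative r sits at a negative lag — activity anticipates
  glucose. On a full session with slow clearance the positive branch of
  the correlogram can dominate |r|, so anticipated inhibition should be
  read from the negative extremum, not only the global peak.
* **Transient boundaries**: first crossing of baseline mean + 3 sd
  sustained 60 s, ending at the first sustained return (else the last
  sample). The boundary rule was unstated; 3 sd with 60-s persistence
  is robust to telemetry noise.
* **Hysteresis loops** take exactly 50 points equally spaced *in time*
  across the transient (equal spacing in glucose is ill-defined on a
  non-monotonic transient), interpolated linearly, with the signed
  shoelace area of the ordered polygon. Proportional coupling gives
  area 0 (degenerate line); derivative-coupled inhibition traverses
  counterclockwise, giving positive area. The area is invariant to
  offsets on either axis and flips sign under time reversal.
* **Bouts**: super-threshold runs; gaps of at most 2 s are merged
  first, then bouts shorter than 1 s are discarded — merging first
  makes the two printed rules compose deterministically. A zero bout
  rate is a valid (silent) generator configuration; a negative one is
  an error.

## The encoding model

`build_predictors()` produces exactly ten columns — running, glucose,
temperature, VO2, VCO2 and their derivatives, in that fixed order —
each 1-min bin-averaged, Savitzky–Golay filtered (first order,
five-sample window), differentiated *after* filtering (order of
operations was open; filtering first keeps the derivative columns from
being noise-dominated), and z-scored. A constant column is an error
naming the column (constancy is judged at a 1e-10 relative tolerance so
filtered constants count as constant).

`bootstrap_contributions()` tiles the rows into contiguous chunks of a
quarter of the experiment duration at a random phase — chunking
preserves temporal autocorrelation within folds, which is the evident
purpose of chunked resampling — then randomly assigns chunks to
training until at least 70% of samples are covered, leaving at least
one chunk for validation. Per iteration the full OLS model and ten
leave-one-predictor-out partial models are fit on the training rows;
each predictor's validation ΔR² is clipped at zero; medians across
iterations (default 2000; the pipeline default is 200, which is
sufficient for stable medians at these problem sizes) are normalized to
percent of their sum. If every median is zero the contributions are
reported as all zero with a flag rather than dividing. Out-of-sample
R² can be strongly negative on short sessions (about 60 one-minute
rows against 11 parameters), which inflates the *unclipped* ΔR² scale;
the normalized percentages are unaffected, and
`mode = "leave_one_session_out"` provides the non-bootstrap
confirmation route. Whether z-scoring should precede or follow chunk
selection was open; columns are z-scored once, globally, before
resampling, and that choice is recorded in the fit's `spec`.

## Single-cell classification

Templates come from a *held-out* session (in the original design, from
animals excluded from classification; the pipeline preserves the
holdout rule by building templates from a separate simulated session,
seed-offset from the analysis session, with noiseless glucose).
Construction: 1.5-min moving mean → G; differentiate and re-smooth with
the same window → dG; negate → iG, idG; crop to the first 20 min
post-infusion. Waveforms are z-scored over that window (a constant
waveform falls back to centred zeros): Pearson classification is
scale-invariant, and normalized templates make the population
reconstruction Σ prevalence × amplitude × template well-posed —
unnormalized, the mM-scale G template would swamp the mM/min-scale dG
template. Note the re-smoothed derivative of an asymmetric fast-rise/
slow-decay transient crosses zero a few minutes *after* the smoothed
peak; this is a property of the smoothing, not an error.

Each cell is aligned to the template grid by linear interpolation and
assigned to the template with maximum Pearson r, unless no template
reaches p < 0.001/4 (two-sided t-approximation; Bonferroni over the
four templates), in which case it is `N/A`. Exact ties in r break in
the fixed order G → dG → iG → idG (probability zero in practice;
determinism in tests). The t-approximation ignores autocorrelation and
therefore overstates significance — as it would have in the original —
so the `N/A` rate is conservative-to-liberal depending on trace
autocorrelation; this is documented rather than corrected because the
threshold rule is part of the procedure under study.

Running coupling uses whole-session 5-Hz Spearman correlation with the
stated thresholds (p < 0.05 and |ρ| > 0.01). At ~18,000 autocorrelated
samples these thresholds flag many truly uncoupled cells (about half,
varying strongly between sessions); the generator's running mixture
(28% positive, 14% negative, 58% uncoupled) was chosen so genuinely
coupled cells remain a meaningful minority for recovery tests, and the
observed multiplexed fraction under the procedure comes out
substantially above the generative coupling rate. Treat per-session
multiplexing figures as describing the procedure's output, not the
generative truth.

## ROI matching

Joins require all five criteria: neighbouring planes (index distance
≤ 1), > 5% overlap of radius-3-dilated masks, best-lag Pearson > 0.90
within ±2 s (strict), and recurrence in ≥ 2 sessions. The overlap
denominator is the *smaller* dilated mask — lenient to cells partially
captured in a neighbouring plane, which is the cross-plane use case —
with union normalization available by flag. Dilation applies to the
filled mask (with manually drawn outlines, filled contour and mask
coincide). Joined pairs merge by graph connected components; merged
traces are member means.

## Problem sizes and determinism

The shipped tests and the acceptance script run sessions of 3600 s at
1 Hz (5 Hz cells), 40–400 cells, 50–200 bootstrap iterations, and
1,000-instance oracle sweeps; these sizes give stable statistics for
every recovery check while keeping a full run in minutes on one core.
Every stochastic stage takes an explicit seed and is a pure function of
(configuration, seed); the pipeline report hashes identically across
reruns.

## Known limitations

* The generator's couplings are linear and additive; no saturation,
  adaptation, or state-dependence.
* Metabolic couplings are directional placeholders; do not interpret
  their fitted contributions quantitatively.
* The detrender assumes activity deflects upward from the bleach
  envelope; strongly inhibited populations bias the hull fit.
* Correlation p-values (classification and running) ignore temporal
  autocorrelation; a block-permutation alternative would deflate them
  but would depart from the procedure being reimplemented.
* Multi-session machinery is limited to same-condition averaging before
  classification and leave-one-session-out encoding validation; no
  hierarchical (per-animal) modelling.
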