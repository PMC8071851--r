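---
title: "Methods: the breathsync entrainment model and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the breathsync entrainment model and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`breathsync` implements a closed-loop breathing-sonification system offline:
keypress onsets in, phase-coupled audio control signals out, with a virtual
breather closing the loop for validation. This vignette is the package's own
account of the model, the parameters that matter, the numerical choices, and
what the synthetic experiments do and do not demonstrate.

## Breath tracking

The only behavioural input is a stream of timestamped inhale/exhale
keypresses. The tracker (`breath_tracker()`, `ingest_onset()`, `phase_at()`)
maintains:

* **Phase.** Snapped to 0° at an inhale press and to `exhale_phase`
  (default **240°**) at an exhale press; linearly interpolated at slope
  360°/period between presses; free-running and wrapping if the next press
  is late. There is a genuine tension in this convention: with the target
  1:2 inhale:exhale geometry a continuous phase would put the exhale onset
  at 120°, while the system's stated convention is 240°. We keep 240° as the
  default — the convention is what it is, and "fixing" it silently would
  change the controller's behaviour — but the constant is configurable, and
  a regression test pins down the dichotomy: with 240° the phase jumps at
  exhale presses of a perfect 1:2 breather; with 120° it is continuous.

* **Tempo.** The literal tempo statistic is the median of the last five
  inter-onset intervals, which mixes inhale→exhale and exhale→inhale half
  cycles and therefore depends on the breathing ratio. For the full-cycle
  period the tracker prefers the median of recent inhale→inhale intervals
  (ratio-independent), falling back to twice the mixed-interval median early
  in a trial, and to `default_period` (5 s ≈ 12 breaths/min, a typical
  resting rate) before any history exists.

* **Debouncing.** Keyboards double-fire; presses within `debounce`
  (default 0.2 s, shorter than any plausible half cycle) of the previous
  accepted press are rejected, distinctly from non-monotone timestamps.

## Entrainment and the gated delay

The stimulus oscillator follows a two-channel Kuramoto update
(`kuramoto_step()`): explicit Euler at `dt = 0.01 s`,

* phase: `dθ/dt = ω + K sin(θ_target − θ)`, `K = 0.5 s⁻¹`;
* frequency: `dω/dt = η (ω_breath − ω)`, `η = 0.2 s⁻¹`, where `ω_breath`
  is the tracker's 1/period.

Neither `K`, `dt` nor the frequency-adaptation rule is dictated by the
original system's description, which specifies only "a Kuramoto
implementation" with fluent tempo adaptation; both channels are therefore
exposed in `coupling_config()` with independent gains, and tempo-only
alignment simply sets the phase channel off. The two-oscillator behaviour is
validated against the analytic Adler steady state: for detuning Δω the locked
offset satisfies `sin(ψ*) = 2πΔω/K`, and locking requires `K/2π ≥ |Δω|`; the
test suite checks both the offset (simulated vs closed form) and the
bounded/drifting dichotomy across the threshold.

Synchronization is the circular mean resultant length `R` of the
breather−stimulus phase difference over a trailing window
(`sync_window = 15 s`, a few breath cycles — long enough to average within-
cycle snap artefacts, short enough to track mode changes). In the final trial
phase the stimulus target *trails* the breather by the gated delay
`δ = R · delay_max` with `delay_max = 50°`. Two sign conventions are possible
(“delay” as lead or lag); we implement lag, because only a lagging stimulus
pulls an entrained breather toward longer periods, which is the therapeutic
goal (slower breathing). The gate direction (δ grows with R) encodes the
stated rationale that the delay should act only once entrainment is
established; an inverse gate is available in `coupling_config()`.

Note that with the 240° exhale snap, the tracked breathing phase of even a
perfectly regular breather is discontinuous, so `R` saturates well below 1
in a healthy closed loop (typically 0.4–0.6 here). The delay therefore
realises 20–30° of its 50° bound in practice.

## Trial schedule

`build_schedule()` produces the standard 8-minute timeline — 60 s silence,
60 s tempo-aligned, 180 s phase- and tempo-aligned, 180 s phase-delayed
(480 s total, 420 s with audio). Segments are half-open `[start, end)` with
boundaries computed once as cumulative sums, so lookups are bit-reproducible
and each boundary instant belongs to the later segment.

## Stimulus synthesis

All three families are driven by the stimulus oscillator's phase through a
common control layer (`breath_envelope()`, control rate 100 Hz):

* The **envelope** splits the cycle at `inhale_end_phase` = **120°**, so a
  uniformly advancing phase spends exactly 1/3 of the cycle in the inhale
  region and 2/3 in the exhale region — the 1:2 target ratio. This split is
  deliberately decoupled from the tracker's 240° exhale snap: the snap is a
  tracking convention, the split is stimulus geometry, and only one of them
  can honour the 1:2 ratio. Amplitude and low-pass cutoff are raised
  cosines within each region, with minima (`amp_trough = 0.05`) exactly at
  the onsets ("smooth ramps toward the onset") and one peak per region;
  cutoff spans 200 Hz–4 kHz, a plausible breath-sound brightness range.
* **Noise**: pink noise (Kellett filter cascade; −10 dB/decade verified by a
  Welch-periodogram regression over 20 Hz–5 kHz on a 2²⁰-sample render)
  through a time-varying one-pole low-pass tracking the cutoff trajectory,
  then amplitude modulation. At a cutoff at or above Nyquist the one-pole
  coefficient clamps to 1 (exact passthrough), which gives the renderer a
  well-defined limit case.
* **Nature**: eight wind-leaf sources at fixed azimuths 0°,45°,…,315° on a
  circle whose radius follows the breath phase (`nature_radius()`, one
  expansion per cycle, default widest on inhale — the direction is not
  dictated anywhere, so it is configurable). Full ambisonic/HRTF rendering
  is out of scope; radius maps to equal-power stereo panning and width,
  documented as an approximation. The stems are procedural (filtered noise,
  decaying sines, chirps) — synthetic stand-ins so no sample downloads are
  needed; file-based stems can be substituted upstream of the mixer.
* **Music**: a descending arpeggio (default C-major from C6) into a ii–V–I
  progression (Dm7–G7–Cmaj7; key and voicing are configuration, since only
  the "2-5-1" structure is specified) of a marimba-like additive tone, with
  total notated duration 2/3 of the period — the phrase spans an exhale
  twice the inhale's length. An inhale arriving before the phrase ends
  triggers a 150 ms linear fade of the phrase stem only.

Renders are deterministic given (trajectory, config, seed) and peak-limited
to 0.99; WAV output is plain 16/24-bit PCM written byte-stably.

## The virtual breather

`closed_loop_session()` couples a simulated participant to the full system.
The breather commits to its next onset at each onset (an onset-level model:
humans commit to a breath, and it keeps the update testable): the next onset
time is a convex blend, with weight `entrain_gain`, of intrinsic timing
(from `intrinsic_rate`, `intrinsic_ratio`) and the moment the stimulus phase
next reaches that onset's landmark (0° inhale, 120° exhale), plus Gaussian
jitter truncated at ±3 SD so intervals stay positive. The ratio drifts
toward the stimulus geometry's 2.0 by `ratio_gain` per cycle while audio
plays.

Defaults are the study conditions the package simulates: 8 breaths/min
intrinsic rate (calm but above the ~6 breaths/min resonance goal, leaving
headroom for steering), ratio 1.5 (below the 2.0 target), jitter 0.15 s
(roughly the motor/decision noise of a deliberate keypress), entrainment
gain 0.5 and ratio gain 0.1 (moderate, neither deaf nor captured). With
these conditions a session steadies near
`T = T_int (1−g) / (1 − g(1 + δ/360))` — a bounded slowdown of roughly
0.5–1 breath/min, which is what the direction-of-effect experiments measure.

What the breather does **not** emulate: respiratory mechanics, chemoreflex
dynamics, heart-rate coupling, attention lapses, or any aesthetic response
differing between stimulus families. Passing closed-loop tests therefore
demonstrates that the *controller* behaves as designed against a plausible
entraining agent — not that human breathing will follow it, and not any
difference between noise, nature and music conditions, which in humans is
mediated by perception the simulation has no model of.

## Analysis pipeline

For each trial (`trial_series()`):

1. **Raw streams.** Per-keypress IOTs; per-cycle exhale:inhale ratios
   (inhale→exhale = inhale duration, exhale→next-inhale = exhale duration).
2. **Outlier rule.** A value deviating from the mean of the previous window
   (trailing 5 accepted values — one 6-keypress window) by more than 5 SD is
   an erroneous press and is discarded; the first window is never discarded.
   The rule is applied to the *raw* streams: applied to windowed medians it
   degenerates, because medians are locally constant and their window SD
   collapses to zero. A flagged IOT removes the press that ends it. If the
   previous window is exactly constant (SD < 1e-9) any deviation above that
   guard is discarded — the natural limit of the rule. The skipped
   percentage is reported per trial (`skipped_fraction()`); clean synthetic
   logs skip exactly 0.
3. **Windowing.** Rates use a sliding 6-keypress window and are computed
   from full inhale→inhale cycles within it (`60/median`, in breaths/min,
   ratio-independent; the mixed-interval median is reserved for the live
   tempo tracker). Ratios use a sliding median of 5 per-cycle values.
   Window timestamps are median event times; only full windows are emitted.
4. **Grid.** Linear interpolation onto t = 0, 10, …, 470 s (0.1 Hz, 48
   samples per 480 s trial), holding the nearest value beyond the ends.
5. **Growth model.** Natural-log-transformed values regressed on a
   fourth-order orthogonal polynomial: `orthogonal_basis()` is the QR
   orthonormalisation of the grid-index Vandermonde matrix (Gram identity
   holds to 1e-10; signs fixed so each column ends positive, making the
   linear column increasing). Inside `fit_growth()` the degree-0 column is
   rescaled to a plain intercept so that a constant series `c` yields
   intercept `log c` — the familiar intercept scale — while the time terms
   stay orthonormal. A `condition` column adds condition-by-term
   interactions (treatment coding). Standard errors come from ordinary
   least squares and are Monte-Carlo-verified against the analytic
   `σ²(XᵀX)⁻¹`. Participant-level random effects are deliberately not
   re-implemented: `tidy_growth_table()` emits the long-format table (values
   plus basis columns) that any external mixed-model fitter consumes
   directly.

Non-positive values abort the log transform with the offending index; both
rates and ratios are positive by construction, so this guards only corrupt
input.

## Problem sizes and stochastic checks

The validation experiments use sizes chosen to make their statistics sharp:
2²⁰ samples for the spectral slope (±1 dB band), 10 000 samples for the
uniform-phase R anchor (3/√N bound), 600–2000 s of dt = 0.01 integration for
the Adler comparisons, 200 replicates for the SE Monte Carlo, and 20 seeds
for the closed-loop experiments (intrinsic-rate recovery within twice the
across-seed standard error; final-minute-vs-first-minute rate decrease in at
least 16 of 20 seeds). The decrease criterion is genuinely stochastic: the
steering effect (≈0.2–0.4 breaths/min) is of the same order as the
jitter-induced variability of one-minute rate means, so individual seed sets
range from ~15/20 to ~19/20 decreases. The fixed-seed suite documents one
such draw; the acceptance script reports the fraction for whatever seed it
is given.

## Known limitations

* The 240° exhale convention caps achievable R (see above); the system
  inherits this by design.
* The one-pole low-pass is 6 dB/octave — gentler than a studio filter; it
  was chosen for an exact passthrough limit and unconditional stability
  under fast cutoff modulation.
* The nature scene's stereo width is a perceptual sketch of the original
  circular ambisonic layout, not a binaural equivalent.
* The virtual breather's entrainment is phenomenological (a timing blend),
  not a physiological model; parameter-recovery results quantify pipeline
  correctness, not human efficacy.
* Growth-curve inference here is per-trial/condition OLS; hierarchical
  (participant-level) inference must be done externally on the exported
  long table.
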