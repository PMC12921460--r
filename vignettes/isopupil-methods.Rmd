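---
title: "Methods: separating the light reflex from cognitive load in iso-luminant pupillometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating the light reflex from cognitive load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopupil)
```

## The measurement problem

Pupil diameter mixes two autonomic signals. The pupillary light reflex
(PLR) is a fast brainstem loop — pretectal olivary nucleus to
Edinger-Westphal nucleus — that constricts the pupil within a few hundred
milliseconds of a luminance increase. The task-evoked pupillary response
(TEPR) is a slow dilation driven by the locus coeruleus-norepinephrine
system that builds over one to a few seconds of cognitive effort and is an
order of magnitude smaller. In a virtual-reality headset, scene luminance
ordinarily varies continuously, so the reflex swamps the cognitive signal.

The paradigm this package analyzes removes the confound at the source. A
session has three phases on one timeline (`build_timeline()`):

1. **PLR validation, 60 s** — the whole field alternates between a dark
   gray (level 20/255) and a bright gray (180/255), three cycles of
   10 s + 10 s, to verify the sensor and measure each person's reflex.
2. **Washout and baseline, 60 s** — a fixed mid-gray (90/255) lets
   residual constriction dissipate; the final 10 s are labeled as the
   luminance-adapted baseline.
3. **Cognitive load, 240 s** — luminance stays clamped at the same
   mid-gray while auditory tasks alternate: four 45 s blocks in an ABBA
   order (low, high, high, low) separated by 15 s rests. Because blocks
   and rests alone total 225 s, the default timeline also places a 15 s
   rest before the first block, which settles the pupil after baseline and
   brings the phase to its nominal 240 s; `leading_rest = FALSE` removes
   it. Under clamped luminance, any diameter change during this phase is
   by construction not reflex-driven.

Gray levels are stored as single-channel 0-255 proxies; the stimuli are
achromatic and no photometric calibration is assumed, so no conversion to
luminance units is attempted.

## Preprocessing

Eye trackers embedded in headsets sample at roughly 90 Hz and emit exact
zeros during blinks. The cleaning chain (`preprocess_session()`) is:
detect, dilate, interpolate, resample, filter.

* **Binocular reduction.** Each sample's diameter is the mean of the eyes
  that carry a value, falling back to a single eye; the choice is
  symmetric and configurable (`eye = "left"/"right"`). Openness is stored
  but does not gate validity — the artifact rules below catch closed-eye
  samples through their zero diameters.
* **Artifact rules** (`detect_artifacts()`). A sample is flagged when its
  diameter is missing or within `1e-6` mm of zero, and both endpoints of
  any consecutive pair whose inter-sample slope exceeds ±10 mm/s are
  flagged — faster than any physiological diameter change. The velocity
  rule uses raw inter-sample differences, not a smoothed derivative, and
  missing values are treated as zeros so blink edges trip it too.
* **Dilation** (`dilate_mask()`). Flags spread to every sample within
  50 ms, measured in time rather than samples because acquisition jitters
  around the nominal rate; the boundary is inclusive.
* **Interpolation** (`interpolate_artifacts()`). Flagged samples are
  replaced by linear interpolation between the nearest clean neighbors;
  flagged runs at the edges take the nearest clean value. Clean samples
  pass through bit-identical, and the operation is idempotent.
* **Data-loss QC.** The flagged fraction is computed after dilation (the
  conservative choice) and a session is excluded when it exceeds 15%.
  Metrics are still computed for excluded sessions; the flag travels with
  them so cohort summaries can drop them.
* **Resampling.** Linear interpolation onto a uniform grid at the nominal
  rate, required by fixed-coefficient filtering.
* **Dual-pathway filtering** (`lowpass()`). One order-4 Butterworth
  low-pass per pathway, applied forward and backward so there is no phase
  lag — velocity timing comparisons across pathways would otherwise be
  biased. The PLR pathway uses a 4 Hz cutoff, preserving reflex dynamics;
  the cognitive pathway uses 0.5 Hz, suppressing saccade-scale noise that
  would otherwise masquerade as dilation velocity. Cross-applying either
  filter to the other signal distorts exactly the quantity of interest,
  which is why the asymmetry is deliberate.

Numerically, the filter extends the series by odd reflection at both ends
and anchors each pass at its first value, so the DC gain is exactly 1 on
constants and edge transients stay within the discarded padding. The
padding length is the larger of three warm-up lengths and three cutoff
periods.

## Outcome metrics

From the 4 Hz trace and the timeline (`plr_metrics()`):

* dark and bright mean diameters, pooling all Phase 1 samples per state;
* amplitude = dark mean − bright mean, and the constriction percentage
  100 × amplitude / dark mean;
* peak constriction velocity: the largest magnitude of negative derivative
  (central differences) within 1 s after any dark-to-bright transition,
  reported as a positive number. The 1 s window reflects that the reflex
  completes within a few hundred milliseconds; it is configurable.

From the 0.5 Hz trace (`cognitive_metrics()`): low- and high-load means
over task blocks (rests excluded), their difference and percent change
(that session's low mean as denominator), and the peak positive derivative
within 5 s after any rest-to-high transition — the longer window matching
the slower rise of task-evoked dilation. The per-session maximum across
transitions is used for both velocities.

The **velocity ratio** (`velocity_ratio()`) divides peak constriction
velocity by peak dilation velocity. Values well above 1 are the
quantitative signature that the signal measured under clamped luminance is
not a residual light reflex: the two pathways differ in speed by
construction of their neuroanatomy, and the ratio operationalizes that
difference per session.

A configurable settle-skip (default 0 s) can exclude the first seconds
after each state or block onset from the pooled means. With whole-state
pooling, the means include the approach trajectory; under slow redilation
(time constant ~0.6 s) plus reflex latency, this biases the pooled
amplitude downward by roughly 13% of the true step. The defaults pool
whole states, matching how the metrics are defined; the package's
parameter-recovery tests use a 3 s settle-skip because they compare
against the generative step sizes, for which trajectory-free means are the
right estimator.

## Cohort statistics

`cohort_summary()` drops excluded sessions and reports per metric the n,
mean, SD (n − 1 denominator), and range, then applies the validation
tests: a two-sided one-sample t against 0 for PLR amplitude and cognitive
difference, with one-sample Cohen's d = (mean − μ₀)/SD, and a one-sided
Wilcoxon signed-rank against 1 for the velocity ratio using the normal
approximation z = (W⁺ − n(n+1)/4) / √(n(n+1)(2n+1)/24), average ranks on
ties, zeros dropped. The continuity correction is off by default (for a
22-session cohort with every ratio above 1 it changes z from 4.11 to
4.09) and can be enabled with `correct = TRUE`. `cohort_table()` formats
the publication-style layout.

## The session simulator

`simulate_session()` provides ground-truthed input so every pipeline stage
is testable without data collection. The paradigm's physiology is reduced
to the minimal model consistent with the known time courses — first-order
dynamics, since no published dynamics equations exist for this setting:

* the **luminance-driven component** tracks a state equilibrium (dark:
  baseline; bright: baseline − amplitude; iso: baseline − 0.2 × amplitude)
  through an exponential with time constant 0.2 s when constricting and
  0.6 s when redilating, delayed by a 0.25 s reflex latency. Its analytic
  peak constriction velocity is amplitude/τ at bright onset;
* the **cognitive component** tracks the high-load indicator with time
  constant ramp/3 (default ramp 2 s), so the dilation is ~95% complete
  after one ramp and decays during rests with the same constant;
* **hippus** — the spontaneous resting oscillation — as a 0.05 mm
  sinusoid at 0.15 Hz with random phase; **sensor noise** as independent
  0.02 mm white noise per eye around the common signal; **blinks** as
  Poisson-timed (0.2 /s) zero-diameter gaps of 0.1-0.3 s in both eyes;
  **timestamp jitter** uniform within ±1 ms of the 90 Hz grid.

Defaults were chosen once to match the span reported for healthy adults:
dark baselines of 3.75-6.80 mm, constriction fractions of 25.4-41.1% of
baseline, and task-evoked dilations of 0.1-0.8 mm; `cohort_ranges()`
draws per-session parameters uniformly from those intervals. The default
blink and noise levels keep simulated data loss near 6-8%, comfortably
inside the 15% QC bound, as natural blink rates do. Comparability with
published cohort statistics — not equality — is the contract: the
simulator emulates orders of magnitude and time courses, not individual
humans. Features of real data it does not emulate include pupil
foreshortening with gaze angle, saccade-linked transients, partial-blink
occlusion (openness is binary here), arousal drift, and non-exponential
reflex kinetics; passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to everything real
recordings contain.

Session i of a cohort derives everything from seed + i, so cohorts are
reproducible and individual sessions can be regenerated independently of
the cohort size.

## Numerical choices and limitations

* **Filter attenuation is physics, not error.** A 4 Hz zero-phase
  low-pass necessarily rounds the corner of an exponential onset with
  τ = 0.2 s: the measured peak velocity plateaus near 70% of the analytic
  amplitude/τ (the package's tests verify this against a dense-grid
  filtering oracle, and that the analytic value is always an upper
  bound). Measured velocities are therefore filter-conditional estimates;
  comparisons are meaningful within a fixed pathway configuration. The
  same smoothing perturbs the trace near transitions by several percent
  of the step while leaving plateaus untouched, which is why the
  clean-trace no-op guarantee applies to the cleaning-and-resampling
  chain, not the filter.
* **Whole-state pooling bias** (above): amplitude from pooled means is a
  conservative estimate of the generative step; the settle-skip option
  trades protocol fidelity for estimator sharpness.
* The velocity search takes per-session maxima across transitions; an
  averaging variant would be less variable but is not what a "peak"
  velocity reports.
* Sessions shorter than the timeline, missing a phase, or with all
  samples flagged raise structured errors rather than returning partial
  metrics.
* Problem sizes in the shipped tests — full 360 s sessions at 90 Hz
  (32 400 samples), cohorts of 20-22, and 1 000 small random traces for
  the artifact oracle — were chosen so the whole suite exercises the
  complete pipeline at realistic scale.

## A worked example

```{r example, eval = FALSE}
timeline <- build_timeline()
sim <- simulate_session(simulation_params(seed = 42), timeline)
res <- analyze_session(sim$trace, timeline)
res$plr$amplitude_mm        # reflex amplitude, mm
res$cognitive$difference_mm # task-evoked dilation, mm
res$velocity_ratio          # >> 1: temporal dissociation
cohort <- simulate_cohort(22, seed = 1)
metrics <- lapply(cohort, function(s) analyze_session(s$trace, timeline))
cohort_table(cohort_summary(metrics))
```
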