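# isopupil

Analysis pipeline for **iso-luminant VR pupillometry**: sessions designed so
that pupil dilation during cognitive testing can be attributed to mental
effort rather than to the pupillary light reflex (PLR).

## The problem and who this is for

Pupil diameter carries two superimposed autonomic signals. The PLR is a fast
brainstem reflex (constriction within a few hundred milliseconds of a
luminance increase, peak speeds of tens of mm/s); the task-evoked pupillary
response (TEPR) is a slow, small dilation (tenths of a millimeter over 1-3
seconds) driven by the locus coeruleus-norepinephrine system during
cognitive effort. In a VR headset, scene luminance variation makes the
reflex swamp the cognitive signal. The iso-luminant paradigm clamps
luminance during cognitive testing — after a reflex-validation phase and a
washout — so that residual diameter changes index cognitive load.

`isopupil` is for researchers running or simulating such sessions: it turns
raw ~90 Hz binocular eye-tracker exports into per-session outcome metrics
and cohort-level validation statistics.

## What it computes

For each session, over a three-phase timeline (3 × (10 s dark + 10 s
bright) reflex cycles; 60 s washout whose last 10 s form the baseline; four
45 s auditory task blocks in ABBA order with 15 s rests):

- **PLR metrics** (4 Hz zero-phase Butterworth pathway):
  amplitude = mean dark diameter − mean bright diameter, constriction
  percentage 100·A/dark, and peak constriction velocity = max |negative
  d(diameter)/dt| within 1 s of each bright onset.
- **Cognitive metrics** (0.5 Hz pathway): difference = mean high-load −
  mean low-load diameter, percent change 100·Δ/low, and peak dilation
  velocity = max positive derivative within 5 s of each high-load onset.
- **Velocity ratio** = peak constriction velocity / peak dilation velocity.
  Values well above 1 are the quantitative evidence that the cognitive
  signal is not a residual light reflex.

Preprocessing flags artifacts (inter-sample slopes beyond ±10 mm/s, or
zero/missing diameters), dilates flags by 50 ms, linearly interpolates
them, excludes sessions losing more than 15% of samples, and resamples to a
uniform grid before filtering. Cohort summaries apply a one-sample t test
and Cohen's d to amplitude and difference, and a one-sided Wilcoxon
signed-rank (normal approximation) to the velocity ratio against 1.

A ground-truthed simulator (`simulate_session()`, `simulate_cohort()`)
generates sessions from first-order constriction/dilation dynamics with
hippus, blinks, and sensor noise, so the whole pipeline is testable without
data collection.

## Worked example

```r
library(isopupil)
timeline <- build_timeline()                    # 360 s, three phases
sim <- simulate_session(simulation_params(seed = 42), timeline)
res <- analyze_session(sim$trace, timeline)

res$plr$amplitude_mm                 # 1.322  mm reflex amplitude
res$plr$constriction_pct             # 28.4   % constriction
res$cognitive$difference_mm          # 0.394  mm task-evoked dilation
res$velocity_ratio                   # 17.5   constriction/dilation speed
res$data_loss_fraction               # 0.059  -> excluded = FALSE (< 0.15)
```

The reflex amplitude (1.32 mm, 28% constriction) dwarfs the task-evoked
dilation (0.39 mm), and the measured speed ratio of 17.5 shows the two
responses live on different time scales — the dissociation the paradigm is
built to demonstrate. (The measured amplitude sits below the generative
1.5 mm step because whole-state pooling includes the approach trajectory;
see the methods vignette.)

At cohort level:

```r
cohort <- simulate_cohort(22, seed = 1)
metrics <- lapply(cohort, function(s) analyze_session(s$trace, timeline))
cohort_table(cohort_summary(metrics))
#                  Metric     Mean (SD)     Range Test Statistic  P-value Effect Size
#        plr_amplitude_mm   1.50 (0.30) 1.02-2.17    t(21)=23.67 1.26e-16        5.05
# cognitive_difference_mm   0.49 (0.20) 0.18-0.78    t(21)=11.64 1.27e-10        2.48
#          velocity_ratio 20.37 (15.33) 9.39-78.51         Z=4.11    2e-05
# (plus constriction %, percent change, and both peak velocities)
```

A command-line interface wraps the same functions
(`exec/isopupil simulate|analyze|cohort|timeline`); see `?pupil_cli`.

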