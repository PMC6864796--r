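---
title: "Gait-event detection from foot-worn IMUs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-event detection from foot-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitevents)
```

This vignette is the package's own account of the method: the models and
their assumptions, every tunable parameter with its unit and default, what
the synthetic-data generator does and does not emulate, and the design
choices that were genuinely open.

## The problem

Robot-assisted gait trainers impose a cyclic, sagittal-plane gait pattern.
To time functional electrical stimulation (FES) to that pattern, four gait
events per leg must be detected online from a foot-worn six-axis IMU
(accelerometer ±16 g, gyroscope ±2000 °/s, 500 Hz): Initial Contact (IC,
heel strike), Full Contact (FC, foot flat), Heel Off (HO) and Toe Off (TO).
Two constraints shape everything:

* **Arbitrary mounting.** The therapist must not need to align the sensor;
  the unknown, fixed sensor-to-foot rotation has to be estimated from the
  data themselves.
* **Safety over completeness.** A missed step triggers nothing (type-2
  error, harmless); a falsely detected step can stimulate a muscle at the
  wrong phase (type-1 error, hazardous). The detector therefore prefers to
  drop a cycle over accepting a doubtful one.

## Sensor-to-foot alignment

During foot flat the only specific force is gravity and the gyroscope is
quiet. The aligner exploits this:

1. **Full Contact**: all three gyroscope components stay below
   `omega_fc_thresh` (default 20 °/s) for `k_fc` consecutive samples
   (default 50 = 0.1 s).
2. **ẑ (gravity) axis**: the accelerometer vector averaged over that
   quiescence window. Averaging is a deliberate extension of the
   single-sample reading: at realistic noise a single sample is
   noise-dominated, and foot flat is defined over a window anyway.
3. **ŷ (pitch) axis**: the per-axis *signed* sums of the gyroscope over the
   `k_y` samples after the Full Contact (default 400 = 0.8 s), which span
   the next heel rise. The componentwise absolute sums identify the main
   rotation axis (their argmax); the signed sums keep its direction. Using
   absolute values componentwise would be enough for a sensor roughly
   aligned with one axis, but under a general mounting rotation the pitch
   axis has mixed-sign components and componentwise magnitudes no longer
   describe a direction; the signed sum does, at no extra cost. The global
   sign convention is that heel-rise pitch rate is positive in the foot
   frame.
4. **x̂ = ŷ × ẑ**, all rows normalized, and ŷ recomputed as ẑ × x̂. This
   re-orthogonalization is required because the measured pitch axis is
   generally not exactly perpendicular to gravity; without it the "rotation"
   would shear the frame. All emitted matrices satisfy R Rᵀ = I and
   det R = +1 to 1e-9.

The rotation is refreshed at every new Full Contact and governs samples from
the moment its summation window closes. Windows with no rotation content
above `y_sum_floor` (default 5 °/s mean; pure rest) yield a *degenerate*
estimate: gravity is still correct, the pitch axis is an arbitrary
orthogonal direction, and the estimate is flagged. Degenerate estimates are
only recorded until the first informative one exists; offline, samples
before the first informative estimate are rotated with it retroactively.

**Why `k_y` = 0.8 s.** The quiescence condition completes in late swing or
early stance, so the summation window must reach *past* the upcoming heel
rise. At cycle durations of 1.05–1.4 s (treadmill 1.2–1.7 m/s), heel rise
begins ~0.4–0.6 s after the window opens; 0.8 s captures a substantial part
of the pitch ramp at every speed while still fitting within one cycle.

**Sign of gravity.** The package orients ẑ along the measured specific
force, so rotated resting z-acceleration is **+9.81 m/s²**. Conventions
differ on the sign (a frame with z up measures +g specific force at rest);
the measured-tables convention is used consistently throughout, including
the Heel-Off gravity correction.

## Event detection

All detection runs on the rotated (foot-frame) stream, under a
finite-state machine that only accepts the awaited event
(IC → FC → HO → TO → IC); everything else is discarded.

**Jerk.** IC detection needs d a_z/dt. The differentiator is a first-order
*backward* difference times the sampling rate — the only causal choice for
streaming — followed by a trailing moving average (`jerk_smooth`; lokomat 5,
lyra 9 samples). The smoothing is not cosmetic: differencing at 500 Hz
amplifies accelerometer noise by the sampling rate, so with σ = 0.2 m/s²
per sample the raw jerk noise is ~140 m/s³ — inside any plausible IC band.
A width-w trailing average reduces this by the factor w while delaying the
pulse by only w/2 samples (≤ 9 ms). The moving average uses zero history at
the stream start, so the startup transient is damped, never amplified.

**Initial Contact** fires when |jerk| enters the floating band
`(jerk_min, jerk_max)`, no earlier than `min_swing_time` after the last Toe
Off; for the lyra profile the pitch rate must additionally lie inside
`ic_band` (default ±5 °/s — at a true IC the foot is momentarily still,
while the late-swing artifacts that mimic an IC occur at elevated pitch
rate). On every accepted IC the band updates from the pulse peak (the
maximum |jerk| in the 50 ms after the trigger, since a crossing detector
fires on the rising edge below the peak):

```
edge' = (1 - alpha) * edge + alpha * gamma * peak
```

with `alpha` = 0.3 and `gamma` = (0.5, 1.5) (lyra: 0.6 low). The
exponential blend is the simplest rule that "remembers the previous
threshold and adds a fraction of the current jerk"; partial updates keep a
single outlier step from capturing the band. With constant peaks the band
converges geometrically (ratio 1 − alpha) to (0.5·peak, 1.5·peak).

**Full Contact** fires once all gyroscope components have been quiet for
`k_fc` samples *counted from the accepted IC* — about 0.1 s after IC, i.e.
early midstance. (Counting a trailing window regardless of the IC would
fire one sample after IC, since late swing is already quiet.)

**Heel Off** fires when |ω_y| exceeds `omega_heeloff_thresh_y` (15 °/s)
while |a_x|, |a_y| and |a_z − g| stay below `a_heeloff_thresh` (3 m/s²
each), no earlier than `min_roll_time` (0.15 s) after IC. The comparator
directions deserve a note: a printed all-below form of these conditions
would be satisfied trivially during quiet foot flat, reducing Heel Off to a
pure timer, while the surrounding description speaks of an *increase* of
rotation. The package default therefore requires the rotation to exceed its
threshold while translation is still quiet — rotation precedes translation
at heel rise — and every comparator direction is a config switch
(`heeloff_omega_exceeds`, `heeloff_acc_below`).

**Toe Off** requires three conditions *sequentially*: ω_y >
`omega_threshold_high` (200 °/s), then strictly decreasing for `k_to`
consecutive samples (25 = 50 ms, on a 5-sample trailing-averaged trace),
then ω_y < `omega_threshold_low` (150 °/s); the event fires at the third.
The event therefore lands on the falling flank after the swing peak — later
than anatomical toe off, but at a highly repeatable phase, which is what a
cycle-percentage scheduler needs. The peak ω_y observed feeds the
adaptation.

**Speed adaptation.** After each Toe Off,
`f = clamp(omega_max / omega_ref, 0.5, 2)` (reference 300 °/s) scales the
two Toe-Off thresholds by `f` and both temporal gates by `1/f`: faster
cycles swing faster and have shorter phases. The linear, clamped form is
the package's choice; nothing more specific is derivable from the method's
description. The gates default to `min_swing_time` 0.10 s (lokomat) /
0.12 s (lyra) and `min_roll_time` 0.15 s: the swing gate must stay below
the detected-TO-to-next-IC interval at the fastest speed (~0.14 s at
1.7 m/s, given the post-peak TO timing above), which is why a much longer
gate would veto legitimate steps.

**Cycles and dropouts.** A gait cycle is the span between consecutive
accepted ICs and is *valid* only if all four events occurred in order
within it and it contains no timestamp gap larger than `gap_factor / fs`
(default 5 samples) — transmission dropouts invalidate the cycles they
touch. Only valid cycles ever produce stimulation. Left and right streams
are processed by independent detector instances; no cross-leg constraint is
imposed (one IMU per limb suffices).

## Stimulation scheduling

Each of the eight chart channels switches on at `start_pct` and off at
`stop_pct` of the gait cycle; entries with start > stop wrap across the
cycle boundary. Event-to-percent mapping uses piecewise-linear anchors
IC = 0, FC = 8, HO = 40, TO = 60, next IC = 100 (standard gait-phase
values; configurable). The scheduler is causal: when a cycle opens, its
duration is unknown, so times are predicted from the previous IC-to-IC
duration; the first cycle of a session and every invalid cycle produce no
stimulation. Stimulator parameter sets are validated as data against the
device grid (≤130 mA / 5 mA, 10–50 Hz / 5 Hz, 20–500 µs / 10 µs).

## The synthetic-data generator

`simulate_gait()` emulates exactly the features the detector consumes, as
piecewise-smooth primitives rather than biomechanical simulation — anything
richer would be unverifiable without reference recordings:

* raised-cosine IC jerk pulse (width 0.04 s, analytic jerk peak 400 m/s³
  lokomat / 150 m/s³ lyra — the end-effector trainer's heel strike is much
  softer);
* quiet foot flat with acceleration (0, 0, g);
* pitch-rate ramp from 40% of the cycle, raised-cosine rise to a 300 °/s
  peak at 65%, linear (strictly decreasing) fall to zero at 97%;
* foot pitch up to 15° mid-swing, with gravity resolved into the tilted
  frame;
* speed mapping 1.2/1.5/1.7 m/s → cycle durations 1.4/1.2/1.05 s (belt
  speeds are published, cadences are not; the table is editable);
* Gaussian noise σ_acc = 0.2 m/s², σ_gyr = 1 °/s, of the order of the
  resting-phase standard deviations measured on real sensors;
* an arbitrary mounting rotation (Haar-uniform when drawn);
* lyra artifacts: sharp spurious jerk spikes late in swing (94/91/88% of
  the cycle), where the pitch rate is still away from zero — the pattern
  the IC angular-velocity band rejects;
* disturbances: IC-like spikes at arbitrary times, sample dropouts, slow
  gyroscope drift.

Ground truth carries the constructed event indices; with n cycles there are
n ICs but only n − 1 *complete* IC-to-IC reference steps, and evaluation
counts complete steps (a perfect detector scores 100%, not (n−1)/n).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: soft-tissue and orthosis vibration, harmonic
distortion of the robot drive, inter-step amplitude variability,
subject-induced voluntary movement, sensor bias instability and
misalignment drift. The published per-window results on real recordings
(mean detection rates of 98.1% for the exoskeleton and 94.1% for the
end-effector trainer, with small type-1 errors) came from treadmill
sessions that are not deposited; the simulator results are exact under its
own conditions and qualitative benchmarks beyond them.

## Evaluation

Steps are matched greedily in time order, each detected opening IC to the
earliest still-unmatched reference IC within `tol` (default 10% of the
median reference cycle duration — the original counts were manual, with no
published tolerance; earliest-within-tolerance makes the greedy matching
maximum-cardinality). Detection rate and type-1/type-2 errors follow the
standard formulas on a 0–100 scale. Windowed evaluation uses 75,000-sample
windows whose starts snap to a resting phase (gyroscope quiescence),
forward when the window still fits, otherwise backward.

Shape verification normalizes a signal by removing its mean and dividing by
the square root of its autocorrelation maximum (its energy), so the
normalized autocorrelation maximum is exactly 1; similarity is the maximum
cross-correlation of two normalized signals over lags up to half a cycle.
One caveat documented by a test: for finite windows the mean removal turns
quiet margins into a small negative plateau, so a time-shifted copy scores
slightly below 1 (≈0.99 for one cycle), which is inherent to the
normalization, not an implementation artifact.

## Numerical and degenerate-input choices

* Sample indices are 1-based; timestamps are seconds from stream start;
  t = (index − 1)/fs.
* CSV files use '.' decimals, comma separators, UTF-8, one header line;
  doubles are written with 17 significant digits and parsed with a
  correctly-rounded `strtod`, so write-then-read is bit-identical.
* Zero or parallel axis vectors, constant signals, empty charts and
  zero-length dropouts all have defined behaviour (error, error, empty
  schedule, no-op respectively).
* Rotation estimates whose summation window would cross the stream end are
  not emitted.
* The test-suite problem sizes (20-cycle runs for completeness and rotation
  recovery, 1,000 short adversarial runs for FSM safety, 50 random
  mountings) keep each property statistically meaningful at a few minutes
  of total runtime.

## Known limitations

* The detected Toe Off is a repeatable *phase marker* on the falling
  pitch-rate flank, not anatomical toe off; anchor percentages absorb the
  offset for scheduling, but latency-sensitive uses should account for it.
* Initial thresholds before any adaptation are package defaults sized to
  the simulator's amplitudes; on a new device they must be calibrated (the
  floating band converges within a few steps once ICs are being accepted,
  but the *initial* band must bracket the first step's jerk).
* The scheduler predicts from the previous cycle; a sudden speed change
  mistimes one cycle's stimulation by the duration difference.
* Per-limb processing cannot exploit bilateral symmetry to reject
  artifacts that a cross-leg model would catch.
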