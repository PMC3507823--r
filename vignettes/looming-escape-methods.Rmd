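---
title: "Methods: looming geometry, DCMD rate analysis and glide detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: looming geometry, DCMD rate analysis and glide detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomglide)
```

## The problem

A bird diving at a flying locust is, from the locust's point of view, a dark
shape expanding over the eye — a looming stimulus. The locust's
looming-detector pathway (LGMD in the optic lobe, relayed one-for-one by the
DCMD to the thoracic motor centres) fires a train of spikes whose rate tracks
the expansion, and high-frequency DCMD bursts can trigger a last-ditch
*glide*: the locust stops beating its wings just before projected impact.
`loomglide` implements the quantitative chain from predator kinematics to
this behaviour: how fast an attack closes, what angular expansion it
produces, how a looming-detector's rate is measured, and how glides are
detected and summarised. A synthetic-data generator with the same
statistical structure stands in for video and electrophysiology recordings,
which cannot be redistributed.

## Geometry and time conventions

A disc of half-size $l$ (m) approaching at constant speed $|v|$ (m/s)
subtends $\theta(d) = 2\arctan(l/d)$ at distance $d$. Writing
$d = |v| \cdot t$ with $t$ the time to collision, the whole time course of
$\theta$ depends on $l$ and $|v|$ only through the ratio $l/|v|$ (reported in
ms). This is why a 0.08 m laboratory disc can stand in for a 0.136 m kite
thorax at matched $l/|v|$, and it is tested pointwise in the suite. The
expansion rate is

$$\theta'(t) = \frac{2\,l\,|v|}{|v|^2 t^2 + l^2},$$

checked against a central difference of $\theta$.

Two clocks are used and never mixed:

* geometry functions take **time to collision** in seconds, positive before
  collision;
* event data (spikes, wingbeats, glide onsets) are in **signed milliseconds
  relative to projected collision**, negative before. Simulated approaches
  stop `end_distance` (default 0.07 m) short of the eye, so "collision" is a
  projection: `collision_offset()` = `end_distance / speed` past the end of
  motion.

Angles are computed in radians and reported in degrees. Printed $l/|v|$
labels use `display_round()`, which rounds halves away from zero (2.67
$\to$ 2.7, 1.25 $\to$ 1.3) with a $10^{-9}$ relative epsilon guarding binary
representation of decimal halves; base `round()` would give 1.2 for 1.25.

`frame_schedule()` converts a stimulus into per-frame on-screen sizes. The
frame count is $\lfloor(\mathrm{start} - \mathrm{end})/|v| \cdot
f_\mathrm{refresh}\rfloor$ — frames exist only while the object moves — and
frames are spaced evenly over the travel so the final frame sits exactly at
the end distance (at 200 Hz the spacing differs from $1/f$ by well under one
part in a thousand). Both wing-bar dimensions use the same perspective
projection $\mathrm{viewing} \cdot \mathrm{size}/d$; whether the original
display scaled the bar height this way is unknowable from the outside, and
the schedule records both dimensions under the one rule. The physical pixel
pitch is a required argument: monitor resolution alone does not determine
it, and inventing a screen size would silently scale every pixel quantity.
Oversized frames are clipped, flagged, and warned about. The wing bar's
0.018 m vertical offset affects rendering only; the wing-tip subtense uses
the full span, $2\arctan((\mathrm{span}/2)/d)$.

## Attack kinematics

Track segments are digitized beak positions (pixels) at known frame indices;
a calibration pair (a feature of known length in pixels and metres — here the
predator's published mean body length) converts to metres. Per-frame speed is
the Euclidean displacement times scale times frame rate, divided by the frame
gap when frames were skipped. Averaging is strictly hierarchical and
unweighted — frames $\to$ segment $\to$ attack $\to$ individual — and the
grand mean and *sample* SD are taken across individuals only, so an
individual contributing many attacks carries no extra weight
(anti-pseudoreplication). A configurable trim (default the final 1.25 s of
each attack) restricts speeds to the terminal phase. `smooth_for_display()`
(a 3-point mean) is flagged `smoothed = TRUE` and exists for plotting only;
the averaging pipeline computes from raw segments and never consumes it.

Closing speed for heading vectors meeting at $\varphi$ is
$\sqrt{v_1^2 + v_2^2 - 2 v_1 v_2 \cos\varphi}$: the sum of speeds head-on
($\varphi = 180°$), the difference in a tail chase ($\varphi = 0°$).
`lov_range()` brackets the $l/|v|$ a predator's thorax presents using exactly
the endpoint recipe of the source analyses: fast predator (mean + SD) meets
fast prey (mean + SD) head-on; slow predator (mean − SD) overtakes fast prey
from behind. A scenario may carry a separate chase-context predator speed
(the barn swallow flies at 8.6 m/s low and straight but 6.8 m/s when higher
and erratic). If the slow predator cannot overtake the fast prey the chase
endpoint is undefined and the function stops with instructions rather than
returning a negative speed.

## Spike-rate analysis

`rate_at_spikes()` computes, at each spike time $t$, the count of spikes in
the half-open window $(t - w, t]$ divided by $w$ (default 25 ms, one half
wingbeat). **The anchoring spike is counted.** The convention is not stated
by the experimental literature this mirrors; including the anchor guarantees
a nonzero rate at every spike event (a rate "computed at each spike event"
that can be zero at that event would be odd) at the cost of a bias of exactly
$1/w$ (+40 Hz at 25 ms) on homogeneous trains. The bias is documented,
flagged in the output (`inclusive = TRUE`), and *tested*: a property test
checks that homogeneous Poisson trains average to $r + 1/w$ within three
standard errors. Peak ties are broken toward collision (the later time),
which is conservative when asking whether peaks occur *earlier* at higher
$l/|v|$. PSTHs use left-closed 25 ms bins and aggregate hierarchically:
presentations $\to$ individual mean $\to$ group mean $\pm$ SEM across
individuals. `threshold_crossings()` reports the first time a rate series
reaches 150 Hz — the approximate level above which DCMD spikes summate to
fire the glide motor neuron — and the span spent above it.

## Glide detection

A glide is an inter-wingbeat interval exceeding $k = 1.25$ times the mean of
the preceding $n = 10$ intervals. Two choices the verbal rule leaves open:

* the first $n$ intervals are ineligible (the rule requires a full history;
  animals fly before stimulus onset, so the burn-in is benign);
* after a detection the history buffer is **reset** and must refill — the
  glide interval itself must not inflate the baseline against which the next
  pause is judged.

Glide onset is the last sensor event before the pause. "Before collision"
is strictly `onset < 0`; an onset exactly at collision does not count.
Occurrence is the proportion of valid presentations with at least one glide;
the before-collision proportion is computed only over individuals that
glided (non-gliders are excluded from that metric, not scored zero); and by
default only the first glide of a presentation enters timing summaries —
flight resuming after a glide is not modelled, and multiple detections in
one presentation would double-count a single behavioural event. Weak-flight
presentations are excluded before any counting.

## The synthetic generator

`eta_params()` / `eta_rate()` implement the η-model of looming-detector
firing:

$$f(t) = C \cdot \theta'(t + \delta)\, e^{-\alpha\,\theta(t + \delta)},$$

with angles in radians, $t$ the time to collision, and $\delta$ the response
latency. Its two structural predictions drive the whole battery: the peak
occurs $\alpha \cdot l/|v| - \delta$ before collision (linear in $l/|v|$),
and the peak rate scales as $1/(l/|v|)$, with the subtense at the peak fixed
at $2\arctan(1/\alpha)$.

Defaults, chosen once: $\alpha = 4.7$ and $\delta = 27$ ms sit at the values
the looming-detector literature typically reports (a threshold angle near
24° and a ~27 ms latency); $C = 133$ then puts the peak at ~400 Hz for
$l/|v|$ = 4 ms, matching the strongest group means reported for fast looms.
No claim is made that these reproduce any particular animal. With a winged
stimulus the rate is multiplied by `wing_attenuation` (default 0.85, a
~10–15% depression) during the final quarter of the approach — a
phenomenological stand-in for stronger lateral inhibition from the extra
moving edges, not a mechanistic model.

Spike trains are inhomogeneous Poisson by thinning (candidates at a grid
bound inflated 5%, kept with probability $f/f_{\max}$), with a 1 µs time
resolution matching the 3-decimal CSV format. Wingbeats are a 50 ms lattice
(25 ms half wingbeat) with Gaussian jitter (default SD 2 ms; SDs above a
third of the period would scramble event order and are rejected) and a
uniform random phase per presentation — wingbeat phase is not stimulus
locked, and a fixed phase would quantize glide onsets artificially. Glide
injection mirrors the summation-gating hypothesis: at the first wingbeat
whose following half-cycle overlaps a model rate ≥ 150 Hz, with probability
`gating_probability` the next `glide_beats` (default 3) wingbeats are
deleted, giving a pause of ~4 periods (glide duration ~150 ms, consistent
with reported glides exceeding 130 ms); at most one glide per presentation.
The gating probability has no published estimate; 0.7 places occurrence in
the 50–80% band typical of last-ditch escape responses and is a free
parameter, not an estimate. Wingbeat spans extend several periods past the
response so that a glide injected near collision is always followed by
resumed flight and remains detectable.

`scenario_battery()` fans a master seed out to independent per-presentation
seeds (spike sampling, wingbeat phase/jitter, gating draw), so regeneration
is byte-identical, and records a pseudorandom presentation order.

### What the generator does *not* emulate

No refractoriness (pure Poisson), no habituation across presentations, no
steering responses, no arousal-dependent peak timing, no receptive-field
geometry, and a flat (rate-independent) gating probability. Consequently a
green battery test establishes that the *pipeline* recovers the structure the
generator encodes — monotone peak-rate dependence on $l/|v|$, threshold-gated
glide occurrence, collision-referenced timing — not that the η-model with
these defaults reproduces any animal's numbers. Real wingbeat jitter also
produces occasional false glide detections in long recordings (about 0.5% of
intervals at 2 ms jitter); the generator shows the same behaviour, visible as
an isolated low-occurrence entry at $l/|v|$ 80 ms in the worked example.

### The threshold-boundary inversion

In this model the suprathreshold window is governed by two opposing
scalings: the response timescale grows with $l/|v|$, but the peak amplitude
shrinks as $1/(l/|v|)$. Stimuli with $l/|v| > 10.7$ ms never reach 150 Hz
(peak 121 Hz at 13.3 ms) and never glide. At the boundary ($l/|v|$ 10 ms,
peak 161 Hz) the suprathreshold window is a narrow patch around the peak, so
the first crossing (−35 ms) is *later* than at $l/|v|$ 8 ms (−41 ms); from 8
ms downward the crossing is set by the rising edge and moves monotonically
toward collision (−41, −40.5, −39, −35, −31, −27.5 ms at 8, 6, 5.3, 4, 3.2,
2.7 ms). The acceptance test for the onset trend therefore covers the
rising-edge regime (model peak ≥ 1.2× threshold); asserting it across the
boundary would test a property the model genuinely does not have. For the
same reason the generator cannot reproduce the full-range decline of glide
timing seen in animals, whose measured rates stay well above 150 Hz even at
$l/|v|$ 80 ms.

## Parameter recovery

The linearity $t_\mathrm{peak} = \alpha \cdot l/|v| - \delta$ is recovered
from sampled spikes by `fit_peak_time_law()`. Estimating a peak time from
windowed rates is biased (a backward window shifts the argmax by ~$w/2$; the
max of a noisy series is biased toward broad regions), so the estimator uses
the structure of the model instead: because start distance, end distance and
$l$ are fixed across the battery, the spike-time density is *identical for
every stimulus up to the $l/|v|$ time scaling*. The per-stimulus peak is the
KDE mode with bandwidth proportional to $l/|v|$, Richardson-extrapolated
over two bandwidths ($0.5$ and $1 \times l/|v|$) to cancel the
smoothing shift; any residual mode bias is a constant in scaled units and
lands entirely on the slope, leaving the intercept ($-\delta$) unbiased. The
fit is weighted least squares with weights $1/(l/|v|)^2$, matching the
scaling of the estimation error. At the experiment-mirroring battery size
(60 presentations/stimulus, ~27 spikes each) sampling error alone exceeds
the 10%/5 ms recovery tolerance, so the recovery test pools 1500
presentations per stimulus — a test-design choice; every generator parameter
keeps its default. Verified over 12 independent seeds: slope error SD 0.16
(tolerance ±0.47), intercept error SD 1.0 ms (tolerance ±5 ms).

## Numerical and degenerate-input choices

* Thinning requires a finite rate bound; an unbounded rate function is an
  error, and the grid bound is inflated 5% (an approximation documented
  here: a rate exceeding the grid maximum between grid points by more than
  5% would be undersampled).
* `frame_schedule()` of a stimulus whose approach is shorter than one frame
  returns an empty schedule, not an error.
* Empty spike trains yield empty rate series; `peak_response()` on an empty
  series is an error (there is no peak to report).
* A single-value group has SEM 0 by convention, with $n = 1$ reported so the
  consumer can tell.
* Track segments need ≥ 2 samples; duplicate frame indices are rejected
  rather than de-duplicated (they indicate a digitizing error).
* CSV event times are written with 3 decimals (1 µs); readers validate
  headers, types and within-presentation time ordering and name the
  offending row and column.

## Known limitations

Spike generation omits refractoriness, so measured peak rates carry the
documented $+1/w$ inclusive-window bias on top of Poisson variability. The
wing effect is a single late-phase multiplier, not a lateral-inhibition
model. Glide occurrence in the generator is a step function of $l/|v|$
(threshold crossing × flat gating probability) where animals show a graded
increase. Tracks are straight lines with isotropic pixel noise — no camera
pan, no curvature, no correlated digitizing error. The pipeline implements
descriptive aggregation only (means, SD, SEM, proportions); inferential
statistics are out of scope.
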