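---
title: "Methods: m-sequence reverse correlation of optic-flow-sensitive neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m-sequence reverse correlation of optic-flow-sensitive neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Optic-flow-sensitive descending neurons carry widefield motion signals from
the optic lobe toward the motor centres that stabilise head and body
posture. Their temporal response dynamics can be characterised efficiently
with white-noise system identification: a maximal-length shift-register
sequence (m-sequence) of +1/-1 values sets the direction of a train of
small roll impulses displayed at the monitor frame rate, and the neuron's
first-order impulse response (linear kernel) is recovered by
cross-correlating the impulse polarity sequence with the recorded spike
train. `rollkernel` implements that full analysis — stimulus construction,
kernel extraction, kernel parameterisation, linear–nonlinear (LN) model
validation and group statistics — together with a synthetic LN–Poisson
recording generator so that every stage can be verified end to end against
known ground truth.

# Stimulus model

## m-sequences

An order-`n` m-sequence is produced by a Fibonacci linear-feedback shift
register whose feedback taps form a primitive polynomial over GF(2); output
bits are mapped `1 -> +1`, `0 -> -1`. One period has `2^n - 1` values with
three defining properties: balance (`2^(n-1)` values of +1, one fewer -1),
uniqueness of every circular length-`n` subword, and closure of the
elementwise shift product. The package embeds a catalogue of primitive
polynomials for orders 2–16 (several per order where convenient) rather
than searching for them at run time; `generate_msequence()` verifies
maximality by construction and reports the observed period when handed
non-primitive taps.

One subtlety: balance and shift-product closure cannot both hold verbatim
under one bit-to-sign convention. With `1 -> +1` (which yields the stated
excess of +1), the product of the sequence with a shifted copy equals a
shifted copy with *flipped* signs, because XOR maps to a product only under
the opposite convention. `verify_msequence()` therefore accepts a shifted
copy of the sequence or of its negation as closure; both conventions pass,
corrupted sequences do not.

The recording protocol uses order 8 (255 impulses), circularly extended to
400 frames to let onset transients die out; only the final 255 impulses —
exactly one full period — enter the analysis. `extend_circular()` aligns
the tiling so that the final period is the sequence itself.

## Starfield geometry

The displayed stimulus is a 3-D cloud of 2 cm spheres at 100 per cubic
metre in a 4 m cube centred on the animal, projected gnomonically onto a
screen 6.5 cm in front of the head subtending 155 x 138 degrees
(2560 x 1440 pixels, 165 Hz). Sphere brightness interpolates linearly from
black at 6 cm to white at 2 m; spheres nearer than 6 cm are not drawn.
Spheres *farther* than 2 m are not drawn either: at 2 m they are white on
the white background and therefore invisible. That reading is not
arbitrary — with it, a Monte-Carlo count of rendered spheres at the default
geometry averages about 1220 (the solid angle of the 155 x 138 degree
pyramid times the 2 m ball, times the density), matching the roughly 1200
anterior spheres the protocol reports; without the far cutoff the count
doubles.

Roll rotates the cloud about the body (viewing) axis, counter-clockwise on
screen being excitatory for a left-receptive-field neuron; lift translates
it vertically, downward being excitatory. Positions wrap modulo the cube
under lift so density is stationary over a trial. The analysis pipeline
consumes only the per-frame trace (impulse sign, roll increment, lift
increment, frame log); rendering exists for inspection.

Per-frame arithmetic is kept un-rounded. Constant roll at 50 deg/s at
165 Hz is 50/165 = 0.303 deg per frame; combined with 0.33 deg impulses
this gives +0.027/-0.633 deg increments (the figures' printed 0.03 and
0.63 are two-decimal roundings). The printed impulse sizes 0.18/0.33/0.48
deg are treated as exact and the quoted velocities (30/50/80 deg/s) as
approximate, since the two are mutually inconsistent at the second decimal.

## Stimulus polarity convention

Impulse polarity is defined in the *neuron-relative* frame: +1 is the
preferred (excitatory) roll direction. For a right-side neuron the same
neuron-relative sequence appears mirrored on the screen. The synthetic
generator stores the screen-frame trace (mirrored for right-side neurons)
and the analysis pipeline applies `mirror_normalize()` before estimation.
This matters for the validation stage: the shared trial is identical
across neurons in the neuron-relative frame, which is what makes the
across-neuron reference response coherent. If instead both sides viewed
the same screen polarity, left- and right-side responses to the shared
sequence would be anti-correlated and their sum would carry no signal.

# Synthetic recording generator

Each synthetic neuron is an LN–Bernoulli cascade. The kernel is a
log-normal-in-lag bump with exact closed-form placement of its peak
(default amplitude 1 at 18 ms) and width (default FWHM 12 ms, the protocol's
median kernel statistics); an optional slow tail flag exists for probing
return-to-baseline behaviour and is off by default. Drive is the physical
per-frame increments convolved with the kernel: roll increments in degrees
times `roll_gain` (drive per degree) plus lift increments in cm times
`lift_gain`. Expressing the roll gain per degree rather than per impulse
handles impulse-size and constant-flow conditions with one constant
(per-impulse gain is then `roll_gain * base_impulse`, so amplitude still
scales with impulse size). Rate is a rectified line with saturation,
`r = min(rmax, max(0, r0 + slope * u))`, and spikes are Bernoulli per 1 ms
bin (an implicit 1 ms refractory period, adequate below ~300 Hz).

Defaults: `r0 = 30` Hz, `slope = 1` Hz per drive unit, `rmax = 300` Hz,
`roll_gain = 260` per degree, `lift_gain = 60` per cm. The roll gain is
set so that the simulated steady-state response to preferred-direction
roll at 50 deg/s is ~199 spikes/s — the previously reported mean response
for these neurons, which also anchors the inclusion gate below — with
m-sequence peak rates around 150–200 Hz. The lift gain is a compromise:
excitatory (downward) lift raises the m-sequence spike rate strongly while
neutral (upward) lift suppresses without silencing, keeping all nine
protocol conditions above the 5 Hz inclusion gate. A symmetric LN cascade
cannot reproduce the recorded asymmetry where neutral lift leaves the
spike rate unchanged; that would need the upstream rectification and
adaptation this generator deliberately omits.

What the generator does *not* emulate: spike-frequency adaptation,
persistent firing after excitatory stimulation, neuron-to-neuron
heterogeneity of kernels, ocellar input, or recording artifacts. Passing
tests therefore show that the *analysis* is correct and unbiased under an
idealised LN world at realistic rates — not that real neurons are LN.

The simulated protocol mirrors the recording sessions: nine conditions
(Roll 18/33/48; Roll 33 with constant roll at ±25 and ±50 deg/s; Roll 33
with lift at ±50 cm/s), 8 trials per condition, every trial a fresh unique
m-sequence except trial 2 of Roll 33, which is one shared sequence across
all neurons (uniqueness is enforced by redraw — the catalogue holds
finitely many circular shifts, so collisions would otherwise occur).
Optional per-frame drop probability marks dropped frames in the frame log;
the default is 0 because every retained trial under the protocol is clean by
construction of its QC rule.

# Kernel estimation

The estimator is the plain cross-correlation
`h(tau) = (1/M) * sum_i s_i * y(t_i + tau)` over the final `M = 255`
impulses, with `s_i` the impulse polarity, `t_i` the frame-onset sample on
a 1 ms grid, and `y` the binned spike train; lags span -200..600 ms. Only
the m-sequence polarity enters the regressor — constant-flow components
are excluded by construction. On noiseless linear responses this equals
`h (1 + 1/N) - sum(h)/N` exactly (the circular autocorrelation identity),
which the test suite asserts to 1e-9 for orders 3–8 using a 200 Hz frame
grid where onsets fall on exact 1 ms samples; at 165 Hz the 6/7 ms onset
spacing makes the identity approximate, and correctness there is covered
by parameter recovery on synthetic neurons. Normalisation by `M` is one
fixed choice among the many the arbitrary-units axis permits.

Per-trial correlations are averaged and smoothed with a Gaussian filter
("5 ms window" read as SD 5 ms, truncated at ±3 SD, edge-renormalised; a
narrower full-width-5 reading can be had by passing a different
`window_ms`). Six parameters are extracted per neuron-condition:

* amplitude — maximum over nonnegative lags;
* TTP — lag of that maximum (earliest on ties);
* half-width — distance between the interpolated 50%-of-maximum crossings
  bracketing the peak;
* decay — interpolated first crossing of `amplitude/e` after the peak,
  minus TTP;
* return to baseline — on a separate 25 ms-smoothed version of the mean
  correlation, the first lag after the peak that re-enters the baseline
  mean ± 2 SD band, minus TTP. The baseline is lags -200..-10 ms (the
  protocol never defines it; pre-stimulus lags are the only
  stimulus-independent span available), with an SD floor of 1e-6 of the
  amplitude so noiseless inputs have a finite band;
* spike rate — spikes during the 255 analysed impulses over their
  duration.

Responses with no positive peak return `NA` parameters flagged
`defined = FALSE` rather than silent zeros.

# LN validation

For each neuron, a kernel and a binned static nonlinearity (20
equal-occupancy bins over the generator signal; bin count and placement
are unstated in the protocol, and quantile bins keep occupancy balanced)
are fitted on the shared-condition trials *excluding* the shared trial.
The shared trial is then predicted — generator signal through the fitted
nonlinearity — and correlated (Pearson, over the final-255-impulse span)
with the reference: the summed spike trains of all *other* neurons on the
shared trial, smoothed with a centred 200 ms sliding mean. The prediction
is smoothed with the same sliding mean before correlating; smoothing only
the reference deflates the correlation for bandwidth reasons unrelated to
model quality (a switch disables this).

The shuffled-spike control repeats the whole procedure 20 times per neuron
with the training spike trains redrawn uniformly in time (spike counts
preserved), reporting per-neuron means and their median, which should be
~0. Two implementation details matter for that null and were chosen after
explicit bias analysis:

1. **Shuffle support.** Spikes are redrawn over the full trial, not just
   the stimulus presentation. The simulated trial extends 0.7 s past the
   last frame (so late response lags are observable); redrawing only
   within the presentation creates a rate cliff at the stimulus end that
   real trials do not have, which imprints trial-specific partial-sum
   structure on the shuffled kernels at long lags and biases individual
   neurons' control correlations by up to ±0.2 in either direction.
2. **Kernel baseline in the generator signal.** One m-sequence period sums
   to +1, not 0, so the cross-correlation estimator carries a flat offset
   of `mean_rate * (sum of signs) / M` at *every* lag. Convolved with the
   stimulus, a flat kernel offset becomes the stimulus's running-sign-sum
   envelope — stimulus-locked structure that is shared by every shuffled
   kernel and pushed the control median to ~+0.07. The prediction stage
   therefore references the kernel to its own mean across the lag grid,
   which cancels exactly this term. The correction applies identically to
   real and shuffled kernels; *reported* impulse responses remain plain,
   uncorrected cross-correlations.

With both choices, the control median across simulated datasets is
0.005 ± 0.024 (six independent replicates) while leave-one-out predictions
from real kernels reach median correlations of ~0.88–0.95 under the
default homogeneous generator — higher than recorded data, whose
neurons differ from each other and from any LN model.

# Inclusion rules and statistics

A neuron is excluded outright if its mean preferred-direction roll
response falls strictly below 80% of the previously reported mean
(`round(0.8 * 199) = 159` spikes/s; exactly 159 is kept — "below" is read
as strictly less). A neuron-condition is excluded if its mean rate over
trials is below 5 spikes/s, since a kernel cannot be estimated without
spikes. Any trial with a dropped frame is discarded whole. Both constants
live in configuration so the provenance of 159 stays visible.

Parameters are compared with an omnibus Kruskal–Wallis test (tie-corrected
H, chi-square p) across conditions, then pairwise two-sided Mann–Whitney U
tests — exact for tie-free samples of at most 12 per group, normal
approximation with tie correction otherwise; the protocol does not state
which variant it used — corrected by Benjamini–Hochberg within each
comparison panel (impulse-size, constant-roll, constant-lift families,
matching the per-panel letter displays; a single global family is a
configuration away). Percent change is
`100 * (median_experimental - median_reference) / median_reference`.
These delegate to `kruskal.test`, `wilcox.test` and `p.adjust`; the test
suite pins them to hand-enumerated oracles (H = 7.2 for {1,2,3}, {4,5,6},
{7,8,9}; exact p = 1/3 for {1,2} vs {3,4}; the BH step-up example) and to
a brute-force enumeration of the exact U distribution.

# Numerical choices and problem sizes

All spike processing is on a 1 ms grid with a floor binning convention;
frame onsets are mapped to samples with a 1e-6 ms epsilon so exact-integer
frame times do not fall into the previous bin. Crossings (half-width,
decay) are linearly interpolated; maxima break ties toward the earliest
lag. Gaussian smoothing truncates at ±3 SD and renormalises at the edges;
the 200 ms sliding mean shrinks its window at the edges. Convolutions use
FFTs, so identities hold to ~1e-12 rather than exactly.

The test suite runs the synthetic protocol at the protocol's full scale where the
property demands it (12 neurons x 8 trials for parameter recovery,
amplitude scaling and the shuffle null; 100 Monte-Carlo placements for the
rendered-sphere count) and at reduced scale (4 neurons x 4 trials)
elsewhere; those sizes are the package's choice of how much simulation a
routine check needs. The shuffle-null dispersion quoted above comes from
six full replicates run during development.

# Known limitations

* The generator's neurons are identical by default; recovered validation
  correlations are therefore optimistic relative to recordings.
* Return-to-baseline depends on the baseline-window convention; with the
  default short-tailed kernel it reflects noise-band re-entry (~40 ms)
  rather than the long (~100 ms) tails recorded in vivo, which would need
  the optional slow-tail kernel component.
* The exact stimulus sequences of the original study are not
  reconstructable: its polynomials, states and phases were never
  published. `load_recordings()` ingests the package's own CSV/JSON
  schema; deposited data would need a thin adapter at that boundary.
* Letter displays are a greedy clique cover — presentation plumbing, not
  a guaranteed-minimal labelling.
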