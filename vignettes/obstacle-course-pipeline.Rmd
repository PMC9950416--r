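---
title: "Methods: analyzing locomotion over a dynamically reconfigurable obstacle course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing locomotion over a dynamically reconfigurable obstacle course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rungwalk)
```

# The assay and the analysis problem

`rungwalk` implements the complete analysis pipeline for a shuttling assay
in which a rat crosses a 48 cm obstacle course of eight 2 cm steps spaced
by 4 cm gaps, filmed from the side (1280x680 px at 120 Hz by default). The
two interior "center" steps can be covertly switched between a locked
(*stable*) and a freely rotating (*unstable*) state, so the animal learns
about the state of the world only by touching it. The pipeline turns raw
video, event annotations, multichannel electrocorticography (ECoG) and
traced histological outlines into the study's quantitative measures:
crossing times, slip rates, approach posture, speed profiles and the
speedup index, response-type contingency statistics, step-locked evoked
potentials, and lesion volumes.

Because raw recordings of this kind are large and not generally
redistributable, the package pairs every analysis stage with a
synthetic-data generator that emulates the rig with known ground truth.
The generators are first-class, tested code: every fixture used by the
test suite and the acceptance script is produced by them at run time.

# Synthetic data: what is emulated, and what is not

`generate_crossing()` produces a kinematically consistent crossing: a nose
trajectory sampled at the camera frame rate, forelimb contacts on each
step (the forepaw lands when the nose carries a configurable lead over the
step's near edge), later hindlimb contacts (when the head is well past the
next step — exactly the events the head-position constraint must reject),
and optional slips into gaps. Posture at the first manipulated step is
drawn from state-conditional Gaussians whose defaults reproduce the
group-level observations on the real assay: nose progression 0.77 ± 0.93 cm
and height 0.61 ± 1.02 cm on stable trials, −0.25 ± 0.73 cm and
−0.25 ± 0.69 cm on unstable trials, and a ~20% slow-down after an unstable
center step. A Gaussian family is an assumption — the real nose positions
were reported as normally distributed, which is what motivates it. The
jump strategy (probability `p_jump`) omits all center-step contacts, as
jumping animals' paws never touch the manipulated steps.

`render_frames()` composites a high-contrast body over a static
background: an ellipse, a triangular nose protrusion whose apex *is* the
ground-truth nose point, and paw disks during contacts whose intensity
differs by side (the basis of the brightness-histogram side classifier).
The appearance is deliberately minimal: the tracker relies only on
segmentation geometry, so photorealism would add nothing the pipeline can
measure. What the renderer does **not** emulate — fur texture, shadows,
motion blur, occlusions by the apparatus, step rotation physics — is
exactly what a pass on these fixtures cannot certify about real footage;
the fixtures validate the geometry of the algorithms, not their robustness
to photometric nuisance.

`synthesize_roi_traces()` is the lightweight alternative: it writes each
contact directly as a smoothed rectangular pulse on the matching ROI
trace. Baseline noise is *bounded* (uniform) rather than Gaussian: with
the detector's robust default threshold (five times the median absolute
first difference), a bounded noise floor guarantees that no baseline
noise step can cross the threshold, which mirrors the near-noiseless
background-subtracted activations of the real rig while keeping the
zero-false-positive property exact on fixtures.

`synthesize_ecog()` injects per-condition evoked-potential templates at
the exact sample of each contralateral-paw step event: a −100 µV
negativity peaking 10 ms after contact for stable steps, and a −300 µV
negativity peaking at 70 ms followed by a slow positive rebound for
unstable steps. Template widths (6 and 15 ms Gaussian sigma) and the
rebound time constant (150 ms) are generator choices — the source
observations fix peak amplitude and latency, not the full waveform. Noise
is white (50 µV) plus 1/f (20 µV) by default. The camera strobe is a
square wave whose falling edges mark frame exposures, with per-frame
hardware counters (wrapping at 2^16) — the same synchronization contract
as the real acquisition. The acquisition rate is 1 kHz by default; all
analysis windows are specified in milliseconds and converted at run time,
so nothing depends on that choice beyond the Nyquist requirement for the
50 Hz low-pass.

`generate_lesion_stack()` cuts cylinders, boxes and ellipsoids into
100 µm serial sections, sampling each cross-section at the slice center
as a traced polygon — phantoms whose closed-form volumes calibrate the
Cavalieri estimator.

`simulate_ethograms()` builds response-interval cohorts with configured
per-group counts of halting-first / halting-dominant / over-one-third
outcomes; it exists so the contingency statistics can be exercised on
ethograms rather than on bare counts.

# Tracking

Background is the pixel-wise temporal median of subsampled frames — with
the animal present at any pixel in fewer than half the samples, the
median recovers the empty arena exactly. Segmentation thresholds the
absolute difference from the background and labels 8-connected components
(run-based union-find); the largest component above a minimum area is the
animal. The body ellipse comes from second-order image moments (for a
filled ellipse the principal standard deviations are half the semi-axes),
and the nose is the mask pixel with the largest signed projection on the
major axis, oriented by the recent centroid displacement (falling back to
the expected travel direction before movement is seen). Image coordinates
are 0-based, origin top-left, y down; conversions to centimeters negate y
so heights are reported upward.

Open choices resolved here: thresholding is applied *after* background
subtraction (absolute difference, then threshold); connectivity is
8-connected; the segmentation threshold and minimum component area are
parameters with defaults calibrated on rendered fixtures, as the
procedure itself fixes no values.

# Event detection

Crossings are maximal runs of valid poses (gaps up to 0.25 s tolerated)
whose endpoints lie on opposite sides of the course midline. A paw-step
moment on a step ROI is the **first** supra-threshold peak of the
activation trace's first difference inside the crossing. The default
threshold is five times the median absolute first difference of the
trace; a local maximum must strictly exceed its left neighbor (plateaus
resolve to their earliest frame), and candidate peaks closer than
`min_gap` frames (default 10) merge into the earlier one, because noise
on a pulse's rise and plateau can split a single activation into
neighboring derivative maxima.

The head-position constraint then separates forelimb contacts from
hindlimb/tail artifacts: a candidate is accepted only when the nose at
that frame lies before the near edge of the *next* step in travel
direction. The "head" is operationalized as the nose (the body centroid
is available behind the `use` switch). Slip candidates on gap ROIs relax
the head constraint entirely — the screen is designed for zero false
negatives and the surplus is resolved by a human verdict table joined via
`apply_slip_labels()`, mirroring the semi-automated workflow of the
original assay. Paw side is classified from per-frame brightness
histograms (32 bins) clustered by seeded K-means with 10 restarts;
cluster-to-side mapping comes from a partial label vector, which is also
the manual-correction mechanism.

# Behavioral measures

Crossing time is `(end − start) / frame rate`; a session meets the
performance criterion when its mean is strictly below 8 s per crossing
(one second per obstacle). Transition sessions split into the last 20
trials before the change and the remainder from the change onward.
Slips-per-crossing is confirmed slips divided by crossings, with optional
limb filters.

Posture at the first manipulated step is the nose position at the
detected contact frame, as progression (signed along travel) and height,
relative to a reference point. The package default references the near
edge of the first manipulated step and the per-animal mean nose height;
the end-to-end recovery analyses instead pass the generator's known
baseline height as the explicit reference, which puts recovered means
directly on the generator's scale. History conditioning
(`prev_two_states`) keeps only trials whose two predecessors share a
state — mixed histories are excluded, matching the both-stable vs
both-unstable comparison.

Speed profiles divide the course into eight equal segments (one per
step-plus-gap pitch; the segment width is a free choice), take segment
length over traversal time from boundary-crossing times interpolated on
the nose trajectory, and subtract the per-trial mean approach speed
(segments strictly before the first manipulated step). The baseline is
per-trial rather than per-session because the procedure measures "for
every trial" the segment speeds; a per-session baseline is available by
averaging externally. The speedup index is the sum over segments of mean
stable minus mean unstable baselined speed — exactly antisymmetric under
exchanging the two sets, with missing segments excluded pairwise. An
animal is a *jumper* when its probability of skipping both center steps
exceeds 0.5 (the exclusion rule needs a cutoff; the reported exclusions
imply but do not state one), and jumpers are excluded from
randomized-protocol posture analyses.

# Ethogram statistics

Response intervals (compensation / investigation / halting) are aligned
to first contact at time zero and must not overlap; overlapping
annotations are rejected at load with a repair suggestion rather than
silently truncated. Outcomes: the category of the earliest interval; the
dominant category by total duration within a window (default 5 s —
"the first few seconds" is not quantified, so the window is a parameter),
clipping at the window edge, ties to the earliest onset; and the halting
fraction of annotated time, tested strictly against 1/3.

The 2x2 chi-square with Yates correction is implemented from the closed
form `N(max(|ad−bc| − N/2, 0))² / (r1 r2 c1 c2)` with the continuity
correction floored at zero, so identical rows give exactly zero; it is
cross-checked in the tests against `chisq.test(correct = TRUE)`. The
unpaired Student's t-test is implemented in its pooled summary-statistics
form (mean, SD, n per group) because the published group tables are the
input; the raw-sample overload reduces to the summary form algebraically.

# ECoG evoked potentials

Frame-sample correspondence comes from matching hardware frame counters
to the falling edges of the camera strobe (threshold at half the signal
range, one-sample debounce); dropped frames leave holes rather than being
interpolated, and counter wraparound is unwrapped monotonically. Epochs
are 750 ms (250 pre / 500 ms post contact). Filtering is a 4th-order
Butterworth low-pass at 50 Hz applied forward and backward — zero phase,
squared magnitude response — with odd-symmetric reflective padding (300
samples by default) so the IIR transient of the two passes stays out of
short epochs. Baselining subtracts the per-channel mean of the first
250 ms; it is idempotent and commutes with the linear filter. Channels
whose broadband variance exceeds 10x the median channel variance (or
whose impedance exceeds a limit, when provided) are excluded — the damage
criterion describes a symptom, so the factor is a parameter. Condition
averages carry the trial count and a 95% pointwise normal band of the
mean, and peaks are the windowed extremum of the requested polarity on
the channel-pooled (or single-channel) average.

In simulation studies, inter-trial spacing matters: the unstable
template's slow positive rebound (150 ms time constant) extends for
hundreds of milliseconds, so trials closer than ~1 s leak rebound tail
into the next trial's epoch and baseline. The packaged analyses space
trials 2 s apart, which is also the realistic pace of consecutive
crossings.

# Lesion volumetry

Volume is the Cavalieri estimate: the absolute shoelace area of each
traced outline times the 0.1 mm slice thickness, summed per hemisphere;
outlines flagged as holes subtract. Self-intersecting outlines raise an
error instead of contributing a misleading signed area. Inputs are
assumed to be pre-aligned traced polygons — section alignment is an
imaging step outside the computational scope, and sagittally sectioned
material is handled identically because the estimator is
orientation-agnostic. A lesion is "large" when the total strictly
exceeds 15 mm³. On phantoms the estimator's error is O(thickness) (plus
the polygonal approximation of curved cross-sections, <0.2% at 64
vertices), verified by a convergence suite.

# Problem sizes and determinism

The packaged analyses and tests run on a scaled camera (4 px/cm,
256x136 px, 50 Hz) with 14-trial animals, 40-trial ECoG sessions and
single rendered crossings — sizes chosen so the whole suite exercises
every stage end to end in minutes on one core while keeping Monte-Carlo
tolerances (3 SE plus the pixel/frame quantization grain) meaningful. All
randomness flows through explicit integer seeds via an RNG-state-preserving
`with_seed()`, so identical seeds reproduce bit-identical fixtures.

# Known limitations

* The tracker is single-animal and assumes the animal is the largest
  moving object; it does not handle occlusion or multi-blob merges beyond
  largest-component selection.
* Slip confirmation is semi-automated by design: the screen is
  exhaustive, and final verdicts come from an annotation table.
* The ECoG module measures time-domain evoked potentials only — no
  spectral analysis, source localization or unit activity.
* Synthetic fixtures validate algorithmic geometry and statistics; they
  cannot certify robustness to photometric or physiological artifacts
  absent from the generators (see above).
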