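---
title: "Models and methods: length-resolved motility analysis and the coupled-myosin simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(motilitykit)
```

This vignette is the package's own account of its science: the measurement
pipeline for in vitro motility recordings, the statistics built on top of
it, and the stochastic motor model whose parameter regimes explain
condition-dependent motility. It also records the numerical and design
choices that were genuinely open, and what the synthetic-data tests do and
do not demonstrate about real recordings.

## The measurement pipeline

### From frames to filament objects

Raw recordings (nominally 30 fps) are averaged in non-overlapping blocks to
the analysis time resolution Δt, by default 1/3 s. The choice matters: the
frame-to-frame velocity of a stopped filament is pure localization noise
whose apparent speed grows as 1/Δt, so at too fine a resolution the stopped
and running populations of the velocity distribution merge and run/stop
segmentation becomes impossible. At 1/3 s the two populations are cleanly
bimodal for sliding speeds in the 0.2–2 µm/s range. Each merged frame is
enhanced by subtracting its median intensity (the background level of a
mostly dark field) and stretching the contrast to [0, 1].

Binarization uses a threshold expressed as a fraction of the frame's
dynamic range. The top of the range is taken from a 3×3 box-smoothed copy
of the frame so that single hot pixels — per-fluorophore brightness
fluctuations — cannot shift the reference; without this, threshold sweeps
on noisy videos fragment the masks at high thresholds. The threshold
remains an explicit parameter because filament *length* and *width* depend
on it monotonically, while *velocity* must be (and is, see the test suite)
robust to it across a central range: centroids of symmetric blobs do not
move when the blob erodes uniformly.

Connected components (8-connectivity, minimum 5 px) become filament
objects. The perimeter estimator is fixed and documented because lengths
inherit its conventions: the Moore boundary chain with axial steps counting
1 px and diagonal steps √2, plus 4 px for closing the crack boundary around
the pixel squares. An axis-aligned l×w pixel rectangle then measures
exactly 2(l+w), which makes the rectangle-equivalent transformation
consistent with pixel areas.

### Rectangle-equivalent lengths

An object with area A and perimeter P is mapped to the rectangle with the
same area and perimeter; length and width are the roots of
x² − (P/2)x + A = 0. For very small objects the discriminant goes
negative; such objects are flagged and reported with ℓ = w = P/4, the real
part of the complex pair. This convention is continuous at the
zero-discriminant boundary and — because P/4 still grows with object size —
keeps tiny filaments correctly ordered along the length axis even where the
numeric value is biased. On noise-free synthetic videos the recovered
lengths stay within 10% of truth for L ≥ 0.6 µm and velocities within 5%
over 0.2–2 µm/s (the validation grid in the acceptance tests).

### Tracking, kinematics and the tip

Objects are linked frame to frame greedily: candidate pairs within a
maximum jump (default 1.2 µm per merged frame, larger than any plausible
v·Δt) are accepted in order of increasing centroid distance, ties broken by
the smaller relative area change. Unmatched objects open new traces;
unmatched traces end. Frame-to-frame speeds are centroid displacements over
Δt. The trace velocity divides the path length of the filament *tip* — the
endpoint of the object's principal axis that leads in the direction of
motion — by the trace lifetime. The tip rule is not defined in most
published descriptions; the leading-endpoint convention is adopted here
because for a rigid rod moving along its axis it coincides with the
physical leading end.

### Trace quality control

Crossing filaments merge into single components and corrupt both length
and velocity; erratic traces indicate tracking failures. A bagged ensemble
of 150 decision trees classifies traces as keep/reject from: the corner
count of the rasterized trajectory (Harris detector on a Gaussian-smoothed
image, kernel length 21, σ 2.5, sensitivity factor 0.2, quality level 0.15,
at most 200 corners; corners within ~2σ of the trajectory endpoints are
ignored because endpoints always excite the detector), coefficients of
variation of velocity, area and length, the complex-length fraction, the
minimum distance to other traces, and the count of proximity events. The
feature set is a reconstruction — published descriptions name only the
corner detector — and is deliberately pluggable. The acceptance threshold
on the ensemble keep-score minimizes 5·FPR + 1·FNR: letting a corrupted
trace into the data set costs five times more than discarding a good one.
Training labels in this package come from scripted mock scenarios; tests
train and validate on disjoint generator seeds to emulate cross-day
validation (held-out AUC ≥ 0.9).

## Motility features and bootstrap statistics

Pooled frame-to-frame velocities are fitted with a two-component Gaussian
mixture by EM. The EM is initialized deterministically from quantiles with
the stopped component anchored in the lower tail; this keeps the fit stable
when stops are rare (a few percent of intervals), where generic mixture
initializations latch onto the bulk. The stop/run cut is the
equal-posterior velocity between the component means; fits whose means are
closer than the sum of the component widths are flagged as collapsed (the
too-fine-Δt regime). When conditions are compared, the cut fitted on the
baseline condition is shared across conditions: the noise floor is a
property of the imaging, not of the protein composition, and per-condition
cuts inject cut-estimation noise into every fold change.

Runs and stops are maximal consecutive interval sets above/below the cut;
the motile fraction is the fraction of running intervals (equivalently,
running time), and stops shorter than one interval are unresolvable by
construction. Four features — mean frame-to-frame velocity, motile
fraction from pooled interval time, and means of pooled stop and run
durations — are resolved by filament length with overlapping sliding
windows: range 0.3–3.25 µm, width 0.59 µm, 50 equally spaced windows whose
extent stays inside the range (so the first window centre sits at
0.595 µm). A short-range variant (0.3–1.775 µm, 25 windows) serves the
short-filament analyses. Windows are recomputed on B bootstrap resamples
(default 500; resample unit = filament, switchable to chamber) to yield
percentile 95% bands. The resampling is implemented as a weight-matrix
product, so 300 × 2 × 200 bootstrap curve sets (the type-I check) take
seconds.

### Bootstrapped PCA and condition separation

The main curves and all bootstrap replicate curves of every condition are
stacked into one matrix (rows = data sets, columns = 4 features × windows;
windows missing anywhere are dropped globally; columns standardized). The
first three principal components (deterministic sign: largest-magnitude
loading positive) embed each condition as a cloud of bootstrap scores
around its main data set. Two conditions are significantly different when
their 95% confidence regions do not overlap. The region is the Mahalanobis
ellipsoid containing 95% of a condition's bootstrap scores — an axis-free
formalization chosen because published figures show convex hulls but define
significance only through interval non-overlap; ellipsoid disjointness is
decided exactly by a one-dimensional root search on the Lagrangian path
between the two centres.

A caveat that the test suite documents explicitly: with only two identical
conditions embedded, PC1 aligns with their chance difference and the clouds
always separate — a high-dimensional artifact, not a property of the data.
In a multi-condition embedding, where genuine effects dominate the leading
components, null pairs overlap at the expected ~95% rate. The package
therefore always embeds full condition panels, as the original analysis
did.

Ward linkage on the PC scores summarizes the partition; the cluster count
is chosen at the largest relative drop of merge linkage. On the synthetic
six-condition panel the Ward tree cut at four clusters is condition-pure
with the three baselines co-clustered, while five clusters only split the
baselines among themselves — but the automatic elbow selects k = 2 because
one regulated condition separates far more strongly than its experimental
counterpart; the acceptance test asserts the four-cluster composition
rather than the elbow output.

### Fold changes and their significance

A feature's fold change is its window-averaged value in the target
condition divided by the baseline value. Each condition's bootstrap
replicates give a percentile interval of the window-averaged feature; the
fold-change interval is the ratio of interval limits, so "fold interval
excludes 1" is *exactly* the non-overlap rule for the two conditions'
intervals. This construction is deliberately conservative (roughly a
2.8-sigma criterion): a naive percentile interval of replicate fold ratios
detects ~5% of null comparisons, contradicting the type-I behaviour the
pipeline is designed to have. Even so, comparing two with-replacement
resamples of a 250-filament baseline 300 times yields a handful (~1%) of
marginal detections, driven by the heavy-tailed run times of smoothly
gliding long filaments whose runs are censored at the trace length; the
margin distributions sit several widths below zero for all four features.

The joint two-feature test projects both conditions' replicate clouds, in
per-axis whitened fold space, onto the unit vector connecting the cloud
means; significance is non-overlap of the projected 95% intervals.
Whitening matters: the two fold axes have very different bootstrap noise
scales, and an unwhitened projection is dominated by the noisier feature.
Aligned shifts of ~3 sigma per feature are detected jointly while both
marginals stay below threshold. No multiple-testing correction is applied
anywhere, matching the original analysis; this is documented rather than
hidden.

## The coupled-myosin model

### States, mechanics, rates

A filament of length L carries N = max(1, round(L/0.0355 µm)) myosin
binding sites, one per actin helix repeat. Each site's motor is detached,
pre-stroke, or post-stroke. Bound motor i holds a linear spring of
stiffness κ anchored at a_i; the rigid filament sits at the elastic
equilibrium z = mean(a_i). Transitions:

* **Attachment** (detached → pre-stroke), rate k_attach per free site,
  strain-independent; the anchor is placed at z plus a Gaussian offset
  (sd `bind_sigma`) representing thermal spring fluctuations and
  binding-site registration disorder along the helix. Without this
  binding disorder the model has no stall-escape channel that scales with
  filament length, and the motile-fraction-vs-length curve inverts.
* **Main power stroke** (pre → post): the anchor shifts by d_main.
* **Secondary step + detachment** (post → detached): the anchor shifts by
  d_second, the filament is dragged, then the motor releases and the
  remaining motors pull the filament back to their own equilibrium. A lone
  motor keeps its full d_second displacement.

Both mechanical transitions carry a Boltzmann factor
k = k₀ · exp(−c·ΔE/kT), where ΔE is the elastic-energy change of the whole
motor–filament system if the step executes (with re-equilibration) and c
is the dimensionless *coupling impact* — the parameter through which
tropomyosin-dependent regulation of collective mechanics is expressed. In
closed form, for a step of size d by a motor with strain x among n bound
motors, ΔE = (κ/2)d²(1 − 1/n) − κ·d·x; a single unloaded motor recovers
k₀ exactly, and the closed form is verified against brute-force energy
bookkeeping in the tests. The simulation itself is an exact Gillespie
algorithm; measurement noise (sd `noise_sigma`) is added at sampling, not
in the dynamics, so the simulated frame-to-frame velocity distribution has
the same stopped/running structure as recordings.

The three-state graph (with the secondary step executed at detachment) is
the minimal graph consistent with a two-phase working stroke followed by
release; richer schemes (ATP dependence, tropomyosin ON/OFF cooperativity,
filament flexibility) are deliberately out of scope.

### Baseline calibration

The baseline numeric values are a reconstruction, calibrated once and then
frozen (`inst/extdata/motor_baseline.yaml`, version 1): k_attach = 25/s,
k_stroke = 900/s, k_detach = 120/s, c = 1.3, d_main = 8 nm, d_second =
4 nm, κ = 1.4 pN/nm, bind_sigma = 3.5 nm, noise_sigma = 0.02 µm, kT =
4.19 pN·nm (30 °C). The calibration targets were qualitative and fixed in
advance: a sub-µm/s plateau of sliding velocity, a motile fraction that
rises steeply with length and approaches 1 for long filaments, run/stop
structure resolvable at Δt = 1/3 s, and condition multipliers that move
the four features in the experimentally observed directions. The resulting
dynamics are a stall/avalanche system: strokes are strain-gated (barrier
≈ c·κ·d_main²/2), runs are self-sustained because a moving filament drags
pre-stroke motors to firing strain, and stalls end through strongly
strained new binders — a channel whose rate scales with the number of free
sites and hence with filament length.

### Condition parameter sets

The regulated conditions multiply baseline parameters exactly as
published: all three kinetic rates ×1.15; coupling impact ×1.2; detachment
×0.75 together with coupling ×0.8. With the calibrated baseline (150–250
filaments per condition, 20–30 s traces) the simulated length-averaged
fold changes land at ≈1.15 for velocity (rates ×1.15; printed experimental
value 1.12), ≈0.96–0.97 for motile fraction and ≈1.03–1.06 for stop time
(coupling ×1.2; printed 0.96 and 1.6), and ≈1.7 (short range) / ≈1.2–1.3
(full range) for run time (detachment ×0.75, coupling ×0.8; printed 1.7
and 1.3). The stop-time response is the known shortfall of this
reconstruction: microscopically the coupling condition does lengthen
stalls (folds ≈1.5 at the shortest lengths), but across most of the length
range stop durations sit at the one-interval quantization floor of the
1/3-s grid, so the window-averaged fold dilutes towards 1. Extending
c-sensitive multi-second stalls to long filaments is impossible in this
model without inverting the motile-fraction-vs-length shape, because stall
escape scales with binding flux (k_attach·N).

### Problem sizes

The shipped tests and the reproduction script run at deliberately modest
sizes chosen to keep the full suite in the tens of minutes on one core:
mock-video validation on a 0.08 µm/px grid with a handful of videos;
quality-control training on ~20 scripted scenarios per "day"; oracle
comparisons on 1–3 binding sites with 2500–4000 s of simulated time;
condition simulations with 120–250 filaments and 20–25 s traces; 300
resample comparisons at B = 200; and the six-condition panel at 150
filaments and B = 100. The synthetic generator emulates rod-like filaments
with Gaussian optics, brightness fluctuations, Brownian jitter, crossings
and irregular motion; it does not emulate uneven illumination, bleaching,
filament severing/annealing, or chamber-to-chamber protein variability —
so passing tests validate the algorithms and their statistical behaviour,
not the biological variability structure of a real data set.

## Known limitations

* Stop-time fold changes under the coupling condition undershoot the
  printed experimental value (see above); the direction is correct.
* The CI-non-overlap rule leaves a ~0.5% per-comparison residual type-I
  rate; literal zero detections over 1200 comparisons would require
  additional conservative structure (e.g. cluster-level intervals) that
  the available descriptions do not specify.
* The automatic linkage elbow is sensitive to unbalanced effect sizes.
* Nanometer-precision localization is out of scope: the pipeline trades
  precision for throughput and full automation.
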