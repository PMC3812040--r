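# motilitykit

Quantitative analysis of the in vitro motility assay — surface-immobilized
myosin motors propelling fluorescently labeled actin filaments — together
with a stochastic model of mechanically coupled myosins that explains
condition-dependent differences in filament sliding.

The package is aimed at muscle biophysicists who record motility videos (or
want to simulate them) and need length-resolved, statistically defensible
comparisons between protein conditions (e.g. actin and tropomyosin isoform
combinations).

## What it does

**Video analysis.** Multi-frame fluorescence stacks are merged to the
analysis time resolution Δt (default 1/3 s), binarized, and segmented into
connected components. Each object is summarized by its area *A* and
crack-boundary perimeter *P*, and transformed into the rectangle with the
same area and perimeter: the filament length ℓ and width *w* are the roots
of

x² − (P/2)·x + A = 0,  ℓ ≥ w,

with complex solutions (tiny objects) flagged and reported as ℓ = w = P/4.
Objects are tracked greedily by centroid distance and area; per trace the
frame-to-frame speeds v_f2f = |Δcentroid|/Δt and the trace velocity
v_trace = (tip path length)/(lifetime) are computed.

**Trace quality control.** A bagged decision-tree ensemble (150 trees)
rejects traces with filament crossings or irregular motion, using corner
counts along the rasterized trajectory (Harris detector; kernel 21,
σ = 2.5, sensitivity 0.2, quality level 0.15, ≤ 200 corners), coefficient-of-
variation features, and proximity to other traces. The acceptance threshold
minimizes 5·FPR + 1·FNR on a validation day.

**Motility features.** Pooled v_f2f samples are decomposed into stopped and
running populations by a two-Gaussian EM fit; the equal-posterior cut
segments each trace into runs and stops. Four features — mean sliding
velocity v̄, motile fraction f_mot, stop time τ_s, run time τ_r — are
resolved by filament length with sliding windows (0.3–3.25 µm, width
0.59 µm, 50 windows) and equipped with percentile confidence bands from 500
bootstrap resamples of filaments.

**Statistics.** The main and bootstrap curves of all conditions are stacked
into one standardized matrix and embedded in the first three principal
components. Two conditions differ significantly when their 95% Mahalanobis
ellipsoids of bootstrap scores do not overlap; Ward clustering of the
scores summarizes the partition. Length-averaged fold changes (with the
confidence-interval non-overlap rule), a joint two-feature test, and a
type-I self-check by comparing baseline resamples complete the toolbox.

**Motor model.** An exact Gillespie simulation of a rigid filament with one
myosin binding site per actin helix repeat (0.0355 µm). Motors cycle
detached → pre-stroke → post-stroke → detached; the main power stroke
(8 nm) and the secondary pre-detachment step (4 nm) shift the motor's
anchor, the filament re-equilibrates to the mean anchor position, and
mechanical rates carry a Boltzmann factor exp(−c·ΔE/kT) in the elastic
energy change ΔE — the coupling impact *c* is the tunable regulation
parameter. Condition parameter sets multiply the baseline rates (all rates
×1.15; coupling ×1.2; detachment ×0.75 with coupling ×0.8).

## Worked example

```r
library(motilitykit)
set.seed(1)

# simulate a baseline condition and a condition with stronger coupling
base <- motor_params()
rb <- simulate_condition(base, n_filaments = 100, T_total = 20)
rg <- simulate_condition(apply_multipliers(base, condition_params("gammaA-TmAlpha")),
                         n_filaments = 100, T_total = 20,
                         cut = attr(rb, "cut"))

cb <- bootstrap_curves(rb, B = 200)
cg <- bootstrap_curves(rg, B = 200)
fold_changes(cg, cb, "f_mot")
#> # A tibble: 1 × 6
#>   feature  fold lower upper significant margin
#>   <chr>   <dbl> <dbl> <dbl> <lgl>        <dbl>
#> 1 f_mot   0.974 0.966 0.983 TRUE        0.0172
```

The motile fraction of the stronger-coupling condition is 0.974-fold the
baseline value (interval 0.97–0.98, excluding 1): coupling makes filaments
pause more.
`autoplot(cb)` draws the four length-resolved feature curves with their
confidence bands; `pca3()`, `pairwise_separation()` and
`hcluster_embedding()` reproduce the condition-separation analysis.

A ground-truth mock video for validating the image pipeline:

```r
sp <- filament_specs(length = c(1, 2), velocity = c(0.5, 1),
                     x0 = c(10, 25), y0 = c(10, 25), heading = c(0.3, 2))
truth <- build_paths(sp, duration = 6, frame_rate = 6)
video <- render_video(truth, optics_spec(psf_sigma = 1.5, pixel_size = 0.08))
res <- analyze_video(video$stack, native_dt = 1 / 6, bw_threshold = 0.5,
                     pixel_size = 0.08)
res$traces[, c("trace_id", "L_um", "v_trace_um_s")]
#> # A tibble: 2 × 3
#>   trace_id  L_um v_trace_um_s
#>      <int> <dbl>        <dbl>
#> 1        1  1.07        0.499
#> 2        2  2.16        0.998
```

Both scripted filaments are recovered with lengths within ~8% and trace
velocities within 0.2% of the ground truth.

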