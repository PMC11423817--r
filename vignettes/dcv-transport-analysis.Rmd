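---
title: "Quantifying dense-core vesicle transport from kymograph tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dense-core vesicle transport from kymograph tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcvmotility)
```

## The problem

Dense-core vesicles (DCVs) carry neuropeptides and insulin-like peptides
along axons, pulled toward microtubule plus ends by kinesins (anterograde)
and toward the cell body by cytoplasmic dynein (retrograde). Time-lapse
imaging of a labelled axon collapses naturally into a *kymograph* — a 2-D
image of position along the axon versus time — in which moving vesicles
appear as sloped lines, stationary vesicles and vesicle clusters as
vertical lines. Automated tracers turn a kymograph into per-particle lists
of (frame, pixel) coordinates. `dcvmotility` takes those lists and produces
the standard motility quantities: per-direction velocity statistics, track
behaviour classes, displacement distributions, Gaussian-mixture velocity
decompositions, between-condition comparisons, and cluster-interaction
scores. Because raw imaging data for this kind of study is rarely
deposited, the package also ships a ground-truthed simulator that generates
tracks with the statistical structure the analysis assumes, in the exact
input formats, so every stage can be validated against planted truth.

## From tracer output to calibrated tracks

Tracks arrive either as a long CSV (`kymograph_id, track_id, t_frame,
x_pixel`) or as JSON mapping kymograph → track → `[t, x]` pairs, the shape
of per-track exports from deep-learning kymograph tracers. Ingest does
three things, in order:

1. **Duplicate repair.** A tracer occasionally reports two positions for
   one particle at one frame, which is physically impossible; the positions
   are replaced by their arithmetic mean. The operation is idempotent and
   preserves the set of frames.
2. **Calibration.** Frames become seconds (`frame_interval_s`, default
   0.156 s) and pixels become micrometres (`pixel_size_um`, default
   0.1074 µm), signed so that anterograde displacement is positive. The
   orientation flag `plus_end_right` is per-kymograph configuration,
   defaulting to plus ends on the right. The default pixel size is chosen
   so that the conventional 0.6444 µm movement threshold equals an even
   6 pixels; it is exposed because instruments differ.
3. **Gap retention.** Frames dropped during image stabilization leave time
   gaps in tracks. Gaps are kept, never interpolated: all downstream
   windows are defined in *time*, so a gap simply stretches a window.

## Sliding-window segmentation

Each calibrated track is split into maximal **anterograde (A)**,
**retrograde (R)** and **stationary (S)** segments. For point *i*, let
*j(i)* be the first point at least `tau_w` seconds later (default 2 s). The
windowed displacement *d* = *x[j] − x[i]* labels the point:

* A if *d* ≥ `theta` (default 0.6444 µm),
* R if *d* ≤ −`theta`,
* S otherwise.

Trailing points with no complete window inherit the last computed label;
tracks shorter than one window are labelled from their net displacement.
Maximal runs of one label become segments, and the first point of each new
run also closes the previous segment, so segment displacements telescope
exactly to the net track displacement. Segment velocity is displacement
over duration, signed. Moving segments with fewer than `min_points` points
(default 4) are excluded from *velocity statistics only*; classification
and coverage always see every segment.

Two genuinely open design points are resolved as follows and are
configurable:

* The "2 s time threshold" is implemented as the **duration of the sliding
  window**, not a minimum segment duration — the natural reading of a
  sliding-window rule, and the one that makes frame gaps unproblematic.
* Windows look **forward**. Centered or backward windows change labels
  only within `tau_w` of run boundaries; forward windows are simple,
  deterministic and directly checkable against a brute-force enumeration
  oracle, which the test suite does on thousands of random tracks.

The minimum detectable speed is `theta / tau_w` = 0.3222 µm/s at the
defaults: a slower drift never accumulates a window displacement of
`theta`.

### Boundary smearing — a known, quantifiable bias

The window rule fires as soon as the *forward* window reaches `theta`, so
the A/R label turns on up to `tau_w − theta/v` **before** a run really
starts (while the vesicle still pauses) and turns off `theta/v` before it
ends. A pause-bounded run of true speed *v* and duration *T* is therefore
recovered with speed approximately

$$ \hat v \;=\; \frac{vT - \theta}{T + \tau_w - 2\theta/v}, $$

a **downward** bias of order \((v\,\tau_w - \theta)/T\). For a 2 µm/s run
of 20 s that is about −0.17 µm/s; shorter runs are hit harder. Segments
that start at track birth or end at track exit are unbiased (the trailing
labels inherit), which is why tracks that move without pausing are
recovered essentially exactly while pause-interleaved tracks are
under-read. This is a property of the published windowing rule itself, not
of this implementation — the same bias is present in any velocity table
produced by the rule — and the acceptance suite quantifies it: recovered
per-direction mean speeds sit a few hundredths to ~0.2 µm/s below the
planted means, with the deficit concentrated in pause-bounded segments.
Nothing in the package corrects for it, deliberately: the goal is to
reproduce the published procedure, bias included.

## Motility statistics

* **Velocity summaries** per condition × direction: n, mean, s.d. (n−1),
  median, max of speed magnitudes — the usual motility-table row. Speeds
  are reported as magnitudes per direction while segment velocities stay
  signed internally, matching both common presentation conventions.
* **Track classes.** A track is `stationary_only` (no moving segment),
  `moving_no_pause` (moving, never stationary) or `moving_with_pause`
  (both); the categories partition the tracks, and participation fractions
  (≥ 1 A segment; ≥ 1 R segment) are reported alongside. Classification
  uses *all* segments — the short-segment filter applies to velocity
  calculations only.
* **Displacement within N frames** (N ∈ {5, 10, 20, 40} by default): every
  start index with a partner exactly N frames later contributes
  |Δx|; gapped windows are skipped. Pooled overlapping windows are the
  default; a per-track-maximum mode ("reached a given displacement") is
  available because the conventional phrasing supports either reading.
* **Origin alignment** translates every track to (0, 0) for the classic
  all-tracks displacement plot; no resampling.
* **Axon-position stratification** assigns tracks to half-open distance
  bins `[lo, hi)` (edge values start the upper bin; the final top edge is
  closed so the observed maximum is not orphaned), defaulting to four
  equal-width bins over the observed range.
* Velocity histograms conventionally use **100 bins**; the phrase "bin
  size of 100" in the field is ambiguous between bin count and bin width,
  and bin count is implemented (configurable) since a 100-unit-wide bin
  would be degenerate on µm/s-scale data.

## Mixture decomposition and comparisons

Per-direction speed distributions are decomposed into 1-D Gaussian
mixtures fitted by EM, written in the package rather than delegated so
that every numerical choice is explicit (an independent mixture
implementation, `mclust`, is used as a cross-check in the unit tests):

* initialization at spread quantiles plus jitter, pooled variance,
  near-uniform weights; best of `restarts` = 10 random starts;
* log-space responsibilities (log-sum-exp) for numerical stability;
* component variances clamped at `var_floor` = 1e-4 (µm/s)² so a component
  cannot collapse onto a point;
* convergence at relative log-likelihood change ≤ 1e-6, cap 500
  iterations; the per-iteration log-likelihood trace is returned and the
  tests assert it is non-decreasing;
* fits are refused when n < 3K, and the AIC uses 3K − 1 free parameters
  (K means, K s.d.s, K − 1 weights): AIC = 2(3K − 1) − 2 logL. K is chosen
  by minimizing AIC over K = 1…`K_max` (default 6), ties toward smaller K.

Conditions are compared per direction with the two-sample
Kolmogorov–Smirnov test (via `stats::ks.test`; asymptotic p by default,
exact optional for small samples), over all unordered pairs. Multiplicity
is handled by Holm adjustment by default (Bonferroni and none are
available). A Tukey–Kramer post-hoc procedure is sometimes quoted next to
KS tests in this literature, but it is defined for ANOVA mean contrasts,
not for KS statistics, so it is intentionally not imitated; raw and
adjusted p values are both reported.

## Cluster interactions

Vesicle clusters appear as long-lived vertical lines. Detection is
explicitly geometric (the historical alternative is visual scoring):
stationary segments lasting ≥ 30 s are cluster evidence at their mean
position; co-temporal evidence within 0.3222 µm (3 px) in the same
kymograph merges transitively into a cluster with a duration-weighted
centre. A moving segment that strictly spans the ± tol band of a live
cluster is a **pass**; a stationary segment of an otherwise-moving track
within tol of the centre, adjacent to a moving segment, is a **stop**; a
track born within tol of a live cluster whose first segment moves is a
**shed**. One moving segment yields at most one pass per cluster, so a
repeat crossing requires an intervening stop or reversal. All three
thresholds are parameters and are echoed in the output. On planted
zero-noise geometries the tests require every planted event to be
recovered and every reported event to be geometrically valid.

## The synthetic track generator

The simulator emulates the phenomenology the analysis assumes — nothing
more. Each track draws an observed phenotype from `class_probs` (defaults
0.666 stationary / 0.215 moving-without-pause / 0.119 moving-with-pause,
the published wild-type classification): stationary tracks hold a fixed
position; movers alternate runs with exponential durations
(`mean_run_s`) and, for the with-pause class, exponential pauses
(`mean_pause_s`); run speeds come from a per-direction Gaussian mixture
truncated below at `v_min` = 0.35 µm/s (redraw), so every planted run
exceeds the 0.3222 µm/s detection floor; direction flips with
`p_reversal` = 0.02 at run boundaries (reversals are rare in this system);
tracks truncate on leaving the 80 µm field; observation = truth +
N(0, `noise_sd_um`²) with a 0.05 µm default, sampled every frame for 500
frames at 156 ms and emitted in pixel units. A few whole-movie stationary
tracks are designated clusters and shed no-pause movers at `shed_rate`
(outgoing direction 0.716 anterograde / 0.284 retrograde — the published
48%/19% split renormalized over the two moving outcomes). Everything is
reproducible bit-for-bit from one seed.

Strain presets (`sim_preset`) plant the published per-direction mean ±
s.d. segment speeds: wild type 1.4 ± 0.68 (A) and 2.14 ± 0.77 (R) µm/s;
the kinesin heavy-chain reduced-function mutant 0.67 ± 0.26 and
0.63 ± 0.24; the KLC-1 null 1.4 ± 0.68 and 2.38 ± 1.03; the KLC-2
hypomorph 1.2 ± 0.48 and 1.66 ± 0.67. The wild-type preset also offers a
three-component anterograde variant (means 0.6/1.4/2.4, weights
0.3/0.5/0.2) as a surrogate for the multi-modal anterograde distribution.
The heavy-chain mutant's class fractions are not published beyond "more
stationary"; the preset uses 0.78/0.13/0.09 as a documented assumption.
`p_antero_start` is set so that planted anterograde participation equals
12.2% of tracks (= P(moving) × p_antero_start); retrograde participation
then comes out near its published 22.7% because participation is dominated
by the first-run direction when reversals are rare.

Three generator choices deserve justification:

* **Observed-phenotype semantics.** The published class fractions were
  scored from kymographs, so they describe what a track *shows* during the
  movie. Each simulated mover is therefore conditioned (bounded rejection
  resampling) on its phenotype manifesting in the recorded window: a
  with-pause track must show a ≥ 2 s pause flanked by runs, a mover must
  show a detectable run. Without this, a "with-pause" mover that exits the
  field mid-first-run would be indistinguishable from a no-pause one and
  classification recovery would be ill-posed. The conditioning slightly
  favours shorter first runs for with-pause tracks.
* **Dwell times.** No run/pause duration statistics are published for this
  system; defaults are `mean_run_s` = 20, `mean_pause_s` = 4. The run
  scale was chosen from the smearing analysis above: with 2 s windows the
  per-segment speed bias is ≈ −(v·τ_w − θ)/T, so runs much shorter than
  ~20 s would make recovered means of fast strains deviate from planted
  means by amounts large compared with the recovery tolerances the
  generator is meant to support, while kymographs in this literature show
  runs spanning tens of micrometres. These are modelling conveniences, not
  biological claims.
* **Truncated velocity draws.** Redrawing below `v_min` shifts realized
  mean run speeds slightly above nominal (a few hundredths of µm/s for the
  fast strains, ~0.09 µm/s for the slow heavy-chain mutant whose
  distribution has mass below the floor). `truth_velocity_summary()`
  reports the realized means so recovery is always judged against truth,
  not nominal.

What the generator does **not** emulate: photobleaching, tracer
mis-linking and split tracks, non-exponential dwell times, spatially
varying motor behaviour, cluster growth/dissolution, or the correlated
localization noise of a real tracer. Passing recovery tests therefore
validates the analysis chain, not any biological model of transport.

## Problem sizes and runtime choices

The acceptance-grade checks simulate 2000 tracks per strain (about the
scale of a full per-strain dataset in this literature: ~3000 tracks over
~80 kymographs), fit mixtures to n = 3000 samples with K up to 6, compare
the sliding-window labeller with a brute-force oracle on 1000 random
tracks of up to 50 points, and estimate the KS type-I error from 1000 null
replicates at n = 500 per arm. These sizes keep the whole suite at a few
minutes on one CPU while leaving Monte-Carlo error well inside the stated
tolerances.

## Known limitations

* The window rule's boundary smearing biases pause-bounded segment speeds
  low (quantified above); consumers who need unbiased run velocities
  should fit dwell-resolved models rather than window statistics.
* Cluster detection scores only what stationary *tracks* reveal; clusters
  whose member vesicles were never traced are invisible.
* The KS comparison treats segments as independent observations, as is
  conventional; segments of one track are in reality correlated.
* The JSON ingest dialect is a documented assumption about tracer export
  layout, not a published schema.

## A minimal end-to-end run

```{r example, eval = FALSE}
library(dcvmotility)

cfg <- run_config(
  conditions = list(
    wild_type = list(preset = "wild_type", n_tracks = 500),
    klc2_km11 = list(preset = "klc2_km11", n_tracks = 500)),
  seed = 1)
summary <- run_pipeline(cfg, "results/")

summary$velocity_summaries   # per-direction motility table
summary$class_fractions      # stationary / no-pause / with-pause + participation
summary$gmm_selection        # AIC-selected component counts
summary$ks                   # pairwise KS comparisons
```
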