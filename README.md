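# dcvmotility

Quantitative analysis of dense-core vesicle (DCV) axonal transport from
kymograph particle tracks.

Neurons move DCVs — the organelles that carry neuropeptides and
insulin-like peptides — along axonal microtubules using kinesin motors
(anterograde, toward the axon tip) and cytoplasmic dynein (retrograde,
toward the cell body). The standard readout is a kymograph: position along
the axon versus time, in which each traced particle becomes an ordered
list of (frame, pixel) points. `dcvmotility` turns those point lists into
the field's standard motility quantities and ships a ground-truthed
simulator for validating every stage.

## What it computes

Given per-track points `(t, x)` in frame/pixel units and a calibration
(µm/px, s/frame, axis orientation), the pipeline:

1. averages duplicate timepoints and converts to seconds / micrometres,
   signed so anterograde is positive;
2. splits each track into maximal **anterograde / retrograde /
   stationary** segments with a sliding-window rule: point *i* is moving
   if the displacement to the first point ≥ *τ_w* = 2 s later reaches the
   threshold *θ* = 0.6444 µm (signed), stationary otherwise; segment
   velocity is displacement over duration, and moving segments with fewer
   than 4 points are excluded from velocity statistics;
3. summarizes speeds per direction (n, mean, s.d., median, max),
   classifies tracks (stationary-only / moving-without-pause /
   moving-with-pause, plus per-direction participation), and computes
   displacement-within-{5, 10, 20, 40}-frames distributions and
   combined-origin track ensembles, with optional stratification by
   distance from the cell body;
4. decomposes per-direction speed distributions into 1-D Gaussian
   mixtures fitted by EM, selecting the component count K by minimizing
   AIC = 2(3K − 1) − 2 log L;
5. compares conditions per direction with pairwise two-sample
   Kolmogorov–Smirnov tests (Holm-adjusted by default);
6. detects long-lived stationary DCV clusters and scores moving-track
   interactions: pass-through, stop-at-cluster, shedding.

The synthetic generator (`simulate_tracks()`) plants a run-and-pause
state-switching transport model — mixture-distributed run velocities per
direction, exponential dwell times, rare reversals, a large permanently
stationary fraction, shedding clusters, Gaussian localization noise — and
emits tracks in the exact ingest formats together with the full ground
truth. `sim_preset()` parameterizes it for wild-type and three kinesin-1
mutant strains from their published motility statistics.

## Worked example

```r
library(dcvmotility)

sim <- simulate_tracks(sim_preset("wild_type", n_tracks = 500, seed = 1))
tracks <- calibrate_tracks(deduplicate_timepoints(sim$tracks),
                           calibration(), "wild_type")
segments <- segment_tracks(tracks)
eligible <- filter_for_velocity(segments)
#> filter_for_velocity: 19 of 291 moving segments dropped (6.53%) below 4 points

summarize_velocities(eligible)
#>   condition   direction n_segments mean_speed  sd_speed median_speed max_speed
#> 1 wild_type anterograde        139   1.298279 0.5969500     1.193449  2.973398
#> 2 wild_type  retrograde        133   1.925137 0.6726879     1.945048  3.570362

class_fractions(classify_tracks(segments))
#>   condition n_tracks frac_stationary_only frac_moving_no_pause
#> 1 wild_type      503            0.6819085            0.1968191
#>   frac_moving_with_pause frac_antero frac_retro
#> 1              0.1212724   0.1431412  0.1848907

select_gmm(abs(eligible$velocity_um_per_s[eligible$label == "R"]),
           K_max = 4, seed = 1)$best
#> Gaussian mixture, K = 1 (n = 133, logL = -135.486, AIC = 274.972)
#>   comp 1: weight 1.000, mean 1.925, sd 0.670
```

Reading the output: the wild-type preset plants anterograde runs at
1.4 ± 0.68 µm/s and retrograde runs at 2.14 ± 0.77 µm/s; the recovered
segment means (1.30 and 1.93 µm/s at this small n) sit slightly below the
planted values because the sliding-window rule smears segment boundaries
into adjacent pauses — a property of the windowing procedure itself,
quantified in the methods vignette. About 68% of tracks are stationary
for the whole movie, matching the planted 66.6% class probability, and
the single retrograde velocity peak is what AIC selects on a
single-Gaussian preset.

`run_pipeline()` orchestrates the whole flow (multiple conditions,
mixtures, KS matrix, cluster scoring, CSV + JSON report bundle) from one
configuration object or YAML file; `inst/scripts/dcvmotility.R` is a thin
command-line wrapper around it.

## Vignette

`vignettes/dcv-transport-analysis.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
boundary-smearing bias of the window rule, the generator's semantics and
its limitations, and the numerical choices in the mixture fitter.
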