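# hdemg

Spatiotemporal analysis of high-density surface electromyography (HD-sEMG)
of the forearm.

## What this package is for

When 64 monopolar electrodes are wrapped around the forearm as an 8 × 8 grid
(8 circumferential rows, 8 longitudinal columns, 2 cm longitudinal pitch),
each hand/wrist gesture paints a characteristic spatial image of muscle
activity. Comparing those images across repetitions, gestures and participant
groups — for example healthy adults against individuals with Duchenne
muscular dystrophy (DMD), whose progressive muscle degeneration changes how
the forearm is recruited — answers questions that matter for myoelectric
control of hand exoskeletons: are activation patterns repeatable, how many
independent patterns does a person produce, how close to maximal effort are
comfortable gestures, and how well can a classifier tell gestures apart?

`hdemg` implements the complete analysis chain:

1. **Preprocessing** — zero-phase Butterworth band-pass (order 4, 20–450 Hz),
   50 Hz biquad notch (Q = 50), full-wave rectification and 2 Hz low-pass
   envelope extraction; faulty-channel repair by 8-neighborhood grid
   interpolation (circumferential wrap, truncated longitudinal edges).
2. **Segmentation** — contraction onsets where a summary envelope exceeds the
   baseline mean + 10 SD; 3 s contraction windows; middle-1 s steady state.
3. **Normalization** — per electrode, the maximum of the 1 s moving-averaged
   envelope across the participant's complete dataset.
4. **Heatmaps and spatial statistics** — per-repetition and gesture-average
   8 × 8 amplitude maps; thresholded center of gravity
   (COG): the amplitude-weighted centroid of cells ≥ 80% of the map maximum,
   with a circular (wrap-aware) row coordinate, expressed as % of forearm
   circumference (COGx) and length (COGy).
5. **Motor-control metrics** — repeatability and gesture similarity as
   squared Pearson correlation R² between reshaped 1 × 64 maps (45 repetition
   pairs per gesture, 21 gesture pairs per participant); activation-pattern
   dimensionality as the number of principal components explaining > 90% of
   the variance of the 64 × 70 heatmap concatenation.
6. **Myocontrol assessment** — Hudgins time-domain features (MAV, ZC, SSC,
   WL) over 200 ms windows with 100 ms overlap, a shrinkage-regularized
   linear discriminant classifier, three-split 70/30 Monte Carlo
   cross-validation, and accuracy-versus-gesture-count curves.
7. **Synthetic cohorts** — a generator that plants Gaussian spatial templates
   with known centers, rank, onsets, activation levels and noise, so every
   stage of the pipeline can be validated against ground truth without any
   recordings.

Results come back as tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Synthesize one gesture session (10 × 3 s contractions with 3 s rests,
2048 Hz) with a planted activation bump at grid position (2, 5), then run the
chain:

```r
library(hdemg)

grid     <- grid_from_anthropometrics(length_cm = 26, circumference_cm = 27)
template <- make_spatial_template(grid, center = c(2, 5), spread = 1, peak = 50)
protocol <- contraction_protocol(n_repetitions = 10)
session  <- synthesize_session(template, protocol,
                               noise_model(baseline_sd = 1, seed = 42),
                               gesture_label = "wrist_extension", grid = grid)

filtered <- notch(bandpass(session$signals, session$fs), session$fs)
env      <- envelope(filtered, session$fs)
seg      <- detect_onsets(env, protocol)
head(tidy(seg), 3)
#>   repetition onset_s contraction_start_s contraction_end_s steady_start_s
#> 1          1    3.02                3.02              6.02           4.02
#> 2          2    9.02                9.02             12.0           10.0
#> 3          3   15.0                15.0              18.0           16.0
```

The detected onsets sit ~20 ms after the planted ramp starts at 3, 9, 15, …
seconds. Build normalized heatmaps and the spatial statistics:

```r
factors <- normalization_factors(env)
maps <- lapply(seq_len(nrow(seg$steady_windows)), function(j) {
  build_repetition_heatmap(env,
    c(seg$steady_windows$start[j], seg$steady_windows$end[j]),
    grid, factors = factors, repetition = j)
})
avg <- average_heatmap(lapply(maps, `[[`, "normalized"))
compute_cog(avg, grid)
#>     row   col cog_x_pct cog_y_pct threshold n_cells
#> 1  2.00  5.15      31.3      63.5       0.8      23

repeatability(lapply(maps, `[[`, "normalized"))
#> <similarity_matrix> 10 items, 45 unique pairs, mean off-diagonal R^2 0.989

pca_dimensionality(lapply(maps, `[[`, "normalized"))
#> <pca_dim> 1 PCs explain > 90% of variance (PC1: 99.5%)
```

The COG lands on the planted center (row 2, column ~5); COGx ≈ 31% of the
circumference and COGy ≈ 64% of forearm length. Ten repetitions of a single
stable pattern give near-perfect repeatability (R² ≈ 0.99) and a rank-1
gesture space. `run_study()` applies the same chain to whole cohorts
(`make_cohort()` plans them) and `emit_report()` writes the CSV/JSON tables.

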