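# ethomotif

Finds sub-second to day-long structure in one-dimensional animal-activity
recordings — per-frame delta-pixel counts, as produced by multi-well
zebrafish tracking rigs at 25 Hz. The analysis has three stages:

1. **Bout segmentation.** An activity trace alternates between runs of
   positive values (movement) and runs of zeros (rest). After an artifact
   ceiling (active runs containing any frame above 200 delta-pixels are
   zeroed whole) and water-change masking, every *active bout* is described
   by six features — length (s), mean, SD, total, minimum and maximum
   delta-pixels — and every *inactive bout* by its length.
2. **Module clustering.** Active bouts are z-scored per animal
   (`z = (x - mean_animal) / sd_animal`, feature-wise), pooled, centered and
   PCA-projected to the scree knee; inactive bouts are taken on
   log10(length). Both are clustered by *evidence accumulation*: an ensemble
   of Gaussian mixture models (random component count, random training
   subsample, k-means++ starts, best of five restarts) votes on pairwise
   co-assignments of probe points; average-link clustering of the evidence
   is cut at the maximum cluster lifetime; clusters are size-normalized and
   every bout takes the modal label of its 50 nearest template points.
   Modules are labeled 1..K by ascending mean bout length.
3. **Motif discovery and selection.** Module sequences are compressed by
   iteratively replacing the most compressive motif, the one maximizing
   `savings = W*N - (W + 1 + N)` for a motif of `W` symbols occurring `N`
   times; compressibility is total savings over sequence length. The merged
   unique rule expansions form the motif library. Each motif is counted per
   animal and schedule window in the real sequence and in 10 shuffles that
   preserve per-window module multisets and the active/inactive alternation,
   and scored `Z = (x - mean(shuffles)) / sd(shuffles)` (zero-SD cases
   become ±sqrt(11)). A samples-by-motifs matrix of these
   enrichment/constraint scores feeds mRMR motif ranking and 10-fold
   cross-validated linear discriminant classifiers, with majority-class and
   random-subset baselines.

A seeded synthetic-data generator with planted modules and motifs makes the
whole pipeline testable end to end without any recordings.

## Worked example

A miniature end-to-end run on simulated data (4 animals, 4,000 modules each,
short day/night cycles so several windows fit):

```r
library(ethomotif)

cfg <- default_config(out_dir = "demo", seed = 7)
cfg$simulate$n_animals  <- 4
cfg$simulate$n_modules  <- 4000
cfg$simulate$day_hours  <- 0.4
cfg$simulate$night_hours <- 0.3
cfg$cluster$n_probe      <- 600
cfg$cluster$n_models     <- 20
cfg$cluster$sample_range <- c(800, 2000)
cfg$cluster$k_nn         <- 20
cfg$classify$top         <- 25

run_pipeline(cfg)
read.csv("demo/module_summary.csv", comment.char = "#")
read.csv("demo/report.csv", comment.char = "#")
```

The module summary shows the clustering recovered the five planted active
and five planted inactive modules, ordered by mean length:

```
       kind module count mean_length_frames
1    active      1  1735           1.978098
2    active      2  1963           3.995925
3    active      3  1628           8.056511
4    active      4  1426          15.984572
5    active      5   894          32.140940
6  inactive      1  2504           6.180511
...
10 inactive      5   624        1568.528846
```

(planted template means: 2/4/8/16/32 frames active, 6/.../1536 frames
inactive). The classifier report for the day-vs-night contrast:

```
  comparison motifs cv_error    cv_sd mc_error    mc_ep rm_error    rm_sd
1  day/night     17 11.53846 7.692308 46.15385 6.913208 31.92308 7.938372
```

reads: 17 mRMR-selected motifs classify day vs night window samples with a
cross-validated error of 11.5% (SD 7.7% across folds), against a 46.2%
majority-class baseline (SE of proportion 6.9%) and 31.9% for random
17-motif subsets — the selected motifs carry day/night information well
beyond both baselines.

The same stages are scriptable from a shell via the thin CLI:

```sh
inst/cli/ethomotif all --config config.yaml --seed 7 --out demo
inst/cli/ethomotif report --out demo
```

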