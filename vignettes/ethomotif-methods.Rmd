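---
title: "From delta-pixel traces to behavioral motifs: the ethomotif methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From delta-pixel traces to behavioral motifs: the ethomotif methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the signal

High-throughput behavioral rigs for larval zebrafish record one number per
animal per frame: the count of pixels that changed intensity within the
animal's well (delta-pixels), typically at 25 Hz across multiple day/night
cycles. Movement produces runs of positive values; rest produces runs of
zeros. `ethomotif` extracts structure from these one-dimensional traces at
three scales:

1. **Bouts** — maximal runs of positive frames (active) or zero frames
   (inactive). Each active bout is described by six features: length in
   seconds, and the mean, SD, total, minimum and maximum of its delta-pixel
   values; each inactive bout by its length alone.
2. **Modules** — clusters of bouts, i.e. recurring bout shapes. Behavior
   becomes a strictly alternating sequence of active and inactive module
   symbols.
3. **Motifs** — recurrent subsequences of modules, discovered by iterated
   grammar-style compression, scored against shuffled nulls, and selected
   for behavioral contrasts with a supervised pipeline.

## Pre-processing

Tracking artifacts (a hand over the plate, a water change) register as
implausibly large delta-pixel values. Any active run containing even one
frame above the **artifact ceiling** (default 200; configurable) is zeroed
over its full extent; the inactive bout that absorbs those frames is flagged
`artifact_touched` so it can be excluded downstream. Masked intervals
(e.g. water changes) are zeroed too; bouts lying wholly inside a mask, and
inactive bouts abutting one, are flagged `excluded`. Excluded modules act as
break points later: no candidate motif may span them. Leading and trailing
bouts carry an `at_edge` flag because their true extent is censored by the
recording boundary.

## Module discovery by evidence accumulation

Active-bout features are z-scored **per animal** (subtract the animal's
mean, divide by its population SD, feature-wise) so that slow animals and
vigorous animals contribute comparable geometry, then pooled, centered, and
projected onto principal components. The retained dimensionality is the
scree-plot knee; because a visual knee is not reproducible, the default rule
takes the largest drop between successive explained-variance fractions
(`n_components = "auto"`, overridable). Inactive bouts are one-dimensional
and are clustered on log10(length) — inactive lengths span frames to hours
and are naturally compared on a log axis (`log_inactive = FALSE` restores
raw lengths).

Clustering itself is consensus-based. An ensemble of Gaussian mixture models
(default 200) is fitted, each to an independently resampled subset (default
40,000–100,000 points) with a uniformly random component count (default
2–20). Every fit uses full, per-component covariances with a small ridge on
the diagonal (default `1e-6`), k-means++ initialization, and five restarts
keeping the best log-likelihood. Each model hard-assigns a fixed panel of
probe points (default 40,000) to its maximum-posterior component, and
pairwise co-assignments are tallied into an evidence matrix. Average-link
hierarchical clustering of `n_models - counts` is cut at the **maximum
lifetime** — the cluster count that persists over the largest gap between
consecutive merge heights, with 0 and `n_models` as floor and ceiling and
ties resolved toward more clusters. Clusters are then size-normalized (the
smallest cluster's size is sampled from each) and every bout — probe or
not — takes the modal label of its 50 nearest template points (Euclidean,
in the clustering space; ties take the lowest module id). Modules are
finally relabeled 1..K by ascending mean bout length, ties broken by mean
total delta-pixels.

All ensemble parameters are capped at the data size, so the same code runs
at desk scale. The component-count range matters more than ensemble size:
when a large share of models have fewer components than the true cluster
count, their merge evidence can pull the lifetime cut below truth, so the
wide default range (2–20) should be kept even on small data.

## Motif discovery by hierarchical compression

A module sequence is compressed by repeatedly replacing the **most
compressive motif**: every contiguous candidate of 2..10 symbols is
enumerated, occurrences are counted non-overlapping (greedy left-to-right —
a motif's own overlaps cannot all be replaced), and the candidate maximizing

    savings = W * N - (W + 1 + N)

(`W` symbols, `N` occurrences; the `W + 1` is the dictionary cost and the
`N` the cost of writing the new symbol) is replaced everywhere by a fresh
symbol. Iteration stops when nothing saves more than zero. Ties prefer
larger savings, then longer motifs, then the lexicographically smallest
definition, so output is deterministic. Because each scan runs over the
partially compressed sequence, rules may contain earlier rule symbols;
expanding such nested rules yields terminal motifs longer than the 10-symbol
scan cap. **Compressibility** is total savings divided by the original
length, in [0, 1). Since compressibility varies with sequence length,
comparisons across samples use non-overlapping 500-module blocks, dropping
the trailing partial block.

The motif **library** is the union of every animal's expanded rules, kept
unique and sorted by length and then lexicographically by module token.

Two structural properties of alternating sequences are worth knowing.
First, compression naturally builds rules out of (active, inactive) pairs,
so an odd-length motif ending on an active module can only ever surface as
a rule extended by the following inactive module. Second, the greedy
heuristic is not order-optimal: a strongly repeated motif whose interior
contains out-of-phase (inactive, active) bigrams can seduce the first
replacements away from the globally better in-phase pairing, occasionally
making a structured sequence compress slightly *worse* than its shuffle.
Both effects are visible in the synthetic benchmark and are inherited from
the offline most-compressive heuristic itself.

## Enrichment against paired shuffles

For every animal and schedule window the module sequence is shuffled ten
times, permuting active ids among active slots and inactive ids among
inactive slots independently within the window — the module multisets and
the active/inactive transition structure are preserved exactly, so the null
keeps module usage and destroys only sequential order. Each library motif
is counted in the real and shuffled segments (overlapping sliding matches
by default; `overlap = FALSE` switches to non-overlapping, since the paper
trail does not pin the convention down), and scored

    Z = (x - mean(shuffles)) / sd(shuffles)

with the population SD. When the shuffle SD is zero the score is infinite
and is replaced by ±sqrt(1 + n_shuffles) (±3.32 for ten shuffles), with the
sign of `x - mean` and 0 when they are equal. The same rule, with the same
constant, applies to the leave-one-out scores of shuffles against each
other. Samples are animal-by-window rows; `drop_censored = TRUE` removes
each animal's final window instance (truncated by the end of the recording,
so its counts are uninformative), and `min_modules` drops undersized
instances, mirroring the usual exclusion of segments with too few modules.

## Supervised motif selection

Scores are column-normalized (mean 0, SD 1, population convention;
constant columns become zeros and are flagged). Motifs are ranked by greedy
mRMR with the mutual-information difference scheme on scores discretized
into three states at mean ± `disc_t` SDs per column. The default is
`disc_t = 0.5`: with a full 1-SD band, a one-sided enrichment signal (high
by day, exactly zero by night) inflates its own column SD until both
cutoffs fall outside the informative mass and the column collapses into the
middle state, erasing its relevance; the half-SD band keeps such columns
informative. Classification error is estimated by linear discriminant
analysis over growing mRMR prefixes with stratified 10-fold cross-validation
(optionally grouped by animal, the default in the pipeline, so rows of one
animal never straddle train and test). The discriminant uses a pooled
covariance with a small ridge so prefixes wider than the sample count stay
usable. Error curves are smoothed with a 3-wide running average whose
windows shrink symmetrically to width 1 at the ends (the convention of the
common `smooth()` implementations), and the first minimum picks the motif
count. Baselines: the majority-class error `100 * (1 - max class fraction)`
with its SE of proportion, and ten classifiers on random motif subsets of
the selected size, sharing one fold split so that drawing all motifs
reproduces the full-matrix error exactly.

A caveat for interpreting mRMR output on day/night contrasts: any motif
that is frequent in one window kind and structurally absent in the other is
a *perfect* discretized discriminator, so relevance saturates at the label
entropy for many columns at once and the ranking among them is decided by
redundancy and tie-breaks. The strongest planted signals therefore surface
near the top both as themselves and through their sub- and super-sequences.

## The synthetic-data generator

The generator is the package's ground truth and emulates the study
conditions of a multi-day larval recording:

* 25 Hz; two 12-h developmental cycles (7 h day, 5 h night — the 14:10
  light-cycle ratio at half scale, so a ~20,000-module animal spans about
  one full two-day period and each complete day/night segment holds
  hundreds to thousands of modules). Labels carry the cycle (`day5`,
  `night5`, ...), letting probabilities or rates drift across development.
* five active templates (mean lengths 2/4/8/16/32 frames; amplitudes
  6/20/45/90/150 delta-pixels, inside the plausible 3–165 range, with a
  hard floor of 3 so active frames are never zero);
* five inactive templates with geometric-mean lengths 6/24/96/384/1536
  frames and a log10 spread of 0.12 — adjacent templates sit 5 SD apart,
  and the shortest is long enough that integer frame quantization stays
  below the spread (shorter templates split into their discrete length
  values and are genuinely multiple clusters, which no method should merge);
* day/night module probabilities favoring short inactivity by day and long
  inactivity by night;
* two planted day-enriched motifs, `A2 I1 A2 I1` and `A3 I2 A3 I2`, each
  starting a kind-compatible day position with probability 0.015 and absent
  at night, with per-animal log-normal rate multipliers (sdlog 0.3) for
  individual variability. Motifs are spliced in *during* generation so
  frame anchors, window labels and ground truth stay consistent. They are
  even-length and active-initial (see the compression note above) and made
  of mid-frequency day modules so their shuffle counts have a realistic,
  non-degenerate spread.

What the generator does **not** emulate: within-bout temporal shape
(amplitudes are i.i.d. around the template mean, real bouts have rise/decay
structure), sequential dependence beyond the planted motifs (background
modules are conditionally i.i.d. given the window), drift or habituation
within a window, and any cross-animal correlation. Passing tests therefore
demonstrate that the machinery recovers structure it was designed to
detect under clean conditions — not that real recordings satisfy those
conditions.

## Numerical and design choices

* Population SD throughout (bout features, Eq.-style z-scores, column
  normalization): every one-frame bout and two-value column stays defined.
* Frames are 0-based; intervals half-open `[start, end)`.
* Seeds: one master seed; every animal and stage derives a 32-bit sub-seed
  from it by hashing a tag, so parallel and serial runs agree exactly.
* GMM regularization: additive diagonal ridge, default `1e-6`, configurable;
  k-means++ seeding draws from R's RNG for reproducibility.
* Evidence dissimilarity `n_models - counts`; lifetime ties toward larger K.
* The per-iteration candidate scan covers the partially compressed
  sequence (the nesting mechanism); candidates never span masked or
  excluded positions.
* Problem sizes in the shipped tests: the end-to-end benchmark uses 8
  animals at 20,000 modules (probe panel 1500, ensemble of 50 models on
  2,000–5,000-point samples), the compression oracle enumerates all 88,569
  sequences of length ≤ 10 over a 3-symbol alphabet, and the shuffle-null
  fuzz runs 1,000 cases; these sizes keep the full suite within a few
  minutes on one CPU while leaving the recovery margins wide.

## Known limitations

* The offline most-compressive heuristic is greedy; rule identity (not
  compressibility) can change under symbol relabeling only through
  lexicographic tie-breaks, and phase interference (above) can cost a few
  savings on strongly structured inputs.
* mRMR with discretized MI saturates on perfectly one-sided columns, so
  motif *identity* at the very top of a ranking is less stable than the
  selected subset's classification error.
* The maximum-lifetime cut inherits the ensemble's biases: with component
  ranges mostly below the true cluster count it merges; scale the range,
  not just the ensemble size.
* Eq.-style Z scores against only ten shuffles have heavy estimation noise
  in the denominator; treat individual scores as screening statistics, not
  calibrated z-values.
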