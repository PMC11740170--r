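---
title: "Methods: raft membrane microarray analysis with rmma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raft membrane microarray analysis with rmma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmma)
```

## The problem

Raft membrane microarrays (RMMAs) immobilize lipid-raft preparations from
different cell types or treatment conditions as a printed grid of ~450 um
spots at a 950 um pitch. Each array is interrogated twice: by MALDI mass
spectrometry imaging (one spectrum per node of a 150 um laser raster), which
yields a lipid fingerprint per spot, and by colorimetric or fluorescent
on-chip assays (scanned images), which yield enzymatic activities or ligand
binding per spot. `rmma` implements the full computational chain for both
readouts and ships a synthetic-data generator so that every stage can be
validated against known ground truth.

## Synthetic arrays

The generator (`generate_array_layout()`, `simulate_msi_dataset()`,
`simulate_assay_scan()`) emulates the printed design: a first row of
standard-curve spots of known protein amount, a blank row, then replicate
rows (triplicates by default) per sample. The default geometry — 450 um
spots, 950 um pitch, 150 um raster — matches the acquisition design the
package targets, and leaves 500 um between neighbouring spot edges so spot
disks never overlap.

Each sample group carries a lipid profile obtained by modulating a common
reference profile (log-normal peak heights, median ~100 a.u.) with
per-feature log2 fold changes. When no effect matrix is supplied, each group
receives |log2 fc| = 2 (4-fold changes) on its own fifth of the features,
and the affected blocks are kept disjoint across groups while features last.
Both choices are deliberate: fold changes of this size on a minority of
species produce fingerprints that correlate ~0.4–0.7 across groups —
clearly distinct, as fingerprints of different cell types are, yet far from
orthogonal — and disjoint blocks make class distinctness structural rather
than a property of a lucky random draw, which matters because the pixel
class labels serve as ground truth for segmentation benchmarks.

Pixel spectra are the group profile times a multiplicative log-normal TIC
factor (mean 1, CV 0.15 by default — the pixel-to-pixel signal variation
that motivates TIC normalization) plus additive Gaussian noise (SD = 2% of
the median reference peak) truncated at zero. Assay scans place
`intercept + slope * amount` inside each spot disk over a zero background
and add independent per-pixel Gaussian read noise, as a flatbed scanner
does; spot quantification then averages that noise down over the ~250
pixels of a disk. What the generator does *not* emulate: isotope envelopes,
mass drift, matrix sublimation artifacts, detector saturation, scanner
gradients, or spot-shape irregularities. Tests passing on these simulations
therefore validate the algorithmic chain, not robustness to every
instrumental artifact of real data.

## Preprocessing

* **TIC normalization** divides a spectrum by its summed intensity; an
  all-zero spectrum is an error rather than silently propagated.
* **Alignment** pools all peaks, sorts them, and merges peaks wherever
  consecutive m/z gaps are at most the bin width (0.01 Da by default). We
  chose gap grouping over fixed-edge bins because two peaks 0.0002 Da apart
  must merge regardless of where an arbitrary bin edge falls; the grouping
  is deterministic and independent of pixel order, and per-pixel total
  intensity is conserved exactly. The shared axis takes each group's
  intensity-weighted mean m/z.
* **Peak filtering** zeroes intensities strictly below 0.5% of the
  spectrum's strongest peak (values exactly at the threshold survive; the
  base peak always survives). A secondary 0.1% threshold can be passed for
  display-oriented tables.
* **Annotation** matches each peak to the nearest entry of a user-supplied
  lipid table within a ppm tolerance and matching ion mode.
* **Replicate outliers**: within each replicate group, a member is flagged
  when its median Pearson correlation against its current siblings falls
  strictly below 0.7. Flagging is iterative — the worst offender is removed
  and medians recomputed — because a single corrupted replicate otherwise
  drags its clean siblings' medians down (with sibling correlations
  {1, −1} the median is 0) and a plain one-shot rule would discard the
  whole triplicate. A discordant pair cannot be arbitrated, so both members
  are flagged.

## Per-spot representative spectra

Pixels are assigned to a spot when their centre lies inside the spot disk
(inclusive boundary). With the default geometry this yields 4–9 pixels per
spot depending on the sub-grid offset of the spot centre; the package does
not assume any particular count. Each spot's pixels are then divisively
partitioned — with the same walker-competition split used for whole-array
segmentation — until every segment has all pairwise correlations strictly
above 0.9, and the most intense segment (largest summed raw TIC; ties broken
by pixel count, then lowest pixel index) provides the TIC-normalized mean
spectrum. "Most intense" is read as signal magnitude: the spot's genuine
material should dominate its representative, not edge pixels of partial
laser coverage.

## Whole-array segmentation

The segmentation is a divisive analysis whose split primitive is a
competition of two restarting random walkers on a Markov chain over pixel
spectra:

* **Affinity** between pixels i and j is `(1 + r_ij) / 2` with `r` the
  Pearson correlation, zero diagonal, rows normalized to sum one. This maps
  similarity monotonically onto [0, 1] and keeps the chain irreducible
  except at exact anti-correlation.
* **Split**: the two walkers are seeded at the least-correlated pixel pair
  of the segment (the most-dissimilar heuristic of divisive analysis). Each
  walker's personalized rank vector solves
  `v = (1 − restart) T' v + restart e_seed` on the segment's renormalized
  sub-chain, computed by power iteration to a 1e-10 sup-norm tolerance
  (restart 0.15, the conventional choice). Every pixel joins the walker
  ranking it higher; ties go to the lower-indexed seed, and each seed stays
  with its own walker, so both halves are non-empty. A one-shot rank
  comparison is used rather than interleaving reassignment with re-ranking;
  it is deterministic and the power-iteration ranks are verified against a
  direct linear solve in the tests.
* **Queue**: the least coherent segment (lowest mean internal pairwise
  correlation) among those with at least `min_size` pixels (3) and cohesion
  below `cohesion_stop` (0.9) is split next; splitting stops when no such
  segment remains or a segment cap is hit. The 0.9 default reuses the only
  cohesion threshold the workflow states elsewhere (the per-spot R > 0.9
  rule).
* **Coloring**: the two segments with the least-correlated mean spectra
  anchor positions 0 and 1 of a rainbow scale; every other segment C sits at
  `d(A,C) / (d(A,C) + d(C,B))` with `d = 1 − r`, so similar segments get
  nearby colors.

The affinity is purely spectral — no spatial smoothing term — so replicate
spots of one sample can receive the same color without being neighbours,
which is exactly the property used to check the segmentation on synthetic
arrays (≥ 95% of each triplicate's pixels sharing the majority label).
There is no randomness anywhere in the segmentation: identical input gives
an identical partition.

```{r segmentation-example}
layout <- generate_array_layout(6, 3,
                                groups = c("astro", "neuro", "astroPQ",
                                           "astroLS"),
                                standards = c(0, 5, 10))
sim <- simulate_msi_dataset(layout, synth_config(seed = 11))
asn <- assign_pixels(sim$dataset, layout)
fg <- which(!is.na(asn$spot) &
  !(sim$truth$pixel_class %in% c("background", "blank", "standard")))
spectra <- t(apply(sim$dataset$spectra[fg, ], 1, tic_normalize))
seg <- color_segments(diana_rankcompete(spectra, cohesion_stop = 0.9))
seg
```

## Multivariate discrimination

Features are ranked by one-way ANOVA F across group labels and the top 50
retained (F rather than p: the orderings coincide at equal group sizes, and
F needs no distributional lookup). PCA standardizes features first
(centring and unit variance — "normalized data" read as z-scoring, the
conventional choice when units are arbitrary relative intensities) and
retains components by a double rule: accumulate until the cumulative
explained variance exceeds 90%, but never add a component contributing
≤ 0.5%. The two conditions can conflict; the share rule wins and the
conflict is flagged, since adding a near-empty component cannot be justified
by an unmet cumulative target.

Four classifiers run under seeded, stratified 10-fold cross-validation with
fixed hyperparameters: k-NN (k = 5, Euclidean, uniform weights), Gaussian
naive Bayes, random forest (10 trees; nodes smaller than 5 are not split —
`randomForest::randomForest(ntree = 10, nodesize = 5)`), and a
single-hidden-layer neural network (200 ReLU units, softmax output,
cross-entropy loss, minibatch SGD with momentum, at most 350 epochs). The
network is implemented in the package because no installed R package
expresses that exact architecture (ReLU hidden layer with an SGD solver);
inputs are z-scored inside the fit, initialization is He-scaled, and the
plumbed seed fixes folds and weights alike. When a class has fewer samples
than folds, the fold count shrinks to the smallest class with a warning.

Per-feature univariate comparisons report a Shapiro–Wilk normality p-value
per group and a two-sided Mann–Whitney rank-sum test at alpha 0.05; the
rank test is reported regardless of the normality outcome, mirroring the
conservative practice of not switching tests per feature.

## Assay quantification

Spot signal is the mean image intensity inside the spot disk minus the
median of a 1.1–1.5-radius annulus (a local, robust background), floored at
zero. The Bradford standard curve is an ordinary least-squares line through
the known-amount spots; protein per spot inverts it, flooring negative
estimates at zero with a warning. Activities are expressed as OD per ng of
immobilized protein. Outliers among replicate values are flagged outside
`mean ± DF·SD` with DF = 1.25 and the sample (n − 1) standard deviation —
appropriate for small replicate groups — and flagging is strict, so values
exactly on a bound survive. Difference-derived activities
(acetylcholinesterase = total cholinesterase − butyrylcholinesterase;
sigma-1 = total sigma − sigma-2) are computed per matched replicate spot
*before* averaging: published group means are not generally consistent with
differences of means, and per-spot differencing also lets outlier removal
act on the derived quantity, which is where it is applied (configurable).
Negative derived activities are floored at zero with a warning. Group
comparisons delegate to one-way or two-way ANOVA with Tukey's post-hoc test
and report mean ± SD per group.

## Numerical choices and degenerate inputs

* Zero-variance spectra get correlation 0 (affinity 1/2) with a warning
  rather than NaNs.
* A pixel with zero affinity to every other node becomes a uniform row in
  the chain, keeping the transition matrix stochastic.
* Walker power iteration errors out (reporting the residual) if 10,000
  iterations do not reach 1e-10; at restart 0.15 convergence takes ~150.
* All tie-breaks (walker ranks, segment ordering, "most intense" segment)
  are deterministic and documented at the function level.
* All simulation entry points take a seed and restore the caller's RNG
  state, so identical seed + configuration is bit-reproducible.

## Problem sizes used in the tests

The shipped test suite and the acceptance script run on arrays of 4 groups
x 3 replicate spots (plus standards and blanks) at the default geometry —
about 90 foreground pixels and 60 lipid features — and on 4 x 12-spot
arrays for cross-validated classification (48 samples). These sizes keep
full-chain checks fast while leaving every per-spot and per-segment
statistic well above its degeneracy limits; all scale linearly or
quadratically (correlation matrices) in pixel count for larger studies.

## Known limitations

* Segmentation builds a dense pixel-by-pixel correlation and transition
  matrix, so whole-slide datasets (10^5+ pixels) would need blocking or
  sparsification; printed arrays stay far below that.
* The imzML reader/writer covers continuous and processed 64-bit float
  uncompressed files — the subset the pipeline emits — not every vendor
  export variant.
* The replicate-outlier and deviation-factor rules assume at least
  triplicates; with duplicates they can only flag the pair as a whole.
* Classifier accuracy on simulated fingerprints reflects the generator's
  separability; it says nothing about the accuracy attainable on any real
  biological contrast.
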