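---
title: "Classifier-based clustering of tracking output: methods and design notes"
author: "trackCBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifier-based clustering of tracking output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackCBC)
```

## The problem

A multiple-object tracker (MOT) applied to a video of a group of
same-species animals returns, for every detection, a frame number, a
bounding box and a track label. Tracks are built from spatio-temporal
contiguity, so one animal that leaves the camera view, is occluded, or
simply moves quickly ends up split across many tracks — in pen footage of
pigs it is common to see hundreds of tracks for a few hundred boxes and
fewer than ten animals. Re-identification then amounts to *post-clustering
the tracks*: merging the fragments of each individual back together until
the number of groups equals the (approximately known) number of animals,
producing a labelled map of the video.

Two pieces of side information make this more than plain clustering:

* **Must-link, implicitly**: all detections of one track are the same
  animal, so tracks are merged or kept whole, never split.
* **Cannot-link (CL), from frames**: two detections in the *same frame*
  are different animals, so two tracks that co-occur in any frame must
  never be merged.

## The data model

`TrackedDataset` extends `SummarizedExperiment`: one column per detection,
the appearance feature vector as the `"features"` assay (54 rows, `NA`
until extracted), and the per-detection annotations (`frame`, box
`x, y, w, h`, `track`, ground-truth `identity`) as `colData`. Boxes are
axis-aligned with 0-based top-left corner and half-open extent
`[x, x + w) x [y, y + h)`; frames are 0-based internally, while
MOTChallenge-style CSV files are 1-based (`frameBase` converts on I/O,
and boxes are written with two decimals). Label vectors are plain integer
vectors aligned with the detection columns; labels are compared by
equality only and need not be contiguous.

## Appearance descriptor

Each box is clamped to the image, split into a 3-by-3 grid (cell edges at
`floor(i * w / 3)`, so cells may differ by one pixel but partition the box
exactly), and summarized by the mean and standard deviation of each colour
plane in each cell: 9 cells x 3 colours x 2 statistics = 54 features on
the raw 0–255 intensity scale. The standard deviation is the population
form — the value describes the cell's pixels, it does not estimate a
population parameter. Boxes whose visible (clamped) part is smaller than
3x3 pixels are rejected. Deliberately simple colour statistics are used
because, with heavily overlapping boxes of visually similar animals, more
expressive features (deep embeddings, HOG, LBP, histograms) mostly encode
nuisance structure.

Whether features should be standardized before clustering is kept as an
explicit choice rather than a fact: classifier-based clustering runs on
the raw intensity scale, while the distance-based comparators z-score each
dimension (`scaleFeatures()`), since a DBSCAN radius on the order of 0.5–4
only makes sense in a standardized space.

## Track generation

`buildTracks()` implements the IoU-gated Hungarian association: for each
pair of adjacent frames, all pairwise IoUs are computed on continuous box
areas, pairs below the threshold (default 0.7, i.e. a 70% overlap) are
inadmissible, and the one-to-one assignment maximizing total IoU is found
with the Hungarian method (`clue::solve_LSAP`). The "best fit" of the
assignment step is read as the total-IoU optimum, which is what the
Hungarian algorithm computes; a greedy per-box reading would differ only
in rare competition cases. Unmatched detections start new tracks, numbered
in creation order; association is strictly between adjacent frames, so a
detection unmatched for even one frame starts a new track. Matched pairs
whose weight falls below the threshold are discarded after solving, which
still leaves an optimal admissible matching because inadmissible weights
are zeroed before solving. With continuous IoU weights, ties between
optimal assignments have probability zero; determinism comes from the
solver being deterministic for fixed input.

## Classifier-based clustering

Starting from the track labels and a desired identity count `K`
(`cbcCluster()` returns the labels unchanged if they already number at
most `K`), each iteration:

1. trains a classifier on the features under the current labels and
   relabels the same data (resubstitution);
2. forms the confusion matrix, zeroes its diagonal (correct
   classifications carry no merge information) and both entries of every
   CL pair (tracks co-occurring in a frame, recomputed each iteration from
   the current labels so merged tracks pool their frame sets);
3. scales each row to sum to one — entry `(i, j)` is then the proportion
   of track `i`'s members relabelled as track `j`, and rows whose masked
   counts are all zero stay all-zero (no division by zero);
4. takes the largest entry `(p, q)`; if it is zero or `K` labels remain,
   stops; otherwise relabels all of `p`'s detections to `q` (row merges
   into column) and repeats.

The unscaled-count variant is not offered: absolute mistake counts favour
large tracks regardless of how coherent they are, and proportions are the
quantity with a fixed meaning across track sizes. Ties for the largest
entry are broken by the lowest row label, then the lowest column label.
The output is always a coarsening of the input tracks; the loop runs at
most `nTracks - K` merges, fewer when CL constraints or an all-zero matrix
stop it early, in which case more than `K` labels come back. `K` is
treated as an exact target; in practice the number of animals is known
only approximately, which simply means the caller chooses the `K` they
want.

The classifier is pluggable (any `function(X, labels)` or a
`ReIDClassifier`); the default is nearest-centroid, which tolerates the
single-member tracks that fragmented output is full of, is cheap enough to
retrain inside the merge loop, and classifies purely by appearance. A
1-nearest-neighbour classifier is pointless here: under resubstitution
every point is its own nearest neighbour and the confusion matrix is
diagonal.

**A degeneracy worth knowing about.** Resubstitution rewards classifiers
for fitting their own training set, and *any* sufficiently expressive
classifier classifies a near-singleton track to itself (a singleton's
centroid is the point itself). Such a track's confusion row is then
structurally zero, and it can only ever be absorbed by attracting some
other whole track. On clean, well-separated synthetic data this is the
dominant failure mode: fragments of fewer than about eight detections can
survive to the end, and the algorithm exits via its nothing-to-merge
branch with more than `K` labels. On noisy real footage confusion is
plentiful and the effect is masked. This is a property of the algorithm,
not a bug; the synthetic generators therefore model track fragments as
*episodes* with a minimum dwell time (below).

## Evaluation metrics

`metricReport()` scores an assigned labelling against ground truth with
four external metrics: normalised mutual information (arithmetic-mean
normalisation of the two entropies), the Hubert–Arabie adjusted Rand
index, counting accuracy (each cluster mapped to its majority class,
many-to-one) and Hungarian accuracy (optimal one-to-one cluster-to-class
assignment on the zero-padded contingency table). The `sanityBattery()`
reproduces the degenerate labellings that expose the difference: against
any truth, the all-singleton labelling scores a perfect counting accuracy
of 1 and a high NMI while its ARI is exactly 0, and the one-cluster
labelling scores ARI and NMI of exactly 0. Only the ARI scores all
degenerate labellings at chance level when the cluster counts of the two
labellings differ wildly — the typical situation when comparing hundreds
of tracks against a handful of identities — which is why ARI is the
package's headline metric.

Conventions for degenerate input are explicit: when the ARI's
chance-correction denominator vanishes (both labellings trivial in the
same way) the score is 1 if the partitions are identical and 0 otherwise;
NMI is 0 whenever exactly one labelling is constant (zero entropy forces
zero mutual information) and 1 when both are.

`incrementalFriedman()` implements the ranking procedure used to compare
many methods over many datasets: order methods by mean rank, test the best
two with the Friedman rank test (classical chi-square approximation, as in
`stats::friedman.test()`, without the Iman–Davenport correction), then add
one method at a time and stop at the first p-value below the cut-off
(0.05 by default); the prefix so far is the statistically
indistinguishable top group. A fully tied sub-matrix makes the Friedman
statistic 0/0; that case is p = 1 by definition of "indistinguishable".

## Comparator approaches

The spectrum of alternatives is exposed through `clusterDetections()`:

* `tracks-only` — use the track labels as identities (no post-clustering);
* `raw-<alg>` — cluster the detection features directly, ignoring tracks;
* `centroid-<alg>` — collapse each track to its feature centroid, cluster
  the centroids, and propagate labels back (always a coarsening of the
  tracks);
* `cbc` — the classifier-based clustering above.

`<alg>` is one of k-means, the seven classical agglomerative linkages
(Ward implemented as `ward.D2`; centroid and median linkage run on squared
Euclidean distances, as those linkages require), a Gaussian mixture with
shared diagonal covariance and an EM cap of 1000 iterations (via `mclust`,
model `"EEI"`, with its deterministic model-based hierarchical
initialisation), DBSCAN, and spectral clustering (`kernlab::specc`).
DBSCAN takes no cluster count, so it is swept over
`eps in {0.5, 1.0, ..., 4.0}` times `minPts in {1, ..., 8}` and the run
whose cluster count is closest to `K` wins, ties going to the smaller
`eps` then the smaller `minPts`; since no DBSCAN implementation is
available among the installed packages, the classical region-query
algorithm is implemented here directly, and noise points are returned as
singleton clusters so every detection is labelled. FINCH is recognised but
reported as unsupported — wrapping an external implementation is the only
mode offered for it, and none is installed.

## Synthetic generators

Real annotated multi-animal videos of the relevant kind are scarce, so the
package tests itself on two simulators whose *defaults are the study
conditions* of the package's own experiments.

`simulateFeatureTracks()` emulates tracker output directly in feature
space: each of 8 identities is an isotropic Gaussian cloud in 54
dimensions; `separation` (default 75) is the mean distance between
identity means and `spread` (default 15) the RMS distance of a detection
from its identity mean, both full-space Euclidean distances, so the
defaults pin the separability ratio at exactly 5. Each identity appears
once per frame over 120 frames (a co-occurrence schedule can restrict
this, creating the CL structure), and its span is split into on average
`fragmentation = 3` tracks. Fragments are exit/re-entry episodes: an
animal that is tracked at all is tracked for at least `minTrackLen = 5`
frames, and the split is uniform over compositions with that minimum.
One-frame fragments do occur in real tracker output, but they belong to
the degenerate regime discussed above, not to the recovery regime these
simulations probe. An optional per-track drift offset models concept
drift between episodes (default 0).

`simulateScene()` renders the same regime as images: noisy coloured
ellipses (24x16 px, per-pixel noise s.d. 8, base colours separated by 120
intensity units on average) performing a reflected random walk of 1
px/frame in a 96x96 pen, or wandering out of view and re-entering with
probability 0.1 per frame in the open arena. Occlusion is painter's
algorithm under a per-frame z-order; the ground-truth box is the full
unoccluded extent clipped to the frame, matching how annotators draw whole
animals, and is dropped when fewer than 3x3 pixels remain visible. All
randomness flows from one seed through named streams (motion, appearance,
schedule) so a component can be varied in isolation; identical
configurations reproduce scenes bit-exactly.

What the simulators deliberately do *not* model: photorealistic
appearance, species shape, lighting changes, camera motion, annotation
error, and the heavy-tailed track-length distributions of real tracker
output. Passing the recovery experiments therefore shows that the
algorithm does what it claims under its stated assumptions — separable
appearance, clean ground-truth boxes — not that it reaches any particular
accuracy on real footage.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use: 699 objects in 8 classes
for the analytic metric cells; 100 random labelings at N <= 30 against
pair-enumeration ARI; 100 random contingency tables up to 6x6 against
exhaustive one-to-one mapping; 200 random association instances with up to
6 boxes per frame against exhaustive assignment search; 20 simulations of
the 8-identity feature-track regime for recovery; and 20 open-arena scenes
(4 animals, 60 frames, 96x96 px) for the CBC versus tracks-only
comparison. These sizes keep every experiment exact or statistically
stable while the whole suite runs in about a minute.

Numerical conventions collected in one place: IoU is computed on
continuous areas (the rasterized pixel count is the test oracle, not the
implementation); assignment uses weight maximization with inadmissible
pairs zeroed and dropped post hoc; merge-matrix rows that are all zero
stay all zero; nearest-centroid ties go to the lowest label; the largest
merge entry ties go to lowest row then column label; `scaleFeatures()`
maps zero-variance dimensions to 0; cluster labels are compared by
equality only.

## Limitations

* CBC inherits the tracker's errors: a track that mixes identities is
  merged whole, and the CL mask then blocks legitimate merges of its
  co-occurring fragments.
* The nothing-to-merge exit means `K` is an upper bound on what the
  algorithm can promise, not a guarantee; clean near-singleton fragments
  are the typical cause.
* The classifier used in the merge loop is a modelling choice; results on
  real data depend on it, and only appearance information is used.
* A label map for one video does not transfer to other videos or cameras;
  the classifier trained inside CBC is bespoke to the clip.
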