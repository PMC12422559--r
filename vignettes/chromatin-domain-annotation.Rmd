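---
title: "Annotating chromatin domains by aligning Hi-C and epigenomic embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating chromatin domains by aligning Hi-C and epigenomic embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromalign)
```

## The model

`chromalign` assigns each fixed-width genomic bin (default 100 kb) one of K
chromatin domain types by combining two views of the bin: its 3D contact
profile from a Hi-C matrix and its 1D chromatin state from a panel of
epigenomic tracks. The central assumption is that the two views are
redundant expressions of a common underlying state — an actively transcribed
bin both contacts other active bins preferentially and carries active
histone marks — so a representation in which the two views of the *same* bin
agree should isolate that state from assay-specific noise.

The pipeline has three stages.

**Structural embedding.** The contact matrix is first distance-normalized:
each intra-chromosomal entry is divided by the mean of its diagonal (same
genomic distance, same chromosome) and inter-chromosomal entries by the
global inter-chromosomal mean, removing the polymer distance decay that
otherwise dominates every bin's contact profile. Zero-mean diagonals stay
zero, so the transform is total. The normalized matrix is read as a weighted
graph over usable bins and embedded with LINE: asynchronous SGD over edges
drawn with probability proportional to weight (alias sampling, O(1) per
draw), each positive draw accompanied by 5 negative contexts drawn
proportionally to weighted degree^0.75, learning rate decaying linearly to
1/100 of its start. Second-order proximity with separate context vectors is
the default — two bins are similar when they contact the *same* partners,
which is exactly the subcompartment notion of similarity — with first-order
available by flag. The embedding dimension defaults to 8.

**Contrastive alignment.** A structural encoder maps the LINE vector and a
functional encoder maps the normalized signal vector of every usable bin to
a shared d-dimensional space (default two ReLU hidden layers of 256 units,
d = 64). Both are trained with the bidirectional InfoNCE loss

$$ L = \tfrac12\Big[\tfrac1n\sum_i -\log \mathrm{softmax}_j\big(C_{ij}\big)_{ii}
      + \tfrac1n\sum_j -\log \mathrm{softmax}_i\big(C_{ij}\big)_{jj}\Big],
      \qquad C_{ij} = \cos(s_i, f_j)/\tau, $$

with in-batch negatives: within a random mini-batch, the matched pair
(s_i, f_i) is the positive and all cross pairings are negatives, in both the
structure-to-function and function-to-structure directions. Gradients are
analytic (softmax minus identity, propagated through the cosine
normalization) and checked against finite differences in the test suite;
optimization is Adam (lr 1e-3) over shuffled mini-batches of 256 bins.

**Clustering.** The 2d-dimensional concatenation [s_i ; f_i] is clustered by
K-means with k-means++ seeding, best of 10 starts, Lloyd iterations; labels
are then renamed so that C1 has the highest mean activity on a chosen track
(first track by default), ties broken by cluster size.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 100 kb | resolution of the whole analysis; bins index every matrix |
| LINE `dim` | 8 | structural embedding dimension |
| LINE `n_samples` | 1e6 | SGD edge draws; more sharpens the embedding |
| `n_negatives` | 5 | negative contexts per positive draw |
| `tau` | 0.1 | InfoNCE temperature; smaller sharpens the softmax |
| `out_dim` (d) | 64 | shared encoder output dimension |
| `epochs` | 30 | contrastive training length (see below) |
| `K` | 6 | number of domain types (2–10 supported) |
| `n_init` | 10 | K-means restarts |

**Why 30 epochs.** The InfoNCE optimum on data with discrete planted types
is perfect *per-bin* discrimination: with enough training the encoders
amplify whatever distinguishes one bin from its same-type neighbours —
i.e. noise — until every bin is its own island on the cosine sphere. On the
package's planted genomes, clustering quality of the concatenated embedding
is perfect after 10–30 epochs, degrades by 50 and collapses by 100 at
τ = 0.1. Cross-modal agreement (the quantity the loss is meant to
establish) is reached early, so training stops at 30 epochs by default;
`epochs` remains exposed for data where per-bin signal is richer.

**Signal normalization.** The default `log1p_zscore` (log(1+x), then
per-track z-score over usable bins with the population standard deviation)
suits nonnegative ChIP-seq-style fold-change tracks. Tracks that can be
negative — z-scored inputs, simulated Gaussian tracks, differential signals
— must use `"zscore"`; `normalize_signals()` refuses log1p on negative
values and says so. A zero-variance track maps to all zeros rather than NaN.

## Missing data

A bin is usable iff its contact row sum is positive and all its signal
values are finite. Masked-out bins get zero rows in the LINE embedding,
never enter encoder training or K-means, are NA in the annotation and in
the output BED, and are excluded from every statistic. Coordinates are
0-based half-open (BED convention) throughout; truncated terminal bins are
kept and handled by the mask like any other bin.

## Evaluation battery

- **Variance explained** is one-way ANOVA R² (between-class over total sum
  of squares), the natural reading of "variance explained by a categorical
  annotation"; it is 0 for a zero-variance track by convention, invariant
  to affine transforms of the track and to label renaming.
- **Loop O/E** counts loops whose anchors share a label and divides by the
  mean of that count under uniform permutations of the per-bin labels
  (default 1000, seeded), which preserves anchor positions and label
  composition. A closed-form product-of-marginals expectation is available
  for speed; both agree on uniform-anchor fixtures. Anchors map to the bin
  containing their midpoint; loops with an unlabeled anchor or both anchors
  in one bin are dropped and counted.
- **Fold enrichment** is the within-type median over the global (labeled)
  median per track; empty types give NA rows, zero global medians NA
  columns.
- **ARI** uses the pair-counting contingency formula; **overlap matrices**
  count co-labeled bins with optional row or column normalization;
  **segment lengths** average maximal same-label runs, with chromosome
  boundaries and NA gaps both breaking runs.

## The planted-genome simulator

`generate_planted_genome()` emulates the study design the pipeline targets:
K planted domain types laid out as contiguous segments (geometric lengths,
mean 10 bins) over 1–3 pseudo-chromosomes; Poisson contacts at rate
λ_within for same-type pairs and λ_between otherwise, decayed by 1/(1+d)
within chromosomes; signals as type-specific means plus Gaussian noise;
lognormal expression elevated in designated active types; loops with a set
fraction of within-type anchor pairs. The reference setting
(`default_study_params()`) uses K = 6 over 600 bins of 100 kb on two
chromosomes with 12 tracks, two active types with distinct signatures on
tracks 1–6, one neutral type, and three inactive types with distinct
signatures on tracks 7–12; λ_within/λ_between = 30/3 and noise sd 0.5 give
strong but not degenerate structure. All randomness flows from one master
seed through fixed per-component sub-seeds, so regeneration is bitwise
identical.

What the simulator does *not* emulate: A/B compartment eigenstructure, TAD
hierarchy and loop-extrusion geometry, coverage biases, mappability gaps,
or continuous gradations between chromatin states. Passing the recovery
tests therefore demonstrates that the implementation is correct and that
the pipeline recovers block-structured planted signal; it does not by
itself establish performance on real Hi-C, where domain boundaries are
fuzzier and per-bin evidence richer.

## Numerical choices and degenerate inputs

- Softmax and softplus computations subtract the row maximum / branch on
  sign, so losses are finite for any input scale.
- `info_nce_bidirectional` of a single pair is exactly 0 (no negatives); a
  zero-norm embedding row is an error rather than silent NaN.
- K-means restarts that produce an empty cluster re-seed the empty centroid
  at the farthest point and retry; the returned labeling is the best of
  `n_init` by within-cluster sum of squares, deterministic given the seed.
- The alias sampler is Vose's method; its empirical law matches the target
  within total-variation 0.01 at 1e5 draws in the test suite.
- Label ordering ties (equal mean activity) break by cluster size, then by
  original label index, so relabeling is always a bijection.
- All RNG — including the C++ LINE loop, which consumes R's own
  `unif_rand` — derives from `set.seed`, so every stage is bitwise
  reproducible; the pipeline seed fans out to per-stage seeds internally.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
600-bin reference genome (about 40 s on one CPU, most of it LINE's 2e6 edge
samples and 30 training epochs) and smaller 90–120-bin genomes for
pipeline-level unit tests. Real chromosomes at 100 kb yield a few thousand
bins genome-wide; the same code path applies, with `n_samples` scaled up
with the edge count.

## Known limitations

- Only text contact formats (dense and triplet TSV) are read; cooler/.hic
  binaries are out of scope, as is matrix balancing (input is assumed raw
  or balanced; only O/E is offered).
- Temperature is fixed, not learned; there are no projection heads or
  momentum encoders.
- No HMM-style smoothing of labels along the genome: segment statistics
  reflect the raw per-bin clustering.
- Whether to L2-normalize embedding halves before K-means is data-dependent;
  the default (off) clusters raw encoder outputs, matching the
  concatenate-then-cluster design, and the flag exists because
  cosine-trained embeddings sometimes benefit from it.
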