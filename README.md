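# chromalign

Chromatin domain annotation at fixed bin resolution by aligning Hi-C contact
structure with multi-track epigenomic signals through contrastive learning.

## The problem

Chromatin domain annotation partitions a genome into region classes — active
chromatin, facultative and constitutive heterochromatin, quiescent regions —
from two complementary kinds of evidence: 1D epigenomic tracks (histone
modifications, accessibility) and 3D contact structure (Hi-C). Methods that
concatenate the two modalities as independent features, or use one only to
regularize the other, can miss the direct correspondence between a bin's
contact profile and its chromatin state. `chromalign` learns that
correspondence explicitly and is aimed at anyone producing genome
segmentations from binned Hi-C plus epigenomic data.

## The method

For a genome divided into fixed-width bins (100 kb by default):

1. **Structural input.** The contact matrix is distance-normalized
   (observed/expected per diagonal), interpreted as a weighted graph over
   bins, and embedded with LINE (second-order proximity, negative sampling,
   alias-method edge draws), giving each bin an 8-dimensional contact
   profile vector.
2. **Contrastive alignment.** A structural encoder maps the LINE vector, and
   a functional encoder maps the normalized signal vector, of every bin to a
   shared d-dimensional space (d = 64). Both MLPs are trained jointly with a
   bidirectional InfoNCE loss over in-batch negatives,

   L = ½·[ mean_i −log softmax_j(cos(s_i, f_j)/τ)_ii
         + mean_j −log softmax_i(cos(s_i, f_j)/τ)_jj ],

   which pulls the two views of the same bin together (cosine similarity)
   and pushes non-matching pairs apart.
3. **Clustering.** The per-bin concatenation [s_i ; f_i] is partitioned into
   K domain types (default K = 6) by K-means (k-means++ seeding, best of 10
   starts), and labels are renamed so C1 is the most active type.

An evaluation battery quantifies any annotation: one-way ANOVA variance
explained (VE) for continuous tracks such as gene expression and replication
timing, observed/expected ratios for ChIA-PET-style loop calls under a
label-permutation null, per-type fold enrichment of signals, adjusted Rand
index and overlap matrices between annotations, and coverage / contiguous
segment-length summaries. A planted-domain genome simulator provides ground
truth for end-to-end testing.

## Worked example

```r
library(chromalign)

# a planted genome: 600 bins of 100 kb on 2 chromosomes, K = 6 domain types,
# 12 signal tracks, block-structured contacts, loops and expression
genome <- generate_planted_genome(default_study_params(seed = 1))

fit <- chromalign(genome$contacts, genome$signals, K = 6,
                  normalization = "zscore", seed = 1)
print(fit)
#> Chromatin domain annotation
#>   call: chromalign(contacts = genome$contacts, signals = genome$signals,
#>   K = 6, normalization = "zscore", seed = 1)
#>   600 bins (600 usable), K = 6 domain types
#>   coverage:  C1=112 C2=55 C3=111 C4=71 C5=125 C6=126
#>   contrastive loss: 4.7374 -> 2.3881 over 30 epochs

adjusted_rand_index(fitted(fit), genome$true_labels)
#> [1] 0.9910884

variance_explained(log1p(genome$expression), fitted(fit))
#> [1] 0.9046198

as.numeric(loop_oe_ratio(genome$loops, fit$annotation, seed = 1))
#> [1] 4.687235
```

The fit recovers the planted partition almost exactly (ARI 0.99); the
annotation explains ~90% of the variance in simulated expression, and loops
connect same-domain bins ~4.7x more often than the permutation null expects
(80% of simulated loops are planted within-type). `summary(fit)` adds
per-track VE, fold enrichment, and segment statistics; `plot(fit)` shows
coverage and the training curve. `write_annotation_bed()` exports the
segmentation, and `chromalign_cli()` (or `inst/cli/chromalign`) exposes
`simulate`, `run-all` and `evaluate` subcommands over the same functions.

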