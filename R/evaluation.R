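#' Variance explained by a categorical annotation (one-way ANOVA R-squared)
#'
#' The fraction of a continuous track's variance captured by a labeling:
#' between-class sum of squares over total sum of squares. Pairs with an NA
#' value or NA label are dropped. Returns 0 when total variance is 0.
#'
#' @param values Numeric vector.
#' @param labels Parallel label vector (integers or factor; NA allowed).
#' @return Scalar in `[0, 1]`.
#' @export
variance_explained <- function(values, labels) {
  if (length(values) != length(labels)) stop("length mismatch")
  ok <- !is.na(values) & !is.na(labels) & is.finite(values)
  if (!any(ok)) stop("all values are NA")
  v <- values[ok]; l <- labels[ok]
  if (length(v) < 2L) stop("need at least 2 non-NA pairs")
  mu <- mean(v)
  sst <- sum((v - mu)^2)
  if (sst == 0) return(0)
  grp_mu <- tapply(v, l, mean)
  grp_n <- tapply(v, l, length)
  ssb <- sum(grp_n * (grp_mu - mu)^2)
  ssb / sst
}

#' Variance explained per signal track
#'
#' Applies [variance_explained()] to each column of a signal matrix (or any
#' bin x component matrix, e.g. Hi-C embedding components) against a domain
#' annotation. Masked-out / NA-labeled bins are dropped per track.
#'
#' @param signals A `signal_matrix` or plain numeric matrix.
#' @param ann A `domain_annotation`.
#' @return Named numeric vector, one VE per column.
#' @export
per_signal_ve <- function(signals, ann) {
  v <- if (inherits(signals, "signal_matrix")) signals$values else as.matrix(signals)
  if (nrow(v) != length(ann$labels))
    stop("signals and annotation disagree on the number of bins")
  out <- vapply(seq_len(ncol(v)), function(t)
    variance_explained(v[, t], ann$labels), numeric(1))
  names(out) <- colnames(v)
  out
}

#' Normalize a VE table across annotations
#'
#' Divides each column (signal) by its maximum across the rows (annotation
#' methods), so the best method per signal scores 1. All-zero columns stay
#' zero.
#'
#' @param ve_table Annotations x signals matrix of non-negative VE values.
#' @return Matrix of the same shape with column maxima 1 (or 0).
#' @export
normalize_ve_across_annotations <- function(ve_table) {
  ve_table <- rbind(ve_table)
  if (any(ve_table < 0, na.rm = TRUE)) stop("VE values must be non-negative")
  mx <- apply(ve_table, 2L, max)
  sweep_by <- ifelse(mx > 0, mx, 1)
  sweep(ve_table, 2L, sweep_by, "/")
}

#' Observed/expected ratio of same-domain loops
#'
#' Observed is the number of loops whose two anchors carry the same domain
#' label; expected is its mean under a null that permutes the per-bin labels
#' uniformly (preserving anchor positions and label composition), or a
#' closed-form product-of-marginals expectation. Loops with an unlabeled
#' anchor, and self-pairs (both anchors in one bin), are dropped and counted
#' in the attributes.
#'
#' @param loops A `loop_set` with resolved bin pairs (see
#'   [read_loops_bedpe()] / [loop_set()]).
#' @param ann A `domain_annotation`.
#' @param n_perm Number of label permutations for the permutation null.
#' @param seed Integer seed for the permutations.
#' @param method `"permutation"` (default) or `"closed_form"`.
#' @return Scalar O/E ratio (NA if the expectation is 0), with attributes
#'   `observed`, `expected`, `n_used`, `n_dropped`.
#' @export
loop_oe_ratio <- function(loops, ann, n_perm = 1000L, seed = 1L,
                          method = c("permutation", "closed_form")) {
  method <- match.arg(method)
  pairs <- loops$resolved
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no resolvable loops")
  lab <- ann$labels
  a <- lab[pairs[, 1L]]; b <- lab[pairs[, 2L]]
  usable <- !is.na(a) & !is.na(b) & pairs[, 1L] != pairs[, 2L]
  n_dropped <- sum(!usable)
  if (!any(usable)) stop("no resolvable loops on labeled, distinct bins")
  p1 <- pairs[usable, 1L]; p2 <- pairs[usable, 2L]
  observed <- sum(lab[p1] == lab[p2])
  labeled_bins <- which(!is.na(lab))
  if (method == "permutation") {
    set.seed(seed)
    exp_counts <- vapply(seq_len(n_perm), function(r) {
      perm <- lab
      perm[labeled_bins] <- lab[sample(labeled_bins)]
      sum(perm[p1] == perm[p2])
    }, numeric(1))
    expected <- mean(exp_counts)
  } else {
    ck <- tabulate(lab[labeled_bins], nbins = ann$K) / length(labeled_bins)
    expected <- length(p1) * sum(ck^2)
  }
  ratio <- if (expected == 0) NA_real_ else observed / expected
  structure(ratio, observed = observed, expected = expected,
            n_used = length(p1), n_dropped = n_dropped)
}

#' Fold enrichment of signals per domain type
#'
#' Entry (k, t) is the median of track t over bins labeled k divided by the
#' median of track t over all labeled bins. A track with global median 0
#' yields an NA column; an empty domain type yields an NA row.
#'
#' @param signals A `signal_matrix` (raw scale is conventional here).
#' @param ann A `domain_annotation`.
#' @return K x n_tracks matrix of fold enrichments.
#' @export
fold_enrichment <- function(signals, ann) {
  v <- signals$values
  lab <- ann$labels
  if (nrow(v) != length(lab)) stop("shape mismatch")
  labeled <- !is.na(lab)
  out <- matrix(NA_real_, ann$K, ncol(v),
                dimnames = list(paste0("C", seq_len(ann$K)), colnames(v)))
  gm <- apply(v[labeled, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  for (k in seq_len(ann$K)) {
    rows <- which(lab == k)
    if (!length(rows)) next
    med_k <- apply(v[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    out[k, ] <- ifelse(gm != 0, med_k / gm, NA_real_)
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same bins, from the contingency-table formula. Positions where either
#' labeling is NA are dropped pairwise. 1 for identical partitions (up to
#' label names); approximately 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) stop("need at least 2 jointly labeled positions")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' Overlap matrix between two domain annotations
#'
#' Raw entry (p, q) counts bins labeled p in `a` and q in `b`; only bins
#' labeled in both annotations are counted. `"row"` normalization divides
#' each row by its total (rows sum to 1 where non-empty), `"column"`
#' likewise for columns.
#'
#' @param a,b `domain_annotation` objects over the same bin table.
#' @param normalization `"none"`, `"row"`, or `"column"`.
#' @return An `overlap_matrix`: K_a x K_b matrix with attribute
#'   `normalization`.
#' @export
overlap_matrix <- function(a, b, normalization = c("none", "row", "column")) {
  normalization <- match.arg(normalization)
  if (!same_bins(a$bins, b$bins))
    stop("annotations are defined on different bin tables")
  ok <- !is.na(a$labels) & !is.na(b$labels)
  m <- matrix(0, a$K, b$K,
              dimnames = list(paste0("C", seq_len(a$K)),
                              paste0("C", seq_len(b$K))))
  tab <- table(factor(a$labels[ok], levels = seq_len(a$K)),
               factor(b$labels[ok], levels = seq_len(b$K)))
  m[] <- as.numeric(tab)
  if (normalization == "row") {
    rs <- rowSums(m)
    m <- m / ifelse(rs > 0, rs, 1)
  } else if (normalization == "column") {
    cs <- colSums(m)
    m <- sweep(m, 2L, ifelse(cs > 0, cs, 1), "/")
  }
  structure(m, normalization = normalization, class = c("overlap_matrix", "matrix"))
}

#' Bin counts per domain type
#'
#' @param ann A `domain_annotation`.
#' @return Integer K-vector (NA bins excluded); empty types count 0.
#' @export
domain_coverage <- function(ann) {
  stats::setNames(tabulate(ann$labels[!is.na(ann$labels)], nbins = ann$K),
                  paste0("C", seq_len(ann$K)))
}

#' Mean contiguous-segment length per domain type
#'
#' A segment is a maximal run of consecutive bins with the same label;
#' chromosome boundaries and NA bins both break runs. Reported in bins and
#' in base pairs (bins x bin size).
#'
#' @param ann A `domain_annotation`.
#' @return Data frame with columns `domain`, `mean_bins`, `mean_bp`,
#'   `n_segments`; NA means for empty types.
#' @export
mean_segment_length <- function(ann) {
  lab <- ann$labels
  chrom <- ann$bins$chrom
  # break runs at chromosome changes by tagging each bin with its chromosome
  run_key <- paste(chrom, ifelse(is.na(lab), "NA", lab))
  r <- rle(run_key)
  run_lab <- suppressWarnings(as.integer(sub("^.* ", "", r$values)))
  bs <- attr(ann$bins, "bin_size")
  out <- data.frame(domain = paste0("C", seq_len(ann$K)),
                    mean_bins = NA_real_, mean_bp = NA_real_,
                    n_segments = 0L)
  for (k in seq_len(ann$K)) {
    lens <- r$lengths[!is.na(run_lab) & run_lab == k]
    out$n_segments[k] <- length(lens)
    if (length(lens)) {
      out$mean_bins[k] <- mean(lens)
      out$mean_bp[k] <- mean(lens) * bs
    }
  }
  out
}
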