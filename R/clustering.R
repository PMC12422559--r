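#' Concatenate structural and functional embeddings
#'
#' Row i of the result is `[s_i ; f_i]`, the 2d-dimensional joint
#' representation that is clustered into domain types. Optionally each half
#' is L2-normalized first (off by default: raw encoder outputs are used).
#'
#' @param pe A `paired_embeddings` object (or list with `S`, `F`).
#' @param l2_normalize_halves Normalize each half to unit length first?
#' @return Numeric matrix, n x 2d.
#' @export
concat_embeddings <- function(pe, l2_normalize_halves = FALSE) {
  S <- pe$S; F <- pe$F
  if (!is.matrix(S)) S <- rbind(S)
  if (!is.matrix(F)) F <- rbind(F)
  if (nrow(S) != nrow(F) || ncol(S) != ncol(F))
    stop("S and F must have matching shapes")
  if (l2_normalize_halves && nrow(S) > 0) {
    S <- S / sqrt(rowSums(S^2))
    F <- F / sqrt(rowSums(F^2))
  }
  cbind(S, F)
}

# k-means++ seeding (Arthur & Vassilvitskii); returns a K x p center matrix
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(K - 1L) + 1L) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[k, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

#' Partition rows into K clusters with seeded K-means
#'
#' Runs `n_init` k-means++ initializations, refines each with Lloyd
#' iterations (via [stats::kmeans()]), and returns the labeling with the
#' smallest within-cluster sum of squares. If an initialization collapses to
#' an empty cluster, the empty centroid is re-seeded at the point farthest
#' from its assigned centroid and the run is retried. Deterministic given
#' `seed`.
#'
#' @param X Numeric matrix, one row per observation.
#' @param K Number of clusters (`n >= K` required).
#' @param seed Integer seed.
#' @param n_init Number of independent initializations.
#' @return Integer labels in `1..K` with attributes `tot_withinss` and
#'   `centers`.
#' @export
kmeans_cluster <- function(X, K, seed = 1L, n_init = 10L) {
  X <- as.matrix(X)
  if (nrow(X) < K) stop("need at least K rows (n = ", nrow(X), ", K = ", K, ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_centers(X, K)
    fit <- NULL
    for (attempt in 1:5) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      # re-seed any empty centroid at the point farthest from its own center
      assign_d2 <- function(ctr) {
        d <- vapply(seq_len(nrow(ctr)), function(k)
          rowSums((X - matrix(ctr[k, ], nrow(X), ncol(X), byrow = TRUE))^2),
          numeric(nrow(X)))
        list(lab = max.col(-d), d2 = d[cbind(seq_len(nrow(X)), max.col(-d))])
      }
      a <- assign_d2(centers)
      missing_k <- setdiff(seq_len(K), unique(a$lab))
      if (!length(missing_k) && !is.null(fit)) missing_k <- which(fit$size == 0)
      for (k in missing_k) {
        far <- which.max(a$d2)
        centers[k, ] <- X[far, ]
        a$d2[far] <- 0
      }
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all initializations")
  structure(as.integer(best$cluster), tot_withinss = best$tot.withinss,
            centers = best$centers)
}

#' Attach cluster labels to the genome as a domain annotation
#'
#' @param bins A `bin_table`.
#' @param labels Integer labels in `1..K`, one per masked-in bin, in genome
#'   order.
#' @param mask Logical usable-bin vector (length `nrow(bins)`).
#' @param K Number of domain types; defaults to `max(labels)`.
#' @return A `domain_annotation`: list with per-bin `labels` (NA where masked
#'   out), `K`, and `bins`.
#' @export
annotate <- function(bins, labels, mask = NULL, K = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(bins))
  if (length(labels) != sum(mask))
    stop("got ", length(labels), " labels for ", sum(mask), " masked-in bins")
  if (is.null(K)) K <- if (length(labels)) max(labels) else 0L
  if (length(labels) && (any(labels < 1L) || any(labels > K)))
    stop("labels must lie in 1..K")
  full <- rep(NA_integer_, nrow(bins))
  full[mask] <- as.integer(labels)
  structure(list(labels = full, K = as.integer(K), bins = bins),
            class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cov <- domain_coverage(x)
  cat(sprintf("domain_annotation: %d bins, K = %d (%d NA)\n",
              length(x$labels), x$K, sum(is.na(x$labels))))
  cat("coverage:", paste(sprintf("C%d=%d", seq_len(x$K), cov), collapse = " "),
      "\n")
  invisible(x)
}

#' Relabel domain types from most to least active
#'
#' K-means labels are arbitrary; this renames them so that C1 has the highest
#' mean activity (e.g. an active histone mark or expression) and CK the
#' lowest, ties broken by cluster size (larger first). Memberships are
#' unchanged — the relabeling is a bijection on `1..K`.
#'
#' @param ann A `domain_annotation`.
#' @param activity Numeric per-bin activity proxy (same length as bins;
#'   values at masked-out bins are ignored).
#' @return A relabeled `domain_annotation`.
#' @export
order_labels_by_activity <- function(ann, activity) {
  if (length(activity) != length(ann$labels))
    stop("activity must have one value per bin")
  lab <- ann$labels
  means <- vapply(seq_len(ann$K), function(k)
    mean(activity[which(lab == k)]), numeric(1))
  sizes <- vapply(seq_len(ann$K), function(k) sum(lab == k, na.rm = TRUE),
                  numeric(1))
  means[is.nan(means)] <- -Inf   # empty clusters sort last
  ord <- order(-means, -sizes, seq_len(ann$K))
  relabel <- integer(ann$K)
  relabel[ord] <- seq_len(ann$K)
  new_lab <- ifelse(is.na(lab), NA_integer_, relabel[lab])
  structure(list(labels = as.integer(new_lab), K = ann$K, bins = ann$bins),
            class = "domain_annotation")
}
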