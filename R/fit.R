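#' Annotate chromatin domain types from Hi-C and epigenomic data
#'
#' The full pipeline in one call. Contacts are distance-normalized
#' (observed/expected), turned into a weighted bin graph and embedded with
#' LINE; signals are normalized per track; a structural and a functional MLP
#' encoder are trained jointly with a bidirectional InfoNCE loss so the two
#' modalities agree per bin; the concatenated encoder outputs are partitioned
#' into `K` domain types with seeded K-means; finally labels are renamed so
#' C1 is the most active type under `order_by` (first signal track by
#' default).
#'
#' @param contacts A `contact_matrix`.
#' @param signals A `signal_matrix` over the same bins (raw scale; the
#'   pipeline normalizes internally).
#' @param K Number of domain types (default 6; 2-10 supported).
#' @param normalization Signal normalization method (see
#'   [normalize_signals()]).
#' @param oe Apply [oe_transform()] to the contacts before graph building?
#' @param line Named list of overrides for [train_line()] (`dim`, `order`,
#'   `n_samples`, `n_negatives`, `lr`, `top_k`).
#' @param encoder Named list of overrides for [encoder_config()].
#' @param n_init K-means initializations.
#' @param order_by Track name (or index) whose z-scored mean orders the
#'   labels from active (C1) to inactive (CK); `NULL` keeps raw K-means
#'   labels.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it, so repeated runs are identical.
#' @return A `chromalign` object: list with `annotation`
#'   (a [annotate()] `domain_annotation`), `hic_embedding`, `paired` (the
#'   trained `paired_embeddings`), `mask`, `K`, `seed` and the `call`.
#' @examples
#' \donttest{
#' g <- generate_planted_genome(planted_params(K = 3, n_bins = 90,
#'                                             n_chroms = 1, seed = 7))
#' fit <- chromalign(g$contacts, g$signals, K = 3,
#'                   line = list(n_samples = 2e5),
#'                   encoder = list(hidden_dims = 32, out_dim = 8,
#'                                  epochs = 30), seed = 7)
#' table(fitted(fit), g$true_labels)
#' }
#' @export
chromalign <- function(contacts, signals, K = 6L,
                       normalization = "log1p_zscore", oe = TRUE,
                       line = list(), encoder = list(), n_init = 10L,
                       order_by = 1L, seed = 1L) {
  cl <- match.call()
  stopifnot(inherits(contacts, "contact_matrix"),
            inherits(signals, "signal_matrix"))
  if (K < 2L || K > 10L) stop("K must be in 2..10")

  mask <- compute_bin_mask(contacts, signals)
  signals$mask <- mask
  norm_sig <- normalize_signals(signals, normalization)

  cm <- if (oe) oe_transform(contacts) else contacts
  graph <- build_graph(cm, mask, top_k = line$top_k)

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  line_args <- list(graph = graph, seed = seeds[1L])
  for (nm in intersect(names(line), c("dim", "order", "n_samples",
                                      "n_negatives", "lr")))
    line_args[[nm]] <- line[[nm]]
  hic_emb <- do.call(train_line, line_args)

  enc_args <- encoder
  enc_args$seed <- seeds[2L]
  cfg <- do.call(encoder_config, enc_args)
  paired <- train_contrastive(hic_emb, norm_sig, cfg)

  X <- concat_embeddings(paired)
  labels <- kmeans_cluster(X, K, seed = seeds[3L], n_init = n_init)
  ann <- annotate(contacts$bins, labels, mask, K = K)
  if (!is.null(order_by)) {
    activity <- norm_sig$values[, order_by]
    ann <- order_labels_by_activity(ann, activity)
  }

  structure(list(annotation = ann, hic_embedding = hic_emb, paired = paired,
                 mask = mask, K = as.integer(K), seed = seed,
                 signals = signals, norm_signals = norm_sig, call = cl),
            class = "chromalign")
}

#' @export
print.chromalign <- function(x, ...) {
  cat("Chromatin domain annotation\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d bins (%d usable), K = %d domain types\n",
              length(x$annotation$labels), sum(x$mask), x$K))
  cov <- domain_coverage(x$annotation)
  cat("  coverage: ",
      paste(sprintf("%s=%d", names(cov), cov), collapse = " "), "\n")
  lh <- x$paired$loss_history
  cat(sprintf("  contrastive loss: %.4f -> %.4f over %d epochs\n",
              lh[1L], lh[length(lh)], length(lh)))
  invisible(x)
}

#' @export
fitted.chromalign <- function(object, ...) object$annotation$labels

#' Summarize a chromatin domain annotation fit
#'
#' Reports coverage, mean contiguous segment lengths, per-track variance
#' explained, and per-track fold enrichment.
#'
#' @param object A `chromalign` fit.
#' @param ... Unused.
#' @export
summary.chromalign <- function(object, ...) {
  ann <- object$annotation
  out <- list(
    K = object$K,
    n_bins = length(ann$labels),
    n_usable = sum(object$mask),
    coverage = domain_coverage(ann),
    segment_length = mean_segment_length(ann),
    signal_ve = per_signal_ve(object$norm_signals, ann),
    hic_ve = per_signal_ve(object$hic_embedding, ann),
    fold_enrichment = fold_enrichment(object$signals, ann),
    final_loss = utils::tail(object$paired$loss_history, 1L))
  class(out) <- "summary.chromalign"
  out
}

#' @export
print.summary.chromalign <- function(x, ...) {
  cat(sprintf("Chromatin domain annotation: K = %d, %d/%d usable bins\n",
              x$K, x$n_usable, x$n_bins))
  cat("\nDomain coverage (bins):\n"); print(x$coverage)
  cat("\nMean contiguous segment length:\n")
  print(x$segment_length, row.names = FALSE)
  cat("\nVariance explained per signal track:\n")
  print(round(x$signal_ve, 3))
  cat("\nVariance explained per Hi-C embedding component:\n")
  print(round(x$hic_ve, 3))
  cat(sprintf("\nFinal contrastive loss: %.4f\n", x$final_loss))
  invisible(x)
}

#' Plot a chromatin domain annotation fit
#'
#' Two base-graphics panels: domain coverage (bins per type) and the
#' contrastive training loss per epoch.
#'
#' @param x A `chromalign` fit.
#' @param ... Passed to `barplot`.
#' @export
plot.chromalign <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cov <- domain_coverage(x$annotation)
  graphics::barplot(cov, main = "Domain coverage", ylab = "bins",
                    col = "steelblue", ...)
  graphics::plot(x$paired$loss_history, type = "l", main = "Training loss",
                 xlab = "epoch", ylab = "InfoNCE loss")
  invisible(x)
}
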