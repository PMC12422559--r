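#' Construct a Hi-C contact matrix
#'
#' Bundles a symmetric, non-negative bin-by-bin contact count (or balanced
#' weight) matrix with the bin table that indexes its rows.
#'
#' @param values Square numeric matrix, `n_bins` x `n_bins`, symmetric,
#'   finite, non-negative.
#' @param bins The `bin_table` the rows refer to.
#' @return A `contact_matrix` object (list with elements `values`, `bins`).
#' @export
contact_matrix <- function(values, bins) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (nrow(values) != nrow(bins))
    stop("contact matrix dimension (", nrow(values),
         ") does not match bin table (", nrow(bins), ")")
  if (any(!is.finite(values))) stop("contact matrix must be finite")
  if (any(values < 0)) stop("contact matrix must be non-negative")
  if (max(abs(values - t(values))) > 1e-6 * max(1, max(abs(values))))
    stop("contact matrix must be symmetric")
  dimnames(values) <- NULL
  structure(list(values = values, bins = bins), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins, total contacts %.4g\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Observed/expected distance normalization of a contact matrix
#'
#' Removes the genomic distance decay: every intra-chromosomal entry is
#' divided by the mean of its diagonal (same distance, same chromosome) and
#' every inter-chromosomal entry by the mean over all inter-chromosomal
#' entries. Diagonals (or an inter block) whose mean is zero are left at zero,
#' so the output is always finite.
#'
#' @param contacts A `contact_matrix`.
#' @return A `contact_matrix` with distance-normalized values.
#' @export
oe_transform <- function(contacts) {
  stopifnot(inherits(contacts, "contact_matrix"))
  v <- contacts$values
  out <- v
  chrom <- contacts$bins$chrom
  for (cn in unique(chrom)) {
    rows <- which(chrom == cn)
    m <- v[rows, rows, drop = FALSE]
    n <- nrow(m)
    for (d in 0:(n - 1L)) {
      i <- seq_len(n - d)
      diag_vals <- m[cbind(i, i + d)]
      mu <- mean(diag_vals)
      scaled <- if (mu > 0) diag_vals / mu else diag_vals * 0
      m[cbind(i, i + d)] <- scaled
      m[cbind(i + d, i)] <- scaled
    }
    out[rows, rows] <- m
  }
  inter <- outer(chrom, chrom, "!=")
  if (any(inter)) {
    mu <- mean(v[inter])
    out[inter] <- if (mu > 0) v[inter] / mu else 0
  }
  contact_matrix(out, contacts$bins)
}
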