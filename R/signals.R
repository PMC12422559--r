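#' Construct a multi-track signal matrix
#'
#' Holds binned epigenomic (or evaluation) signals, one column per track,
#' together with a per-bin usability mask. Masked-out bins are excluded from
#' every statistic downstream and never enter training or clustering.
#'
#' @param values Numeric matrix, `n_bins` x `n_tracks`.
#' @param track_names Unique character vector of track names (defaults to
#'   existing column names or `track1..trackT`).
#' @param mask Logical vector of length `n_bins`; `TRUE` = usable. Defaults to
#'   all `TRUE`.
#' @return A `signal_matrix` object (list with `values`, `track_names`,
#'   `mask`).
#' @export
signal_matrix <- function(values, track_names = NULL, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(track_names)) {
    track_names <- colnames(values)
    if (is.null(track_names)) track_names <- paste0("track", seq_len(ncol(values)))
  }
  if (length(track_names) != ncol(values)) stop("one name per track required")
  if (anyDuplicated(track_names)) stop("track_names must be unique")
  if (is.null(mask)) mask <- rep(TRUE, nrow(values))
  if (length(mask) != nrow(values)) stop("mask length must equal n_bins")
  colnames(values) <- track_names
  rownames(values) <- NULL
  structure(list(values = values, track_names = track_names,
                 mask = as.logical(mask)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d bins x %d tracks (%d masked in)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  cat("tracks:", paste(utils::head(x$track_names, 8L), collapse = ", "),
      if (length(x$track_names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Compute the usable-bin mask from contacts and signals
#'
#' A bin is usable iff its contact row sum is positive (it participates in the
#' Hi-C graph) and all of its signal values are finite. The returned mask is
#' also stored into the signal matrix, which is returned invisibly via
#' attribute access; callers typically do
#' `signals$mask <- compute_bin_mask(contacts, signals)`.
#'
#' @param contacts A `contact_matrix`.
#' @param signals A `signal_matrix` over the same bins.
#' @return Logical vector of length `n_bins`.
#' @export
compute_bin_mask <- function(contacts, signals) {
  if (nrow(contacts$values) != nrow(signals$values))
    stop("contacts and signals disagree on the number of bins")
  rowSums(contacts$values) > 0 & apply(is.finite(signals$values), 1L, all)
}

#' Normalize signal tracks
#'
#' `"log1p_zscore"` (the default elsewhere in the package) applies
#' `log(1 + x)` then a per-track z-score; `"zscore"` z-scores the raw values;
#' `"none"` is the identity. Means and standard deviations are computed over
#' masked-in bins only, with the population (1/n) standard deviation. A
#' zero-variance track is mapped to all zeros rather than NaN.
#'
#' @param signals A `signal_matrix`.
#' @param method One of `"log1p_zscore"`, `"zscore"`, `"none"`.
#' @return A `signal_matrix` with transformed values (mask unchanged).
#' @export
normalize_signals <- function(signals,
                              method = c("log1p_zscore", "zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(signals)
  v <- signals$values
  keep <- signals$mask
  if (method == "log1p_zscore") {
    if (any(v[keep, ] < 0, na.rm = TRUE))
      stop("negative values are incompatible with log1p; use method = \"zscore\"")
    v <- log1p(v)
  }
  for (t in seq_len(ncol(v))) {
    x <- v[keep, t]
    mu <- mean(x)
    sd_pop <- sqrt(mean((x - mu)^2))
    v[, t] <- if (sd_pop > 0) (v[, t] - mu) / sd_pop else 0
  }
  signal_matrix(v, signals$track_names, signals$mask)
}
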