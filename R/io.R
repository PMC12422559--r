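#' Construct a loop set from resolved bin pairs
#'
#' @param bins A `bin_table`.
#' @param pairs Two-column matrix of 1-based bin indices (anchor bins).
#' @return A `loop_set`: list with `anchors` (data frame of the two anchor
#'   intervals) and `resolved` (the bin index pairs).
#' @export
loop_set <- function(bins, pairs) {
  pairs <- rbind(pairs)
  if (any(pairs < 1L | pairs > nrow(bins)))
    stop("resolved indices must lie within the bin table")
  anchors <- data.frame(
    chrom1 = bins$chrom[pairs[, 1L]], start1 = bins$start[pairs[, 1L]],
    end1 = bins$end[pairs[, 1L]],
    chrom2 = bins$chrom[pairs[, 2L]], start2 = bins$start[pairs[, 2L]],
    end2 = bins$end[pairs[, 2L]])
  structure(list(anchors = anchors, resolved = unname(pairs)),
            class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d loops\n", nrow(x$resolved)))
  invisible(x)
}

#' Read a contact matrix from text
#'
#' Dense dialect: an n x n numeric TSV (no header). Triplet dialect: rows of
#' `bin_i bin_j count` with 0-based indices, symmetrized on read. Dense input
#' asymmetric beyond a 1e-6 relative tolerance is rejected.
#'
#' @param path Input file.
#' @param bins The `bin_table` the matrix must match.
#' @param dialect `"dense_tsv"` or `"triplet_tsv"`.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, bins,
                                dialect = c("dense_tsv", "triplet_tsv",
                                            "cooler")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  n <- nrow(bins)
  if (dialect == "cooler")
    stop("cooler input is not supported; export the matrix as dense or ",
         "triplet TSV")
  if (dialect == "dense_tsv") {
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    if (nrow(m) != n || ncol(m) != n)
      stop("dense matrix is ", nrow(m), " x ", ncol(m),
           " but bin table has ", n, " bins")
    dimnames(m) <- NULL
  } else {
    tr <- utils::read.table(path, header = FALSE)
    if (ncol(tr) < 3L) stop("triplet file needs 3 columns")
    i <- tr[[1]] + 1L; j <- tr[[2]] + 1L; w <- tr[[3]]
    if (any(i < 1L | i > n | j < 1L | j > n))
      stop("triplet indices out of range for ", n, " bins")
    m <- matrix(0, n, n)
    m[cbind(i, j)] <- w
    m[cbind(j, i)] <- w
  }
  contact_matrix(m, bins)
}

#' Write a contact matrix to text
#' @param contacts A `contact_matrix`.
#' @param path Output file.
#' @param dialect `"dense_tsv"` or `"triplet_tsv"` (upper triangle incl.
#'   diagonal, 0-based, zero entries omitted).
#' @export
write_contact_matrix <- function(contacts, path,
                                 dialect = c("dense_tsv", "triplet_tsv")) {
  dialect <- match.arg(dialect)
  v <- contacts$values
  if (dialect == "dense_tsv") {
    utils::write.table(v, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    ut <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(i = ut[, 1L] - 1L, j = ut[, 2L] - 1L, w = v[ut]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read binned signals from bedGraph tracks
#'
#' Each file contributes one track. Interval values are aggregated per bin
#' with a coverage-weighted mean (default) or a coverage-weighted sum
#' (value x overlapping base pairs). Bins with no coverage get NaN (masked
#' later). Intervals on chromosomes absent from the bin table are skipped
#' with a warning and counted in attribute `n_skipped`.
#'
#' @param paths Character vector of bedGraph files (4 columns, 0-based
#'   half-open).
#' @param bins A `bin_table`.
#' @param aggregation `"mean"` or `"sum"`.
#' @param track_names Defaults to file base names.
#' @return A `signal_matrix`.
#' @export
read_signal_bedgraph <- function(paths, bins, aggregation = c("mean", "sum"),
                                 track_names = NULL) {
  aggregation <- match.arg(aggregation)
  if (is.null(track_names))
    track_names <- sub("\\.(bedgraph|bg|txt)$", "", basename(paths),
                       ignore.case = TRUE)
  n <- nrow(bins)
  out <- matrix(NaN, n, length(paths))
  n_skipped <- 0L
  for (t in seq_along(paths)) {
    bg <- utils::read.table(paths[t], header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(bg) < 4L) stop("bedGraph needs 4 columns: ", paths[t])
    known <- bg[[1]] %in% attr(bins, "chroms")
    if (any(!known)) {
      n_skipped <- n_skipped + sum(!known)
      warning(sum(!known), " interval(s) on unknown chromosomes skipped in ",
              basename(paths[t]))
      bg <- bg[known, , drop = FALSE]
    }
    wsum <- numeric(n)
    cov <- numeric(n)
    for (r in seq_len(nrow(bg))) {
      cn <- bg[r, 1L]; s <- bg[r, 2L]; e <- bg[r, 3L]; val <- bg[r, 4L]
      rows <- which(bins$chrom == cn & bins$start < e & bins$end > s)
      for (bi in rows) {
        ov <- min(e, bins$end[bi]) - max(s, bins$start[bi])
        wsum[bi] <- wsum[bi] + val * ov
        cov[bi] <- cov[bi] + ov
      }
    }
    out[, t] <- if (aggregation == "mean")
      ifelse(cov > 0, wsum / cov, NaN) else ifelse(cov > 0, wsum, NaN)
  }
  sm <- signal_matrix(out, track_names)
  attr(sm, "n_skipped") <- n_skipped
  sm
}

#' Write / read a bin x track signal TSV
#'
#' Header row of track names preceded by bin coordinates
#' (`chrom`, `start`, `end`).
#' @param signals A `signal_matrix`.
#' @param bins The matching `bin_table`.
#' @param path File path.
#' @export
write_signal_tsv <- function(signals, bins, path) {
  df <- cbind(as.data.frame(bins)[, c("chrom", "start", "end")],
              as.data.frame(signals$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path, bins) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != nrow(bins)) stop("signal TSV row count mismatch")
  signal_matrix(as.matrix(df[, -(1:3), drop = FALSE]))
}

#' Read chromatin loops from BEDPE
#'
#' Anchors are mapped to the bin containing their midpoint. Rows that are
#' malformed or whose anchors fall off the bin table are skipped with a
#' warning and counted in attribute `n_skipped`. Self-pairs (both anchors in
#' one bin) are retained here and dropped at evaluation.
#'
#' @param path BEDPE file (>= 6 columns, 0-based half-open).
#' @param bins A `bin_table`.
#' @return A `loop_set`.
#' @export
read_loops_bedpe <- function(path, bins) {
  bp <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          fill = TRUE)
  if (ncol(bp) < 6L) stop("BEDPE needs at least 6 columns")
  s1 <- suppressWarnings(as.numeric(bp[[2]])); e1 <- suppressWarnings(as.numeric(bp[[3]]))
  s2 <- suppressWarnings(as.numeric(bp[[5]])); e2 <- suppressWarnings(as.numeric(bp[[6]]))
  valid <- !is.na(s1) & !is.na(e1) & !is.na(s2) & !is.na(e2) & s1 < e1 & s2 < e2
  i <- bin_index_of(bins, as.character(bp[[1]]), floor((s1 + e1) / 2))
  j <- bin_index_of(bins, as.character(bp[[4]]), floor((s2 + e2) / 2))
  ok <- valid & !is.na(i) & !is.na(j)
  if (any(!ok))
    warning(sum(!ok), " BEDPE row(s) skipped (malformed or off the bin table)")
  if (!any(ok)) stop("no resolvable loops in ", path)
  ls <- loop_set(bins, cbind(i[ok], j[ok]))
  attr(ls, "n_skipped") <- sum(!ok)
  ls
}

#' Write loops to BEDPE
#' @param loops A `loop_set`.
#' @param path Output file.
#' @export
write_loops_bedpe <- function(loops, path) {
  utils::write.table(loops$anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a domain annotation as BED
#'
#' Records are `chrom start end C<label>`; masked-out bins are written with
#' name `NA` (or omitted with `na = "omit"`). With `merge = TRUE` adjacent
#' same-label bins are merged into one record; reading expands records back
#' to bins, so write -> read is the identity either way.
#'
#' @param ann A `domain_annotation`.
#' @param path File path.
#' @param merge Merge adjacent same-label bins into one record?
#' @param na `"emit"` (default) or `"omit"` NA bins.
#' @export
write_annotation_bed <- function(ann, path, merge = FALSE,
                                 na = c("emit", "omit")) {
  na <- match.arg(na)
  bins <- ann$bins
  name <- ifelse(is.na(ann$labels), "NA", paste0("C", ann$labels))
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   name = name, stringsAsFactors = FALSE)
  if (merge) {
    key <- paste(df$chrom, df$name)
    r <- rle(key)
    stops <- cumsum(r$lengths)
    starts_i <- stops - r$lengths + 1L
    df <- data.frame(chrom = df$chrom[starts_i], start = df$start[starts_i],
                     end = df$end[stops], name = df$name[starts_i],
                     stringsAsFactors = FALSE)
  }
  if (na == "omit") df <- df[df$name != "NA", , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @param bins The `bin_table` to expand onto.
#' @return `read_annotation_bed` returns a `domain_annotation` (bins not
#'   covered by any record are NA).
#' @export
read_annotation_bed <- function(path, bins) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")   # keep literal "NA" labels
  if (ncol(df) < 4L) stop("annotation BED needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  bad <- !grepl("^(C[0-9]+|NA)$", df$name)
  if (any(bad)) stop("labels must match C<k> or NA; offending value: ",
                     df$name[bad][1L])
  lab <- rep(NA_integer_, nrow(bins))
  for (r in seq_len(nrow(df))) {
    if (df$name[r] == "NA") next
    rows <- which(bins$chrom == df$chrom[r] & bins$start >= df$start[r] &
                    bins$end <= df$end[r])
    lab[rows] <- as.integer(sub("^C", "", df$name[r]))
  }
  K <- max(lab, na.rm = TRUE)
  annotate(bins, lab[!is.na(lab)], mask = !is.na(lab), K = K)
}

#' Write / read embeddings as TSV
#'
#' Columns: `bin_index` (0-based), `chrom`, `start`, `end`, `e1..e_dim`.
#' @param emb Numeric matrix, one row per bin.
#' @param bins The matching `bin_table`.
#' @param path File path.
#' @export
write_embedding_tsv <- function(emb, bins, path) {
  emb <- as.matrix(emb)
  df <- cbind(data.frame(bin_index = seq_len(nrow(bins)) - 1L),
              as.data.frame(bins)[, c("chrom", "start", "end")],
              stats::setNames(as.data.frame(emb),
                              paste0("e", seq_len(ncol(emb)))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path, bins) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) != nrow(bins)) stop("embedding TSV row count mismatch")
  as.matrix(df[, grep("^e[0-9]+$", names(df)), drop = FALSE])
}

#' Write an evaluation report as JSON
#'
#' @param metrics Named list of metric values (scalars, vectors, matrices).
#' @param path Output JSON path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
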