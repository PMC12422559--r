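#' Partition a genome into fixed-width bins
#'
#' Divides each chromosome into consecutive, non-overlapping bins of
#' `bin_size` base pairs, 0-based half-open (BED convention). The final bin of
#' each chromosome is truncated at the chromosome end and kept.
#'
#' @param chrom_sizes Either a two-column data frame (`chrom`, `length`) or a
#'   named numeric vector of chromosome lengths in base pairs. Chromosome
#'   order is preserved as given.
#' @param bin_size Bin width in base pairs (positive integer).
#' @return A `bin_table`: a data frame with columns `chrom`, `start`, `end`,
#'   one row per bin, sorted by (chromosome order, start), with attributes
#'   `bin_size` and `chroms`.
#' @examples
#' bin_genome(c(chr1 = 250000), 100000)
#' @export
bin_genome <- function(chrom_sizes, bin_size) {
  if (is.data.frame(chrom_sizes)) {
    chroms <- as.character(chrom_sizes[[1]])
    lengths <- as.numeric(chrom_sizes[[2]])
  } else {
    chroms <- names(chrom_sizes)
    lengths <- as.numeric(chrom_sizes)
  }
  if (is.null(chroms) || any(!nzchar(chroms)))
    stop("chromosome names are required")
  if (anyDuplicated(chroms))
    stop("duplicate chromosome name: ", chroms[duplicated(chroms)][1L])
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive")

  per_chrom <- lapply(seq_along(chroms), function(c_i) {
    n <- ceiling(lengths[c_i] / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, lengths[c_i])
    data.frame(chrom = rep(chroms[c_i], n), start = start, end = end,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  rownames(bins) <- NULL
  structure(bins, bin_size = as.integer(bin_size), chroms = chroms,
            class = c("bin_table", "data.frame"))
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins over %d chromosome(s), bin size %d bp\n",
              nrow(x), length(attr(x, "chroms")), attr(x, "bin_size")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

n_bins <- function(bins) nrow(bins)

#' Read a chrom.sizes file
#'
#' @param path Two-column whitespace-separated text: chromosome name, length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chrom.sizes needs two columns: ", path)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write a chrom.sizes file
#' @param bins A `bin_table`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(bins, path) {
  lens <- tapply(bins$end, factor(bins$chrom, levels = attr(bins, "chroms")), max)
  utils::write.table(data.frame(names(lens), as.integer(lens)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# map genomic positions (chrom, pos) to 1-based bin index; NA if off-table
bin_index_of <- function(bins, chrom, pos) {
  idx <- rep(NA_integer_, length(chrom))
  for (cn in unique(chrom)) {
    rows <- which(bins$chrom == cn)
    if (!length(rows)) next
    sel <- which(chrom == cn)
    j <- findInterval(pos[sel], bins$start[rows])
    ok <- !is.na(pos[sel]) & j >= 1L & pos[sel] < max(bins$end[rows]) &
      pos[sel] >= 0
    idx[sel[ok]] <- rows[j[ok]]
  }
  idx
}

same_bins <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b), check.attributes = FALSE))
}
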