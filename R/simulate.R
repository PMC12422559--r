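#' Parameters for a planted-domain genome
#'
#' Collects every knob of the simulator. Labels are drawn as contiguous
#' segments (geometric lengths) over 1-3 pseudo-chromosomes; contacts are
#' Poisson with rate `lambda_within` for same-type bin pairs and
#' `lambda_between` otherwise, decayed by `1/(1+|i-j|)^decay_exponent` within
#' chromosomes; signals are type-specific means plus Gaussian noise; loops
#' place a fraction `loop_within_fraction` of anchor pairs within a type.
#'
#' @param K Number of planted domain types (>= 2).
#' @param n_bins Total bins across chromosomes (>= 10 K).
#' @param n_chroms Number of pseudo-chromosomes (1-3).
#' @param bin_size Bin width in base pairs.
#' @param n_tracks Number of signal tracks.
#' @param mu K x n_tracks matrix of type-specific signal means (defaults to a
#'   staircase making all types mutually distinguishable).
#' @param noise_sd Gaussian noise sd added to every signal value.
#' @param lambda_within,lambda_between Poisson contact rates for same-type /
#'   different-type bin pairs (before distance decay).
#' @param decay_exponent Exponent of the `1/(1+d)` distance-decay kernel.
#' @param mean_segment_bins Mean planted segment length, in bins.
#' @param active_types Types given high lognormal expression.
#' @param n_loops Number of simulated loops.
#' @param loop_within_fraction Fraction of loops with both anchors in one
#'   type.
#' @param seed Integer master seed; component sub-seeds are derived from it.
#' @return A `planted_params` list.
#' @export
planted_params <- function(K = 6L, n_bins = 600L, n_chroms = 2L,
                           bin_size = 100000L, n_tracks = 12L, mu = NULL,
                           noise_sd = 0.5, lambda_within = 30,
                           lambda_between = 3, decay_exponent = 1,
                           mean_segment_bins = 10, active_types = c(1L, 2L),
                           n_loops = 300L, loop_within_fraction = 0.8,
                           seed = 1L) {
  if (K < 2L) stop("invalid params: K must be >= 2")
  if (n_bins < 10L * K) stop("invalid params: n_bins must be >= 10 * K")
  if (!n_chroms %in% 1:3) stop("invalid params: n_chroms must be in 1..3")
  if (noise_sd < 0) stop("invalid params: noise_sd must be >= 0")
  if (lambda_within < 0 || lambda_between < 0)
    stop("invalid params: contact rates must be >= 0")
  if (loop_within_fraction < 0 || loop_within_fraction > 1)
    stop("invalid params: loop_within_fraction must be in [0, 1]")
  if (is.null(mu)) {
    mu <- matrix(0, K, n_tracks)
    for (k in seq_len(K)) {
      on <- ((k - 1L) * 2L) %% n_tracks + 1L
      mu[k, on] <- 3
      mu[k, (on %% n_tracks) + 1L] <- 2
    }
  }
  if (nrow(mu) != K || ncol(mu) != n_tracks)
    stop("invalid params: mu must be K x n_tracks")
  structure(list(K = as.integer(K), n_bins = as.integer(n_bins),
                 n_chroms = as.integer(n_chroms),
                 bin_size = as.integer(bin_size),
                 n_tracks = as.integer(n_tracks), mu = mu,
                 noise_sd = noise_sd, lambda_within = lambda_within,
                 lambda_between = lambda_between,
                 decay_exponent = decay_exponent,
                 mean_segment_bins = mean_segment_bins,
                 active_types = as.integer(active_types),
                 n_loops = as.integer(n_loops),
                 loop_within_fraction = loop_within_fraction,
                 seed = as.integer(seed)),
            class = "planted_params")
}

#' Reference planted-genome setting
#'
#' The default study-scale configuration: K = 6 domain types over 600 bins of
#' 100 kb on two pseudo-chromosomes, 12 signal tracks. The mean matrix gives
#' two "active" types high levels on tracks 1-6 (with distinct signatures),
#' one neutral type intermediate everywhere, and three "inactive" types with
#' distinct low-track signatures on tracks 7-12; types 1-2 additionally get
#' high lognormal expression.
#'
#' @param seed Master seed (default 1).
#' @return A `planted_params` object with `K = 6`.
#' @export
default_study_params <- function(seed = 1L) {
  mu <- rbind(
    c(3, 3, 3, 2, 2, 2, 0, 0, 0, 0, 0, 0),   # active, gene dense
    c(2, 2, 2, 3, 3, 3, 0, 0, 1, 1, 0, 0),   # active, second signature
    c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),   # neutral
    c(0, 0, 0, 0, 0, 0, 3, 3, 0, 0, 1, 1),   # facultative-heterochromatin-like
    c(0, 0, 0, 0, 0, 0, 1, 1, 3, 3, 0, 0),   # inactive
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 2))   # quiescent
  planted_params(K = 6L, n_bins = 600L, n_chroms = 2L, bin_size = 100000L,
                 n_tracks = 12L, mu = mu, noise_sd = 0.5,
                 lambda_within = 30, lambda_between = 3,
                 mean_segment_bins = 10, active_types = c(1L, 2L),
                 n_loops = 300L, loop_within_fraction = 0.8, seed = seed)
}

# deterministic sub-seed per component, kept below 2^31
sub_seed <- function(seed, offset) (as.integer(seed) %% 1000000L) * 1000L + offset

#' Generate a planted-domain genome
#'
#' Produces a fully consistent synthetic dataset — bins, true labels,
#' contact matrix, signal tracks, expression and loops — with known ground
#' truth, in exactly the containers the analysis pipeline consumes.
#' Regenerating with the same parameters (including seed) is bitwise
#' identical.
#'
#' @param params A [planted_params()] object.
#' @return A `planted_genome`: list with `bins`, `true_labels`, `contacts`,
#'   `signals`, `expression`, `loops`, `params`.
#' @export
generate_planted_genome <- function(params = default_study_params()) {
  stopifnot(inherits(params, "planted_params"))
  p <- params
  per_chrom <- diff(round(seq(0, p$n_bins, length.out = p$n_chroms + 1L)))
  sizes <- stats::setNames(per_chrom * p$bin_size,
                           paste0("chr", seq_len(p$n_chroms)))
  bins <- bin_genome(sizes, p$bin_size)

  # labels: contiguous segments with geometric lengths, new type per segment
  set.seed(sub_seed(p$seed, 1L))
  lab <- integer(0)
  for (nc in per_chrom) {
    cl <- integer(0)
    prev <- 0L
    while (length(cl) < nc) {
      len <- 1L + stats::rgeom(1L, 1 / p$mean_segment_bins)
      k <- sample(setdiff(seq_len(p$K), prev), 1L)
      cl <- c(cl, rep(k, len))
      prev <- k
    }
    lab <- c(lab, cl[seq_len(nc)])
  }

  # contacts: Poisson block model with intra-chromosomal distance decay
  set.seed(sub_seed(p$seed, 2L))
  n <- p$n_bins
  same <- outer(lab, lab, "==")
  rate <- ifelse(same, p$lambda_within, p$lambda_between)
  chrom_id <- as.integer(factor(bins$chrom, levels = attr(bins, "chroms")))
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  intra <- outer(chrom_id, chrom_id, "==")
  decay <- ifelse(intra, 1 / (1 + d)^p$decay_exponent, 1)
  lambda <- rate * decay
  ut <- upper.tri(lambda, diag = TRUE)
  draws <- stats::rpois(sum(ut), lambda[ut])
  cm <- matrix(0, n, n)
  cm[ut] <- draws
  cm <- cm + t(cm) - diag(diag(cm))
  contacts <- contact_matrix(cm, bins)

  # signals: type mean + Gaussian noise
  set.seed(sub_seed(p$seed, 3L))
  sig <- p$mu[lab, , drop = FALSE] +
    matrix(stats::rnorm(n * p$n_tracks, sd = p$noise_sd), n, p$n_tracks)
  signals <- signal_matrix(sig, paste0("track", seq_len(p$n_tracks)))

  # expression: lognormal, high mean in active types
  set.seed(sub_seed(p$seed, 4L))
  meanlog <- ifelse(lab %in% p$active_types, log(10), log(0.5))
  expression <- stats::rlnorm(n, meanlog = meanlog, sdlog = 0.5)

  # loops: fraction rho within-type anchor pairs, remainder uniform
  set.seed(sub_seed(p$seed, 5L))
  pairs <- matrix(NA_integer_, p$n_loops, 2L)
  n_within <- round(p$loop_within_fraction * p$n_loops)
  for (l in seq_len(p$n_loops)) {
    if (l <= n_within) {
      k <- sample(lab, 1L)                     # type chosen prop. to coverage
      pool <- which(lab == k)
      pairs[l, ] <- if (length(pool) >= 2L) sample(pool, 2L) else sample(n, 2L)
    } else {
      pairs[l, ] <- sample(n, 2L)
    }
  }
  loops <- loop_set(bins, pairs)

  structure(list(bins = bins, true_labels = lab, contacts = contacts,
                 signals = signals, expression = expression, loops = loops,
                 params = p),
            class = "planted_genome")
}

#' @export
print.planted_genome <- function(x, ...) {
  cat(sprintf(
    "planted_genome: %d bins, %d chromosomes, K = %d, %d tracks, %d loops\n",
    x$params$n_bins, x$params$n_chroms, x$params$K, x$params$n_tracks,
    x$params$n_loops))
  invisible(x)
}

#' Write every component of a planted genome to disk
#'
#' Emits the same text formats the pipeline readers consume (triplet contact
#' TSV, signal TSV, BEDPE loops, chrom.sizes, truth BED, expression TSV), so
#' simulated fixtures double as format round-trip tests.
#'
#' @param genome A `planted_genome`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_planted_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(genome$bins, file.path(dir, "genome.chrom.sizes"))
  write_contact_matrix(genome$contacts, file.path(dir, "contacts.tsv"),
                       dialect = "triplet_tsv")
  write_signal_tsv(genome$signals, genome$bins, file.path(dir, "signals.tsv"))
  write_loops_bedpe(genome$loops, file.path(dir, "loops.bedpe"))
  truth <- annotate(genome$bins, genome$true_labels)
  write_annotation_bed(truth, file.path(dir, "truth.bed"))
  utils::write.table(
    data.frame(bin_index = seq_along(genome$expression) - 1L,
               value = genome$expression),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
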