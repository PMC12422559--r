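# small in-code fixtures shared across test files

toy_bins <- function(n = 3L, bin_size = 100000L, chrom = "chr1") {
  bin_genome(stats::setNames(n * bin_size, chrom), bin_size)
}

# symmetric matrix from its upper triangle entries given as (i, j, w)
sym_matrix <- function(n, triplets) {
  m <- matrix(0, n, n)
  for (t in triplets) {
    m[t[1], t[2]] <- t[3]
    m[t[2], t[1]] <- t[3]
  }
  m
}

# two disjoint uniform-weight cliques of size `sz` as a contact matrix
two_clique_contacts <- function(sz = 10L) {
  n <- 2L * sz
  m <- matrix(0, n, n)
  m[seq_len(sz), seq_len(sz)] <- 1
  m[sz + seq_len(sz), sz + seq_len(sz)] <- 1
  diag(m) <- 0
  contact_matrix(m, toy_bins(n))
}

# a small, quick planted genome for pipeline-level tests
small_planted <- function(seed = 11L) {
  generate_planted_genome(planted_params(
    K = 3L, n_bins = 120L, n_chroms = 2L, n_tracks = 6L,
    mu = rbind(c(3, 3, 0, 0, 0, 0), c(0, 0, 3, 3, 0, 0), c(0, 0, 0, 0, 3, 3)),
    noise_sd = 0.4, lambda_within = 25, lambda_between = 3,
    mean_segment_bins = 8, active_types = 1L, n_loops = 80L, seed = seed))
}

# naive double-loop bidirectional InfoNCE, the independent oracle
info_nce_oracle <- function(S, F, tau) {
  n <- nrow(S)
  cos_ij <- function(i, j) {
    sum(S[i, ] * F[j, ]) / (sqrt(sum(S[i, ]^2)) * sqrt(sum(F[j, ]^2)))
  }
  row_term <- 0
  for (i in seq_len(n)) {
    denom <- 0
    for (j in seq_len(n)) denom <- denom + exp(cos_ij(i, j) / tau)
    row_term <- row_term - log(exp(cos_ij(i, i) / tau) / denom)
  }
  col_term <- 0
  for (j in seq_len(n)) {
    denom <- 0
    for (i in seq_len(n)) denom <- denom + exp(cos_ij(i, j) / tau)
    col_term <- col_term - log(exp(cos_ij(j, j) / tau) / denom)
  }
  0.5 * (row_term / n + col_term / n)
}

# brute-force pair-agreement ARI, the independent oracle
ari_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  denom <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (denom == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / denom
}
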