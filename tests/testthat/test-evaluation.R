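test_that("variance_explained matches hand ANOVA decompositions", {
  expect_equal(variance_explained(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(variance_explained(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variance_explained(c(0, 1, 2, 3), c(1, 1, 2, 2)), 0.8)
  expect_equal(variance_explained(c(5, 5, 5), c(1, 2, 1)), 0)  # zero variance
  expect_error(variance_explained(c(NA, NA), c(1, 2)), "NA")
})

test_that("variance_explained is bounded and invariant to affine maps and renaming", {
  set.seed(17)
  for (r in 1:15) {
    n <- sample(10:60, 1)
    v <- rnorm(n)
    l <- sample(1:4, n, replace = TRUE)
    ve <- variance_explained(v, l)
    expect_gte(ve, 0); expect_lte(ve, 1)
    expect_equal(variance_explained(3.7 * v + 2, l), ve)
    relabel <- c(3, 1, 4, 2)[l]
    expect_equal(variance_explained(v, relabel), ve)
  }
})

test_that("per_signal_ve works per track and respects annotation NA", {
  b <- toy_bins(6)
  ann <- annotate(b, rep(1:2, each = 3))
  sm <- signal_matrix(cbind(rep(1:2, each = 3), rnorm(6)), c("perfect", "noise"))
  ve <- per_signal_ve(sm, ann)
  expect_equal(length(ve), 2L)
  expect_equal(unname(ve["perfect"]), 1)
})

test_that("a noise track has near-zero VE in expectation", {
  set.seed(23)
  b <- toy_bins(1000)
  ann <- annotate(b, sample(1:6, 1000, replace = TRUE))
  ve <- variance_explained(rnorm(1000), ann$labels)
  expect_lt(ve, 0.05)
})

test_that("normalize_ve_across_annotations divides columns by their maxima", {
  m <- rbind(c(0.2, 0), c(0.4, 0))
  out <- normalize_ve_across_annotations(m)
  expect_equal(out[, 1], c(0.5, 1))
  expect_equal(out[, 2], c(0, 0))
  expect_equal(normalize_ve_across_annotations(rbind(c(0.3, 0.7))),
               rbind(c(1, 1)))
})

test_that("loop_oe_ratio has exact degenerate values", {
  b <- toy_bins(10)
  loops <- loop_set(b, cbind(1:5, 6:10))
  one <- annotate(b, rep(1L, 10))
  expect_equal(as.numeric(loop_oe_ratio(loops, one, n_perm = 50, seed = 1)), 1)

  # zero same-domain loops -> 0
  alt <- annotate(b, rep(1:2, 5))
  cross <- loop_set(b, cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(as.numeric(loop_oe_ratio(cross, alt, n_perm = 50, seed = 1)), 0)

  expect_error(loop_oe_ratio(loop_set(b, cbind(3L, 3L)), one), "distinct")
})

test_that("all-within loops on a balanced 2-type labeling give O/E near 2", {
  set.seed(19)
  b <- toy_bins(200)
  ann <- annotate(b, rep(1:2, each = 100))
  pool <- which(ann$labels == 1)
  pairs <- t(replicate(150, sample(pool, 2)))
  loops <- loop_set(b, pairs)
  oe <- loop_oe_ratio(loops, ann, n_perm = 400, seed = 5)
  expect_equal(as.numeric(oe), 2, tolerance = 0.1)
})

test_that("permutation and closed-form nulls agree for uniform anchors", {
  set.seed(25)
  b <- toy_bins(300)
  ann <- annotate(b, sample(1:4, 300, replace = TRUE, prob = c(4, 3, 2, 1)))
  pairs <- t(replicate(200, sample(300, 2)))
  loops <- loop_set(b, pairs)
  perm <- loop_oe_ratio(loops, ann, n_perm = 500, seed = 2)
  closed <- loop_oe_ratio(loops, ann, method = "closed_form")
  expect_equal(attr(perm, "expected"), attr(closed, "expected"),
               tolerance = 0.05)
})

test_that("fold_enrichment matches hand medians and its invariances", {
  b <- toy_bins(6)
  ann <- annotate(b, rep(1:2, each = 3))
  sm <- signal_matrix(cbind(c(2, 2, 2, 1, 1, 1), rep(7, 6)),
                      c("graded", "const"))
  fe <- fold_enrichment(sm, ann)
  expect_equal(fe[, "graded"], c(C1 = 4 / 3, C2 = 2 / 3))  # global median 1.5
  expect_equal(fe[, "const"], c(C1 = 1, C2 = 1))

  # invariant to positive rescaling of a track
  sm2 <- signal_matrix(sm$values * 13, sm$track_names)
  expect_equal(fold_enrichment(sm2, ann), fe)

  # empty domain type -> NA row; single domain -> 1
  ann3 <- annotate(b, rep(1L, 6), K = 2L)
  fe3 <- fold_enrichment(sm, ann3)
  expect_true(all(is.na(fe3[2, ])))
  expect_equal(unname(fe3[1, ]), c(1, 1))
})

test_that("adjusted_rand_index matches the worked example and oracles", {
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 2)),
               12 / 37)  # 0.324324...
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(3, 3, 1, 1, 2, 2)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")

  set.seed(27)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("adjusted_rand_index agrees with mclust and drops NA pairwise", {
  skip_if_not_installed("mclust")
  set.seed(28)
  for (r in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))
  }
  x <- c(1, 1, 2, 2, NA, 1); y <- c(1, 1, 2, 2, 1, NA)
  expect_equal(adjusted_rand_index(x, y),
               adjusted_rand_index(x[1:4], y[1:4]))
})

test_that("overlap_matrix counts co-labeled bins with row/column normalization", {
  b <- toy_bins(10)
  a <- annotate(b, rep(1:2, each = 5))
  expect_equal(overlap_matrix(a, a)["C1", "C1"], 5)
  expect_equal(unname(diag(overlap_matrix(a, a, "row"))), c(1, 1))

  bsplit <- annotate(b, c(rep(1L, 3), rep(2L, 7)))
  aone <- annotate(b, rep(1L, 10))
  row1 <- overlap_matrix(aone, bsplit, "row")[1, ]
  expect_equal(unname(row1), c(0.3, 0.7))

  # disjoint NA patterns: only jointly labeled bins counted
  a2 <- annotate(b, rep(1L, 5), mask = c(rep(TRUE, 5), rep(FALSE, 5)))
  b2 <- annotate(b, rep(1L, 6), mask = c(rep(FALSE, 4), rep(TRUE, 6)))
  expect_equal(sum(overlap_matrix(a2, b2)), 1)

  other <- annotate(toy_bins(4), rep(1L, 4))
  expect_error(overlap_matrix(a, other), "different bin tables")
})

test_that("row-normalized overlap rows sum to one and raw entries to the co-labeled count", {
  set.seed(31)
  b <- toy_bins(60)
  a <- annotate(b, sample(1:3, 50, replace = TRUE),
                mask = c(rep(TRUE, 50), rep(FALSE, 10)))
  b2 <- annotate(b, sample(1:4, 55, replace = TRUE),
                 mask = c(rep(FALSE, 5), rep(TRUE, 55)))
  raw <- overlap_matrix(a, b2)
  expect_equal(sum(raw), sum(!is.na(a$labels) & !is.na(b2$labels)))
  rn <- overlap_matrix(a, b2, "row")
  expect_equal(unname(rowSums(rn)[rowSums(raw) > 0]),
               rep(1, sum(rowSums(raw) > 0)), tolerance = 1e-9)
})

test_that("domain_coverage counts bins per type with NA excluded", {
  b <- toy_bins(3)
  ann <- annotate(b, c(1L, 1L, 2L))
  expect_equal(unname(domain_coverage(ann)), c(2L, 1L))
  ann2 <- annotate(b, integer(0), mask = rep(FALSE, 3), K = 2L)
  expect_equal(unname(domain_coverage(ann2)), c(0L, 0L))
  ann3 <- annotate(b, c(1L, 1L, 3L), K = 3L)
  expect_equal(unname(domain_coverage(ann3)), c(2L, 0L, 1L))
})

test_that("mean_segment_length enumerates runs, breaking at chromosomes and NA", {
  b <- toy_bins(4)
  ann <- annotate(b, c(1L, 1L, 2L, 1L))
  msl <- mean_segment_length(ann)
  expect_equal(msl$mean_bins, c(1.5, 1))
  expect_equal(msl$mean_bp, c(150000, 100000))

  # one chromosome, one label: a single run of n
  ann2 <- annotate(toy_bins(7), rep(1L, 7))
  expect_equal(mean_segment_length(ann2)$mean_bins, 7)

  # chromosome boundary splits a same-label run
  b3 <- bin_genome(c(chr1 = 1e5, chr2 = 1e5), 1e5)
  ann3 <- annotate(b3, c(1L, 1L))
  expect_equal(mean_segment_length(ann3)$mean_bins, 1)

  # NA gap splits a run
  b4 <- toy_bins(3)
  ann4 <- annotate(b4, c(1L, 1L), mask = c(TRUE, FALSE, TRUE))
  expect_equal(mean_segment_length(ann4)$mean_bins, 1)
})
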