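test_that("bin_genome tiles chromosomes with truncated terminal bins", {
  b <- bin_genome(c(chr1 = 250000), 100000)
  expect_equal(nrow(b), 3L)
  expect_equal(b$start, c(0, 100000, 200000))
  expect_equal(b$end, c(100000, 200000, 250000))

  expect_equal(nrow(bin_genome(c(chr1 = 100000), 100000)), 1L)

  b2 <- bin_genome(c(chr1 = 300000, chr2 = 150000), 100000)
  expect_equal(nrow(b2), 5L)
  expect_equal(b2$chrom, c(rep("chr1", 3), rep("chr2", 2)))
  expect_equal(b2$start[4:5], c(0, 100000))
})

test_that("bin_genome bin count equals sum of per-chromosome ceilings", {
  set.seed(41)
  for (r in 1:20) {
    k <- sample(1:5, 1)
    lens <- sample(1e5:5e6, k)
    bs <- sample(c(5e4, 1e5, 25e4), 1)
    b <- bin_genome(stats::setNames(lens, paste0("c", seq_len(k))), bs)
    expect_equal(nrow(b), sum(ceiling(lens / bs)))
  }
})

test_that("bin_genome rejects bad input", {
  expect_error(bin_genome(c(chr1 = 1e5, chr1 = 2e5), 1e5), "duplicate")
  expect_error(bin_genome(c(chr1 = 1e5), 0), "bin_size")
  expect_error(bin_genome(c(chr1 = -5), 1e5), "positive")
})

test_that("compute_bin_mask flags zero-contact rows and non-finite signals", {
  b <- toy_bins(3)
  cm <- contact_matrix(sym_matrix(3, list(c(1, 2, 2), c(2, 3, 5), c(1, 3, 1))), b)
  sm <- signal_matrix(matrix(1, 3, 2))
  expect_equal(compute_bin_mask(cm, sm), rep(TRUE, 3))

  cm0 <- contact_matrix(sym_matrix(3, list(c(1, 2, 2))), b)  # bin 3 isolated
  expect_equal(compute_bin_mask(cm0, sm), c(TRUE, TRUE, FALSE))

  smn <- signal_matrix(matrix(c(1, 1, 1, 1, NaN, 1), 3, 2))
  expect_equal(compute_bin_mask(cm, smn), c(TRUE, FALSE, TRUE))

  expect_error(compute_bin_mask(cm, signal_matrix(matrix(1, 4, 2))), "bins")
})

test_that("normalize_signals follows the per-track transform rules", {
  sm <- signal_matrix(matrix(c(2, 2, 2, 0, exp(1) - 1, NA), 3, 2),
                      c("const", "ramp"), mask = c(TRUE, TRUE, FALSE))
  out <- normalize_signals(sm, "log1p_zscore")
  expect_equal(out$values[, "const"], rep(0, 3))            # zero-variance rule
  expect_equal(out$values[1:2, "ramp"], c(-1, 1))           # population sd

  expect_identical(normalize_signals(sm, "none"), sm)

  neg <- signal_matrix(matrix(c(-1, 0, 1), 3, 1))
  expect_error(normalize_signals(neg, "log1p_zscore"), "zscore")
})

test_that("zscore output has mean 0 and population sd 1 over masked-in bins", {
  set.seed(7)
  for (r in 1:10) {
    n <- sample(5:50, 1)
    sm <- signal_matrix(matrix(rnorm(n * 3, sd = runif(1, 0.5, 5)), n, 3),
                        mask = runif(n) < 0.8)
    if (sum(sm$mask) < 3) next
    out <- normalize_signals(sm, "zscore")$values[sm$mask, ]
    expect_equal(unname(colMeans(out)), rep(0, 3), tolerance = 1e-9)
    expect_equal(unname(sqrt(colMeans(sweep(out, 2, colMeans(out))^2))),
                 rep(1, 3), tolerance = 1e-9)
  }
})

test_that("oe_transform divides by per-diagonal means within chromosomes", {
  b <- toy_bins(3)
  m <- sym_matrix(3, list(c(1, 2, 2), c(2, 3, 4)))
  oe <- oe_transform(contact_matrix(m, b))
  expect_equal(oe$values[1, 2], 2 / 3)   # diagonal-1 mean is (2+4)/2 = 3
  expect_equal(oe$values[2, 3], 4 / 3)
  expect_equal(oe$values[1, 3], 0)       # zero-mean diagonal stays zero

  const <- matrix(5, 4, 4); diag(const) <- 0
  oec <- oe_transform(contact_matrix(const, toy_bins(4)))
  off <- oec$values[upper.tri(oec$values)]
  expect_equal(off, rep(1, length(off)))
})

test_that("oe_transform leaves single-bin chromosomes unchanged and treats inter blocks globally", {
  b <- bin_genome(c(chr1 = 2e5, chr2 = 1e5), 1e5)  # 2 + 1 bins
  m <- sym_matrix(3, list(c(1, 2, 6), c(1, 3, 2), c(2, 3, 4)))
  oe <- oe_transform(contact_matrix(m, b))
  expect_equal(oe$values[1, 2], 1)                  # its own diagonal mean
  expect_equal(oe$values[1, 3], 2 / 3)              # inter mean is 3
  expect_equal(oe$values[2, 3], 4 / 3)
})

test_that("oe_transform preserves symmetry, nonnegativity, and is idempotent on constant-diagonal matrices", {
  set.seed(5)
  m <- matrix(rpois(100, 6), 10, 10)
  m <- m + t(m)
  oe <- oe_transform(contact_matrix(m, toy_bins(10)))
  expect_equal(oe$values, t(oe$values))
  expect_true(all(oe$values >= 0))

  const <- matrix(3, 6, 6)
  o1 <- oe_transform(contact_matrix(const, toy_bins(6)))
  o2 <- oe_transform(o1)
  expect_equal(o1$values, o2$values)
})

test_that("contact_matrix validates its invariants", {
  b <- toy_bins(2)
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(contact_matrix(asym, b), "symmetric")
  expect_error(contact_matrix(matrix(-1, 2, 2), b), "non-negative")
  expect_error(contact_matrix(matrix(0, 3, 3), b), "match")
})
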