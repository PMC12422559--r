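test_that("cosine_similarity_matrix matches hand values and rejects zero rows", {
  expect_equal(cosine_similarity_matrix(diag(3), diag(3)), diag(3))
  expect_equal(cosine_similarity_matrix(rbind(c(1, 0)), rbind(c(0, 1)))[1, 1], 0)
  expect_equal(cosine_similarity_matrix(rbind(c(1, 1)), rbind(c(1, 0)))[1, 1],
               1 / sqrt(2))
  expect_error(cosine_similarity_matrix(rbind(c(0, 0)), rbind(c(1, 0))),
               "zero-norm")
  expect_error(cosine_similarity_matrix(matrix(1, 2, 3), matrix(1, 2, 2)),
               "dimensionality")
})

test_that("info_nce_bidirectional matches its closed forms", {
  expect_equal(info_nce_bidirectional(rbind(c(1, 2)), rbind(c(1, 2)), tau = 1), 0)
  expect_equal(info_nce_bidirectional(diag(2), diag(2), tau = 1),
               log(1 + exp(-1)))
  expect_error(info_nce_bidirectional(diag(2), diag(2), tau = 0), "tau")
})

test_that("info_nce_bidirectional equals the double-loop oracle on random inputs", {
  set.seed(21)
  for (r in 1:25) {
    n <- sample(2:32, 1); d <- sample(2:8, 1); tau <- runif(1, 0.05, 2)
    S <- matrix(rnorm(n * d), n, d)
    F <- matrix(rnorm(n * d), n, d)
    expect_equal(info_nce_bidirectional(S, F, tau), info_nce_oracle(S, F, tau),
                 tolerance = 1e-6)
  }
})

test_that("info_nce is nonnegative and invariant to joint row permutation", {
  set.seed(8)
  for (r in 1:10) {
    n <- sample(2:16, 1)
    S <- matrix(rnorm(n * 4), n, 4)
    F <- matrix(rnorm(n * 4), n, 4)
    l <- info_nce_bidirectional(S, F, 0.3)
    expect_gte(l, 0)
    p <- sample.int(n)
    expect_equal(info_nce_bidirectional(S[p, ], F[p, ], 0.3), l)
  }
})

test_that("info_nce approaches 0 for perfectly aligned, mutually repelled pairs", {
  S <- diag(4)
  expect_lt(info_nce_bidirectional(S, S, tau = 0.02), 1e-8)
})

test_that("analytic InfoNCE gradient matches central finite differences", {
  set.seed(12)
  for (r in 1:5) {
    S <- matrix(rnorm(12), 4, 3)
    F <- matrix(rnorm(12), 4, 3)
    tau <- runif(1, 0.1, 1)
    g <- chromalign:::info_nce_gradient(S, F, tau)
    h <- 1e-5
    for (M in c("S", "F")) {
      X <- get(M)
      num <- X * 0
      for (i in 1:4) for (j in 1:3) {
        Xp <- X; Xp[i, j] <- X[i, j] + h
        Xm <- X; Xm[i, j] <- X[i, j] - h
        up <- if (M == "S") info_nce_bidirectional(Xp, F, tau) else
          info_nce_bidirectional(S, Xp, tau)
        dn <- if (M == "S") info_nce_bidirectional(Xm, F, tau) else
          info_nce_bidirectional(S, Xm, tau)
        num[i, j] <- (up - dn) / (2 * h)
      }
      expect_equal(num, if (M == "S") g$dS else g$dF, tolerance = 1e-4)
    }
  }
})

test_that("encoder_forward is an MLP with exact degenerate behaviour", {
  cfg <- encoder_config(activation = "relu")
  # single linear layer, identity weights -> identity map
  params <- list(list(W = diag(2), b = c(0, 0)))
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(encoder_forward(cfg, params, X), X)
  # zero final layer -> all-zero output
  params2 <- list(list(W = matrix(1, 2, 3), b = rep(0.5, 3)),
                  list(W = matrix(0, 3, 2), b = c(0, 0)))
  expect_equal(encoder_forward(cfg, params2, X), matrix(0, 2, 2))
  # fixed small parameters match hand linear algebra (relu(XW1+b1)W2)
  W1 <- matrix(c(1, -1, 0.5, 2), 2, 2); b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1, 0, -1, 1), 2, 2)
  params3 <- list(list(W = W1, b = b1), list(W = W2, b = c(0, 0)))
  H <- pmax(X %*% W1 + rep(1, 2) %o% b1, 0)
  expect_equal(encoder_forward(cfg, params3, X), H %*% W2)
  expect_error(encoder_forward(cfg, params, matrix(1, 2, 5)), "expects")
})

test_that("train_contrastive is reproducible and aligns planted structure", {
  set.seed(2)
  type <- rep(1:3, each = 12)
  hic <- diag(3)[type, ] + matrix(rnorm(36 * 3, sd = 0.05), 36, 3)
  sig <- signal_matrix(2 * diag(3)[type, c(2, 3, 1)] +
                         matrix(rnorm(36 * 3, sd = 0.05), 36, 3))
  cfg <- encoder_config(hidden_dims = 16, out_dim = 8, epochs = 100,
                        batch_size = 36, seed = 5)
  pe1 <- train_contrastive(hic, sig, cfg)
  pe2 <- train_contrastive(hic, sig, cfg)
  expect_identical(pe1$loss_history, pe2$loss_history)
  expect_identical(pe1$S, pe2$S)

  cs <- cosine_similarity_matrix(pe1$S, pe1$F)
  diag_mean <- mean(diag(cs))
  off_mean <- mean(cs[row(cs) != col(cs)])
  expect_gte(diag_mean - off_mean, 0.2)
})

test_that("initial loss is near log(n) for random encoders", {
  set.seed(14)
  n <- 32
  hic <- matrix(rnorm(n * 6), n, 6)
  sig <- signal_matrix(matrix(rnorm(n * 4), n, 4))
  cfg <- encoder_config(hidden_dims = 16, out_dim = 8, tau = 1, epochs = 1,
                        batch_size = n, seed = 3)
  pe <- train_contrastive(hic, sig, cfg)
  expect_equal(pe$loss_history[1], log(n), tolerance = 0.3 * log(n))
})

test_that("train_contrastive needs at least two usable bins", {
  sig <- signal_matrix(matrix(1, 3, 2), mask = c(TRUE, FALSE, FALSE))
  expect_error(train_contrastive(matrix(1, 3, 2), sig, encoder_config()),
               "fewer than 2")
})
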