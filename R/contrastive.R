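#' Encoder / training configuration for contrastive alignment
#'
#' @param in_dim Input dimensionality (may be `NULL`; filled from data).
#' @param hidden_dims Hidden layer widths of the MLP encoders.
#' @param out_dim Shared embedding dimensionality `d` of both encoders.
#' @param activation Hidden activation, `"relu"` or `"tanh"`.
#' @param tau Softmax temperature of the InfoNCE loss (fixed, not learned).
#' @param lr Adam learning rate.
#' @param epochs Training epochs. The default (30) stops once the two
#'   modalities agree per bin; much longer schedules let the loss optimize
#'   per-bin discriminability, which can erode coarse domain structure.
#' @param batch_size Mini-batch size; negatives are strictly in-batch.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(in_dim = NULL, hidden_dims = c(256L, 256L),
                           out_dim = 64L, activation = c("relu", "tanh"),
                           tau = 0.1, lr = 1e-3, epochs = 30L,
                           batch_size = 256L, seed = 1L) {
  activation <- match.arg(activation)
  if (tau <= 0) stop("tau must be positive")
  structure(list(in_dim = in_dim, hidden_dims = hidden_dims,
                 out_dim = as.integer(out_dim), activation = activation,
                 tau = tau, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "encoder_config")
}

#' Cosine similarity between two sets of row vectors
#'
#' @param S,F Numeric matrices with equal column count; entry (i, j) of the
#'   result is the cosine of the angle between row i of `S` and row j of `F`.
#' @return An `nrow(S)` x `nrow(F)` matrix with values in `[-1, 1]`.
#' @export
cosine_similarity_matrix <- function(S, F) {
  S <- rbind(S); F <- rbind(F)
  if (ncol(S) != ncol(F)) stop("S and F must share their dimensionality")
  ns <- sqrt(rowSums(S^2)); nf <- sqrt(rowSums(F^2))
  if (any(ns == 0) || any(nf == 0)) stop("zero-norm row in cosine similarity")
  (S / ns) %*% t(F / nf)
}

#' Bidirectional InfoNCE loss
#'
#' With `C = cosine_similarity_matrix(S, F) / tau`, returns the mean of the
#' row-wise and column-wise cross-entropies of the diagonal (matched pairs
#' against in-batch negatives):
#' `0.5 * [mean_i -log softmax_row(C)_ii + mean_j -log softmax_col(C)_jj]`.
#' For `n = 1` there are no negatives and the loss is exactly 0.
#'
#' @param S,F Matched n x d embedding matrices (row i of each comes from the
#'   same genomic bin).
#' @param tau Positive temperature.
#' @return Non-negative scalar.
#' @export
info_nce_bidirectional <- function(S, F, tau = 0.1) {
  if (tau <= 0) stop("tau must be positive")
  C <- cosine_similarity_matrix(S, F) / tau
  n <- nrow(C)
  # -log softmax over rows / columns, evaluated on the diagonal, stably
  row_lse <- apply(C, 1L, function(r) {m <- max(r); m + log(sum(exp(r - m)))})
  col_lse <- apply(C, 2L, function(r) {m <- max(r); m + log(sum(exp(r - m)))})
  0.5 * (mean(row_lse - diag(C)) + mean(col_lse - diag(C)))
}

# analytic gradient of info_nce_bidirectional with respect to S and F
info_nce_gradient <- function(S, F, tau = 0.1) {
  if (tau <= 0) stop("tau must be positive")
  S <- rbind(S); F <- rbind(F)
  n <- nrow(S)
  ns <- sqrt(rowSums(S^2)); nf <- sqrt(rowSums(F^2))
  Sh <- S / ns; Fh <- F / nf
  C <- (Sh %*% t(Fh)) / tau
  softmax_rows <- function(M) {
    M <- M - apply(M, 1L, max)
    E <- exp(M)
    E / rowSums(E)
  }
  Pr <- softmax_rows(C)
  Pc <- t(softmax_rows(t(C)))
  G <- (Pr - diag(n) + Pc - diag(n)) / (2 * n * tau)
  dSh <- G %*% Fh
  dFh <- t(G) %*% Sh
  # back through row normalization: d/dx of x/||x||
  dS <- (dSh - Sh * rowSums(dSh * Sh)) / ns
  dF <- (dFh - Fh * rowSums(dFh * Fh)) / nf
  list(dS = dS, dF = dF)
}

# ---- minimal MLP with Adam -------------------------------------------------

mlp_init <- function(in_dim, hidden_dims, out_dim) {
  dims <- c(in_dim, hidden_dims, out_dim)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1L]),
      b = numeric(dims[l + 1L]))
  }
  layers
}

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(x) pmax(x, 0), df = function(x, y) (x > 0) * 1),
         tanh = list(f = tanh, df = function(x, y) 1 - y^2),
         stop("unknown activation: ", name))
}

mlp_forward <- function(params, X, activation = "relu", keep_cache = FALSE) {
  a <- act_fun(activation)
  L <- length(params)
  cache <- if (keep_cache) vector("list", L) else NULL
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% params[[l]]$W + matrix(params[[l]]$b, nrow(H), length(params[[l]]$b),
                                      byrow = TRUE)
    if (keep_cache) cache[[l]] <- list(input = H, pre = Z)
    H <- if (l < L) a$f(Z) else Z
  }
  if (keep_cache) list(out = H, cache = cache) else H
}

mlp_backward <- function(params, cache, dOut, activation = "relu") {
  a <- act_fun(activation)
  L <- length(params)
  grads <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    H <- cache[[l]]$input
    grads[[l]] <- list(W = t(H) %*% delta, b = colSums(delta))
    if (l > 1L) {
      Zprev <- cache[[l - 1L]]$pre
      Yprev <- a$f(Zprev)
      delta <- (delta %*% t(params[[l]]$W)) * a$df(Zprev, Yprev)
    }
  }
  grads
}

#' Forward pass of an encoder
#'
#' A plain multilayer perceptron: affine map and activation per hidden layer,
#' final affine map to the shared embedding dimension. Deterministic given
#' the parameters.
#'
#' @param config An `encoder_config` (supplies the activation).
#' @param params Layer list as produced during training (`W`, `b` per layer).
#' @param X Input matrix, one row per bin.
#' @return Matrix of encoder outputs, `nrow(X)` x `out_dim`.
#' @export
encoder_forward <- function(config, params, X) {
  X <- rbind(X)
  if (ncol(X) != nrow(params[[1L]]$W))
    stop("input has ", ncol(X), " columns but encoder expects ",
         nrow(params[[1L]]$W))
  mlp_forward(params, X, config$activation)
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params)) {
    state[[l]]$mW <- beta1 * state[[l]]$mW + (1 - beta1) * grads[[l]]$W
    state[[l]]$vW <- beta2 * state[[l]]$vW + (1 - beta2) * grads[[l]]$W^2
    state[[l]]$mb <- beta1 * state[[l]]$mb + (1 - beta1) * grads[[l]]$b
    state[[l]]$vb <- beta2 * state[[l]]$vb + (1 - beta2) * grads[[l]]$b^2
    mW <- state[[l]]$mW / (1 - beta1^t); vW <- state[[l]]$vW / (1 - beta2^t)
    mb <- state[[l]]$mb / (1 - beta1^t); vb <- state[[l]]$vb / (1 - beta2^t)
    params[[l]]$W <- params[[l]]$W - lr * mW / (sqrt(vW) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb / (sqrt(vb) + eps)
  }
  list(params = params, state = state)
}

#' Train the structural and functional encoders contrastively
#'
#' Jointly optimizes two MLP encoders — one over per-bin Hi-C (LINE)
#' embeddings, one over per-bin epigenomic signal vectors — to minimize the
#' bidirectional InfoNCE loss over shuffled mini-batches, so that the two
#' modalities agree per bin in a shared d-dimensional space. Only masked-in
#' bins are used. Fully reproducible given `cfg$seed`.
#'
#' @param hic_emb Numeric matrix of Hi-C embeddings, one row per bin.
#' @param signals A `signal_matrix` (normalize first; see
#'   [normalize_signals()]).
#' @param cfg An [encoder_config()].
#' @return A `paired_embeddings` object: list with `S` and `F` (one row per
#'   masked-in bin), `loss_history` (mean loss per epoch), the trained
#'   `params_s`/`params_f`, `cfg` and the `mask` used.
#' @export
train_contrastive <- function(hic_emb, signals, cfg = encoder_config()) {
  mask <- signals$mask
  if (sum(mask) < 2L)
    stop("fewer than 2 masked-in bins: no in-batch negatives possible")
  Xs <- rbind(hic_emb)[mask, , drop = FALSE]
  Xf <- signals$values[mask, , drop = FALSE]
  n <- nrow(Xs)
  set.seed(cfg$seed)
  params_s <- mlp_init(ncol(Xs), cfg$hidden_dims, cfg$out_dim)
  params_f <- mlp_init(ncol(Xf), cfg$hidden_dims, cfg$out_dim)
  st_s <- adam_init(params_s)
  st_f <- adam_init(params_f)
  t_step <- 0L
  loss_hist <- numeric(cfg$epochs)
  bs <- max(2L, min(cfg$batch_size, n))
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    batch_losses <- c()
    for (s0 in starts) {
      b <- idx[s0:min(s0 + bs - 1L, n)]
      if (length(b) < 2L) next
      fs <- mlp_forward(params_s, Xs[b, , drop = FALSE], cfg$activation,
                        keep_cache = TRUE)
      ff <- mlp_forward(params_f, Xf[b, , drop = FALSE], cfg$activation,
                        keep_cache = TRUE)
      loss <- info_nce_bidirectional(fs$out, ff$out, cfg$tau)
      g <- info_nce_gradient(fs$out, ff$out, cfg$tau)
      gs <- mlp_backward(params_s, fs$cache, g$dS, cfg$activation)
      gf <- mlp_backward(params_f, ff$cache, g$dF, cfg$activation)
      t_step <- t_step + 1L
      up <- adam_step(params_s, gs, st_s, cfg$lr, t_step)
      params_s <- up$params; st_s <- up$state
      up <- adam_step(params_f, gf, st_f, cfg$lr, t_step)
      params_f <- up$params; st_f <- up$state
      batch_losses <- c(batch_losses, loss)
    }
    loss_hist[ep] <- mean(batch_losses)
  }
  S <- mlp_forward(params_s, Xs, cfg$activation)
  F <- mlp_forward(params_f, Xf, cfg$activation)
  structure(list(S = S, F = F, loss_history = loss_hist,
                 params_s = params_s, params_f = params_f,
                 cfg = cfg, mask = mask),
            class = "paired_embeddings")
}

#' @export
print.paired_embeddings <- function(x, ...) {
  cat(sprintf("paired_embeddings: %d bins x %d dims per modality; final loss %.4f\n",
              nrow(x$S), ncol(x$S), x$loss_history[length(x$loss_history)]))
  invisible(x)
}
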