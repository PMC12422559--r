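#' Build a weighted graph from a contact matrix
#'
#' Nodes are genomic bins; an undirected edge connects every pair of
#' masked-in bins with a positive contact weight. The diagonal is ignored.
#' With `top_k` set, each node nominates its `top_k` heaviest incident edges
#' and the union over endpoints is kept, sparsifying hairball graphs while
#' preserving every node's strongest neighbours.
#'
#' @param contacts A `contact_matrix` (typically after [oe_transform()]).
#' @param mask Logical usable-bin vector; defaults to all bins.
#' @param top_k Optional per-node edge budget.
#' @return A `weighted_graph`: list with `n_nodes` and an `edges` data frame
#'   (`i`, `j`, `w`), `i < j`, 1-based bin indices.
#' @export
build_graph <- function(contacts, mask = NULL, top_k = NULL) {
  v <- contacts$values
  n <- nrow(v)
  if (is.null(mask)) mask <- rep(TRUE, n)
  keep <- outer(mask, mask, "&")
  ut <- upper.tri(v)
  sel <- which(ut & keep & v > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("empty graph: no positive off-diagonal contacts")
  edges <- data.frame(i = sel[, 1L], j = sel[, 2L], w = v[sel])
  if (!is.null(top_k)) {
    stopifnot(top_k >= 1)
    keep_edge <- rep(FALSE, nrow(edges))
    incident <- vector("list", n)
    for (e in seq_len(nrow(edges))) {
      incident[[edges$i[e]]] <- c(incident[[edges$i[e]]], e)
      incident[[edges$j[e]]] <- c(incident[[edges$j[e]]], e)
    }
    for (node in seq_len(n)) {
      es <- incident[[node]]
      if (!length(es)) next
      ord <- es[order(-edges$w[es], es)]
      keep_edge[utils::head(ord, top_k)] <- TRUE
    }
    edges <- edges[keep_edge, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(n_nodes = n, edges = edges), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d nodes, %d edges, total weight %.4g\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$w)))
  invisible(x)
}

#' Build an alias table for O(1) discrete sampling
#'
#' Vose's alias method: preprocessing O(m), each draw O(1). The induced
#' sampling distribution equals `weights / sum(weights)`.
#'
#' @param weights Positive numeric vector.
#' @return An `alias_table`: list with `prob` and `alias` (1-based).
#' @export
build_alias_table <- function(weights) {
  m <- length(weights)
  if (m == 0L) stop("empty weight vector")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all weights must be positive and finite")
  p <- weights * m / sum(weights)
  prob <- numeric(m)
  alias <- integer(m)
  small <- which(p < 1)
  large <- which(p >= 1)
  while (length(small) && length(large)) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]; large <- large[-length(large)]
    prob[s] <- p[s]
    alias[s] <- l
    p[l] <- p[l] + p[s] - 1
    if (p[l] < 1) small <- c(small, l) else large <- c(large, l)
  }
  prob[c(small, large)] <- 1
  alias[c(small, large)] <- c(small, large)
  structure(list(prob = prob, alias = alias), class = "alias_table")
}

#' Sample from an alias table
#' @param table An `alias_table`.
#' @param n Number of draws.
#' @return Integer vector of 1-based indices.
#' @export
alias_sample <- function(table, n) {
  m <- length(table$prob)
  k <- floor(stats::runif(n) * m) + 1L
  flip <- stats::runif(n) > table$prob[k]
  k[flip] <- table$alias[k[flip]]
  k
}

#' Negative-sampling edge loss of LINE
#'
#' For a directed sample (i -> j) with negative contexts `neg`, returns
#' `-log sigma(u.v) - sum_k log sigma(-u.v_k)` with the logistic `sigma`,
#' computed in a numerically stable way.
#'
#' @param u Embedding vector of the source node.
#' @param v Context vector of the positive target.
#' @param neg Matrix of negative context vectors (rows), or `NULL`.
#' @return Non-negative scalar loss.
#' @export
line_edge_loss <- function(u, v, neg = NULL) {
  if (length(u) != length(v)) stop("dimension mismatch between u and v")
  softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  loss <- softplus(-sum(u * v))
  if (!is.null(neg)) {
    neg <- rbind(neg)
    if (ncol(neg) != length(u)) stop("dimension mismatch in negatives")
    loss <- loss + sum(softplus(as.vector(neg %*% u)))
  }
  loss
}

#' Train LINE node embeddings on a weighted graph
#'
#' Asynchronous SGD over edges drawn proportionally to their weight (alias
#' sampling), with `n_negatives` negative contexts per positive drawn from a
#' noise distribution proportional to weighted degree^0.75. Undirected edges
#' are trained as two directed draws with equal probability. The learning
#' rate decays linearly from `lr` to `lr/100`. Second-order proximity (the
#' default) uses separate context vectors; first-order shares the vertex
#' vectors on both sides. Zero-degree (e.g. masked-out) bins get zero rows.
#'
#' @param graph A `weighted_graph` from [build_graph()].
#' @param dim Embedding dimensionality (default 8).
#' @param order `"second"` or `"first"` proximity.
#' @param n_samples Number of SGD edge samples.
#' @param n_negatives Negatives per positive (default 5).
#' @param lr Initial learning rate (default 0.025).
#' @param seed Optional integer seed; fixing it makes training bitwise
#'   reproducible.
#' @return Numeric matrix `n_nodes` x `dim` with attribute `loss_history`
#'   (mean sampled loss in 100 equal training windows).
#' @export
train_line <- function(graph, dim = 8L, order = c("second", "first"),
                       n_samples = 1e6, n_negatives = 5L, lr = 0.025,
                       seed = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(graph, "weighted_graph"))
  if (n_samples <= 0) stop("n_samples must be positive")
  if (dim < 1L) stop("dim must be >= 1")
  if (nrow(graph$edges) < 1L) stop("graph has no edges")
  if (!is.null(seed)) set.seed(seed)

  edges <- graph$edges
  edge_at <- build_alias_table(edges$w)
  deg <- numeric(graph$n_nodes)
  for (e in seq_len(nrow(edges))) {
    deg[edges$i[e]] <- deg[edges$i[e]] + edges$w[e]
    deg[edges$j[e]] <- deg[edges$j[e]] + edges$w[e]
  }
  active <- which(deg > 0)
  neg_at <- build_alias_table(deg[active]^0.75)

  res <- line_sgd_cpp(
    ei = edges$i - 1L, ej = edges$j - 1L,
    eprob = edge_at$prob, ealias = edge_at$alias - 1L,
    neg_nodes = active - 1L, nprob = neg_at$prob, nalias = neg_at$alias - 1L,
    n_nodes = graph$n_nodes, dim = as.integer(dim),
    second_order = (order == "second"),
    n_samples = as.double(n_samples), n_neg = as.integer(n_negatives),
    lr = lr, n_loss_bins = 100L)

  emb <- res$embedding
  emb[deg == 0, ] <- 0
  attr(emb, "loss_history") <- res$loss_history
  emb
}
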