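# Shared fixtures and independent oracles. The oracles deliberately use
# dense per-node loops / exhaustive enumeration, not the package's sparse
# code paths.

# write a TSV fixture from lines
writeTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# a small deterministic featured graph
tinyGraph <- function(n = 12L, d = 4L, seed = 42L, edgesPer = 2L) {
  cfg <- syntheticConfig(
    nNodes = n, topologyParams = list(m = edgesPer),
    nFeatures = d, effectSize = 1, homophilyRounds = 0L,
    labelFraction = 0.5, posFraction = 0.4, seed = seed
  )
  generateFeaturedGraph(cfg)
}

# random simple undirected graph as an edge matrix (may be disconnected)
randomEdges <- function(n, p = 0.3) {
  em <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(em)) < p
  m <- em[keep, , drop = FALSE]
  matrix(as.integer(m), ncol = 2L)
}

# dense brute-force GCN layer: ReLU(W . mean over N(v) union {v})
denseGcn <- function(X, edges, W, symNorm = FALSE) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- 1
    A[edges[k, 2], edges[k, 1]] <- 1
  }
  out <- matrix(0, n, nrow(W))
  for (v in seq_len(n)) {
    nb <- c(v, which(A[v, ] == 1))
    if (symNorm) {
      dv <- sum(A[v, ]) + 1
      agg <- numeric(ncol(X))
      for (u in nb) {
        du <- sum(A[u, ]) + 1
        agg <- agg + X[u, ] / sqrt(dv * du)
      }
    } else {
      agg <- colMeans(X[nb, , drop = FALSE])
    }
    out[v, ] <- pmax(as.numeric(W %*% agg), 0)
  }
  out
}

# dense brute-force GIN aggregation: (1+eps) f_v + sum over neighbours,
# followed by the two-layer MLP when given
denseGin <- function(X, edges, mlp = NULL, epsilon = 0) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- 1
    A[edges[k, 2], edges[k, 1]] <- 1
  }
  M <- matrix(0, n, ncol(X))
  for (v in seq_len(n)) {
    s <- (1 + epsilon) * X[v, ]
    for (u in which(A[v, ] == 1)) s <- s + X[u, ]
    M[v, ] <- s
  }
  if (is.null(mlp)) {
    return(M)
  }
  out <- matrix(0, n, nrow(mlp$W2))
  for (v in seq_len(n)) {
    h <- pmax(as.numeric(mlp$W1 %*% M[v, ]) + mlp$b1, 0)
    out[v, ] <- as.numeric(mlp$W2 %*% h) + mlp$b2
  }
  out
}

# exhaustive average precision: enumerate descending unique thresholds and
# accumulate (R_k - R_{k-1}) * P_k with a plain loop
bruteAuprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0
  ap <- 0
  nPos <- sum(labels == 1)
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    P <- tp / sum(sel)
    R <- tp / nPos
    ap <- ap + (R - prevR) * P
    prevR <- R
  }
  ap
}

# numerical gradient of a scalar function of a GnnStack parameter entry
finiteDiffStack <- function(stack, layer, name, index, lossFn, eps = 1e-6) {
  s1 <- stack
  s1@layers[[layer]][[name]][index] <- s1@layers[[layer]][[name]][index] + eps
  s2 <- stack
  s2@layers[[layer]][[name]][index] <- s2@layers[[layer]][[name]][index] - eps
  (lossFn(s1) - lossFn(s2)) / (2 * eps)
}
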