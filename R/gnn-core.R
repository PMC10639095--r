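# Message-passing layers and encoder/decoder stacks.
#
# A GCN layer updates each node with ReLU(W . mean over the node and its
# neighbours); a GIN layer applies an MLP to (1 + epsilon) * own features +
# neighbour sum. A GnnStack wires layers with residual links (projection
# where widths differ), per-row layer normalization, and a single ReLU per
# hidden layer; the decoder's last layer stays linear so reconstructions can
# take negative values. The aggregation is implemented with sparse operators
# (Matrix); test oracles use dense per-node loops.

# mean-over-{v} union N(v) propagation operator, or symmetric normalization
.gcnOperator <- function(nNodes, edges, symNorm = FALSE) {
  A <- .adjacency(nNodes, edges)
  AI <- A + Matrix::Diagonal(nNodes)
  if (symNorm) {
    dInv <- 1 / sqrt(Matrix::rowSums(AI))
    Matrix::Diagonal(x = dInv) %*% AI %*% Matrix::Diagonal(x = dInv)
  } else {
    Matrix::Diagonal(x = 1 / Matrix::rowSums(AI)) %*% AI
  }
}

# (1 + epsilon) I + A operator for GIN
.ginOperator <- function(nNodes, edges, epsilon = 0) {
  .adjacency(nNodes, edges) + Matrix::Diagonal(nNodes, x = 1 + epsilon)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Glorot-uniform weight matrix (out x in)
.glorot <- function(nOut, nIn) {
  lim <- sqrt(6 / (nIn + nOut))
  matrix(stats::runif(nOut * nIn, -lim, lim), nrow = nOut, ncol = nIn)
}

.fixedParam <- function(x) structure(x, class = "fixedParam")

#' GCN layer forward pass
#'
#' Computes, for every node `v`, `activation(W . mean(features over N(v) and
#' v itself))`. Isolated nodes aggregate over themselves only. The default
#' uniform mean over the closed neighbourhood can be switched to the
#' symmetric degree normalization of the original GCN with
#' `symNorm = TRUE`.
#'
#' @param features numeric matrix, one row per node.
#' @param edges two-column integer edge matrix.
#' @param W weight matrix, `outputDim x inputDim`.
#' @param activation `"relu"` (default) or `"identity"` (used inside stacks,
#'   where the ReLU follows normalization).
#' @param symNorm use symmetric degree normalization instead of the uniform
#'   closed-neighbourhood mean.
#' @return numeric matrix `nNodes x outputDim`.
#' @examples
#' # path 1-2-3, scalar features: node 2 aggregates mean(1, 2, 3) = 2
#' gcnLayerForward(matrix(1:3), rbind(c(1L, 2L), c(2L, 3L)), matrix(1))
#' @export
gcnLayerForward <- function(features, edges, W,
                            activation = c("relu", "identity"),
                            symNorm = FALSE) {
  activation <- match.arg(activation)
  features <- as.matrix(features)
  if (ncol(W) != ncol(features)) {
    .stopf(
      "weight shape mismatch: W has %d input columns, features have %d",
      ncol(W), ncol(features)
    )
  }
  P <- .gcnOperator(nrow(features), edges, symNorm)
  Z <- as.matrix(P %*% features) %*% t(W)
  if (activation == "relu") .relu(Z) else Z
}

#' GIN layer forward pass
#'
#' Computes `MLP((1 + epsilon) * f_v + sum of neighbour features)`.
#' `epsilon` is a fixed hyperparameter, not learned. When `mlp` is `NULL`
#' the MLP is the identity (useful for inspecting the aggregation); a
#' learned MLP is a two-linear-layer perceptron with a ReLU between,
#' supplied as `list(W1, b1, W2, b2)`.
#'
#' @param features numeric matrix, one row per node.
#' @param edges two-column integer edge matrix.
#' @param mlp `NULL` for identity, else `list(W1, b1, W2, b2)` with `W1`
#'   (`hidden x in`), `W2` (`out x hidden`).
#' @param epsilon fixed self-weight offset (default 0).
#' @return numeric matrix of node outputs.
#' @examples
#' # node 1 with neighbours 2, 3 and identity MLP: 1 + 2 + 3 = 6
#' ginLayerForward(matrix(1:3), rbind(c(1L, 2L), c(1L, 3L)), mlp = NULL)[1, ]
#' @export
ginLayerForward <- function(features, edges, mlp = NULL, epsilon = 0) {
  features <- as.matrix(features)
  S <- .ginOperator(nrow(features), edges, epsilon)
  M <- as.matrix(S %*% features)
  if (is.null(mlp)) {
    return(M)
  }
  if (ncol(mlp$W1) != ncol(features)) {
    .stopf(
      "weight shape mismatch: W1 has %d input columns, features have %d",
      ncol(mlp$W1), ncol(features)
    )
  }
  A1 <- .relu(sweep(M %*% t(mlp$W1), 2L, mlp$b1, `+`))
  sweep(A1 %*% t(mlp$W2), 2L, mlp$b2, `+`)
}

#' Construct a message-passing stack
#'
#' Builds a GCN or GIN stack of `nHidden` layers with Glorot-initialized
#' weights. Residual links connect consecutive layers, with a linear
#' projection inserted (and reported) where widths differ; layer
#' normalization and a ReLU follow each hidden layer. With
#' `finalLinear = TRUE` the last layer skips both, which is how the decoder
#' reconstructs unconstrained feature values.
#'
#' @param layerKind `"gcn"` or `"gin"`.
#' @param inputDim input feature width.
#' @param hiddenDim hidden width (default 256).
#' @param nHidden number of hidden layers (default 3).
#' @param outputDim width of the last layer (defaults to `hiddenDim`; set to
#'   the feature width for a decoder).
#' @param useResidual,useLayernorm wiring flags (default `TRUE`).
#' @param finalLinear last layer omits normalization and activation.
#' @param symNorm GCN aggregation switch, see [gcnLayerForward()].
#' @param epsilon fixed GIN self-weight offset.
#' @param seed integer seed for weight initialization.
#' @return a [GnnStack-class].
#' @export
gnnStack <- function(layerKind = c("gcn", "gin"), inputDim, hiddenDim = 256L,
                     nHidden = 3L, outputDim = hiddenDim, useResidual = TRUE,
                     useLayernorm = TRUE, finalLinear = FALSE, symNorm = FALSE,
                     epsilon = 0, seed = 1L) {
  layerKind <- match.arg(layerKind)
  if (nHidden < 1L) .stopf("nHidden must be at least 1")
  layers <- .withSeed(seed, {
    lapply(seq_len(nHidden), function(i) {
      dIn <- if (i == 1L) inputDim else hiddenDim
      dOut <- if (i == nHidden) outputDim else hiddenDim
      l <- if (layerKind == "gcn") {
        list(W = .glorot(dOut, dIn))
      } else {
        list(
          W1 = .glorot(dOut, dIn), b1 = numeric(dOut),
          W2 = .glorot(dOut, dOut), b2 = numeric(dOut),
          epsilon = .fixedParam(epsilon)
        )
      }
      isLast <- i == nHidden
      if (useLayernorm && !(finalLinear && isLast)) {
        l$gamma <- rep(1, dOut)
        l$beta <- numeric(dOut)
      }
      if (useResidual && dIn != dOut) {
        message(sprintf(
          "gnnStack: residual projection %d -> %d inserted at layer %d",
          dIn, dOut, i
        ))
        l$proj <- .glorot(dOut, dIn)
      }
      l
    })
  })
  new("GnnStack",
    layerKind = layerKind, layers = layers,
    inputDim = as.integer(inputDim), hiddenDim = as.integer(hiddenDim),
    outputDim = as.integer(outputDim), nHidden = as.integer(nHidden),
    useResidual = useResidual, useLayernorm = useLayernorm,
    finalLinear = finalLinear, symNorm = symNorm
  )
}

# forward pass with cached intermediates for backprop.
# X: input features (n x inputDim); edges: canonical edge matrix.
.stackForwardCache <- function(X, edges, stack) {
  n <- nrow(X)
  P <- if (stack@layerKind == "gcn") {
    .gcnOperator(n, edges, stack@symNorm)
  } else {
    NULL
  }
  H <- X
  caches <- vector("list", stack@nHidden)
  embeddings <- vector("list", stack@nHidden)
  for (i in seq_len(stack@nHidden)) {
    l <- stack@layers[[i]]
    cache <- list(Hin = H)
    if (stack@layerKind == "gcn") {
      AH <- as.matrix(P %*% H)
      Z <- AH %*% t(l$W)
      cache$AH <- AH
    } else {
      S <- .ginOperator(n, edges, as.numeric(l$epsilon))
      M <- as.matrix(S %*% H)
      Z1 <- sweep(M %*% t(l$W1), 2L, l$b1, `+`)
      A1 <- .relu(Z1)
      Z <- sweep(A1 %*% t(l$W2), 2L, l$b2, `+`)
      cache$S <- S
      cache$M <- M
      cache$Z1 <- Z1
      cache$A1 <- A1
    }
    if (stack@useResidual) {
      Z <- Z + if (is.null(l$proj)) H else H %*% t(l$proj)
    }
    isLast <- i == stack@nHidden
    if (stack@finalLinear && isLast) {
      Hout <- Z
    } else {
      N <- Z
      if (stack@useLayernorm) {
        mu <- rowMeans(Z)
        xc <- Z - mu
        invstd <- 1 / sqrt(rowMeans(xc * xc) + 1e-5)
        xhat <- xc * invstd
        N <- sweep(sweep(xhat, 2L, l$gamma, `*`), 2L, l$beta, `+`)
        cache$xhat <- xhat
        cache$invstd <- invstd
      }
      Hout <- .relu(N)
      cache$N <- N
    }
    if (!all(is.finite(Hout))) {
      .stopf("non-finite activation in layer %d", i)
    }
    caches[[i]] <- cache
    embeddings[[i]] <- Hout
    H <- Hout
  }
  list(embeddings = embeddings, caches = caches, P = P)
}

#' Run a stack over a graph
#'
#' Applies every layer of the stack to the graph's node features (or the
#' masked features of a [MaskedGraph-class]) and returns the embedding after
#' each layer, aligned to node order. All per-layer embeddings are returned
#' because the graph-level readout concatenates them.
#'
#' @param graph a [FeaturedGraph-class] or [MaskedGraph-class].
#' @param stack a [GnnStack-class] whose input width matches the feature
#'   width.
#' @return list of numeric matrices, one per layer.
#' @export
stackForward <- function(graph, stack) {
  if (is(graph, "MaskedGraph")) graph <- graph@graph
  X <- nodeFeatures(graph)
  if (ncol(X) != stack@inputDim) {
    .stopf(
      "feature width %d does not match stack input width %d",
      ncol(X), stack@inputDim
    )
  }
  .stackForwardCache(X, edgeMatrix(graph), stack)$embeddings
}

# backward pass: dH is the gradient w.r.t. the final layer output.
# Returns grads (same nesting as stack@layers) and dX (gradient w.r.t. X).
.stackBackward <- function(fw, edges, stack, dH) {
  grads <- vector("list", stack@nHidden)
  for (i in rev(seq_len(stack@nHidden))) {
    l <- stack@layers[[i]]
    cache <- fw$caches[[i]]
    g <- list()
    isLast <- i == stack@nHidden
    if (stack@finalLinear && isLast) {
      dZ <- dH
    } else {
      dN <- dH
      dN[cache$N <= 0] <- 0
      if (stack@useLayernorm) {
        g$gamma <- colSums(dN * cache$xhat)
        g$beta <- colSums(dN)
        dxhat <- sweep(dN, 2L, l$gamma, `*`)
        m1 <- rowMeans(dxhat)
        m2 <- rowMeans(dxhat * cache$xhat)
        dZ <- (dxhat - m1 - cache$xhat * m2) * cache$invstd
      } else {
        dZ <- dN
      }
    }
    dHin <- matrix(0, nrow(cache$Hin), ncol(cache$Hin))
    if (stack@useResidual) {
      if (is.null(l$proj)) {
        dHin <- dHin + dZ
      } else {
        g$proj <- crossprod(dZ, cache$Hin)
        dHin <- dHin + dZ %*% l$proj
      }
    }
    if (stack@layerKind == "gcn") {
      g$W <- crossprod(dZ, cache$AH)
      dAH <- dZ %*% l$W
      dHin <- dHin + as.matrix(Matrix::crossprod(fw$P, dAH))
    } else {
      g$b2 <- colSums(dZ)
      g$W2 <- crossprod(dZ, cache$A1)
      dA1 <- dZ %*% l$W2
      dZ1 <- dA1
      dZ1[cache$Z1 <= 0] <- 0
      g$b1 <- colSums(dZ1)
      g$W1 <- crossprod(dZ1, cache$M)
      dM <- dZ1 %*% l$W1
      dHin <- dHin + as.matrix(cache$S %*% dM) # S is symmetric
      g$epsilon <- l$epsilon # fixed, passes through the optimizer untouched
    }
    # keep grads in the same field order as the layer parameters
    grads[[i]] <- g[names(l)[names(l) %in% names(g)]]
    dH <- dHin
  }
  list(grads = grads, dX = dH)
}

#' Mean readout over nodes, concatenated across layers
#'
#' Collapses per-layer node embeddings into one graph-level vector: the
#' arithmetic mean over nodes within each layer, concatenated in layer
#' order (so a 3-layer stack of width 256 yields a 768-long vector).
#' Permutation-invariant in the node order.
#'
#' @param perLayer list of node-embedding matrices, as returned by
#'   [stackForward()].
#' @return numeric vector of length `sum(layer widths)`.
#' @export
readoutMean <- function(perLayer) {
  if (!length(perLayer)) .stopf("readout needs at least one layer output")
  if (nrow(perLayer[[1L]]) == 0L) .stopf("readout of an empty graph is undefined")
  unlist(lapply(perLayer, colMeans), use.names = FALSE)
}
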