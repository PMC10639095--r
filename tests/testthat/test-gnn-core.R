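test_that("GCN layer matches hand-computed closed-neighbourhood means", {
  # isolated node, identity weights: ReLU clamps the negative coordinate
  out <- gcnLayerForward(
    matrix(c(-1, 2), nrow = 1), matrix(integer(0), ncol = 2),
    diag(2)
  )
  expect_equal(as.numeric(out), c(0, 2))

  # path 1-2-3 with scalar features (1,2,3): node 2 sees mean(1,2,3) = 2
  out2 <- gcnLayerForward(
    matrix(c(1, 2, 3)), rbind(c(1L, 2L), c(2L, 3L)),
    matrix(1)
  )
  expect_equal(as.numeric(out2), c(1.5, 2, 2.5))

  expect_error(
    gcnLayerForward(matrix(1, 2, 3), matrix(integer(0), ncol = 2), matrix(1, 2, 2)),
    "shape"
  )
})

test_that("GIN layer matches hand-computed sums and respects epsilon", {
  edges <- rbind(c(1L, 2L), c(1L, 3L))
  X <- matrix(c(1, 2, 3))
  # identity MLP: node 1 aggregates 1 + 2 + 3 = 6
  expect_equal(as.numeric(ginLayerForward(X, edges, mlp = NULL))[1], 6)
  # isolated node with identity MLP and epsilon 0 keeps its features
  iso <- ginLayerForward(matrix(c(4, -2), 1), matrix(integer(0), ncol = 2), mlp = NULL)
  expect_equal(as.numeric(iso), c(4, -2))
  # epsilon scales the self term
  expect_equal(as.numeric(ginLayerForward(X, edges, mlp = NULL, epsilon = 1))[1], 7)
})

test_that("sparse layer implementations match dense brute-force oracles", {
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(3:20, 1)
    d <- sample(2:5, 1)
    edges <- randomEdges(n, 0.3)
    X <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(3 * d), 3, d)
    expect_lt(max(abs(gcnLayerForward(X, edges, W) - denseGcn(X, edges, W))), 1e-10)
    expect_lt(
      max(abs(gcnLayerForward(X, edges, W, symNorm = TRUE) -
        denseGcn(X, edges, W, symNorm = TRUE))), 1e-10
    )
    mlp <- list(
      W1 = matrix(rnorm(4 * d), 4, d), b1 = rnorm(4),
      W2 = matrix(rnorm(2 * 4), 2, 4), b2 = rnorm(2)
    )
    eps <- runif(1)
    expect_lt(
      max(abs(ginLayerForward(X, edges, mlp, eps) -
        denseGin(X, edges, mlp, eps))), 1e-10
    )
  }
})

test_that("node operations are permutation equivariant", {
  set.seed(12)
  n <- 15
  edges <- randomEdges(n, 0.3)
  X <- matrix(rnorm(n * 3), n, 3)
  W <- matrix(rnorm(6), 2, 3)
  perm <- sample(n)
  inv <- order(perm)
  permEdges <- matrix(inv[edges], ncol = 2)
  out <- gcnLayerForward(X, edges, W)
  outPerm <- gcnLayerForward(X[perm, ], permEdges, W)
  expect_equal(outPerm, out[perm, ], tolerance = 1e-12)
  outG <- ginLayerForward(X, edges, mlp = NULL)
  outGPerm <- ginLayerForward(X[perm, ], permEdges, mlp = NULL)
  expect_equal(outGPerm, outG[perm, ], tolerance = 1e-12)
})

test_that("a one-layer stack without extras reduces to the bare layer", {
  sim <- tinyGraph(n = 10, d = 3, seed = 2)
  g <- sim$graph
  stack <- gnnStack("gcn",
    inputDim = 3, hiddenDim = 3, nHidden = 1,
    useResidual = FALSE, useLayernorm = FALSE, seed = 4
  )
  emb <- stackForward(g, stack)
  expect_length(emb, 1L)
  direct <- gcnLayerForward(nodeFeatures(g), edgeMatrix(g), stack@layers[[1]]$W)
  expect_equal(emb[[1]], direct, tolerance = 1e-12)
})

test_that("zero-weight layers with residual links pass the normalized input through", {
  # 2 nodes, 1 edge; W = 0 so the layer output is exactly the residual,
  # then LayerNorm and ReLU: hand-trace of the documented wiring
  g <- FeaturedGraph(
    nodeIds = c("A", "B"), edges = rbind(c(1L, 2L)),
    features = rbind(c(1, 3), c(2, 0))
  )
  stack <- gnnStack("gcn", inputDim = 2, hiddenDim = 2, nHidden = 1, seed = 1)
  stack@layers[[1]]$W <- matrix(0, 2, 2)
  out <- stackForward(g, stack)[[1]]
  ln <- function(x) {
    xc <- x - mean(x)
    pmax(xc / sqrt(mean(xc^2) + 1e-5), 0)
  }
  expect_equal(unname(out[1, ]), ln(c(1, 3)), tolerance = 1e-10)
  expect_equal(unname(out[2, ]), ln(c(2, 0)), tolerance = 1e-10)
})

test_that("all-equal features give all-equal GCN outputs on any graph", {
  set.seed(5)
  edges <- randomEdges(12, 0.4)
  X <- matrix(rep(c(1, -2, 0.5), each = 12), 12, 3)
  out <- gcnLayerForward(X, edges, matrix(rnorm(9), 3, 3))
  expect_lt(max(apply(out, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("mean readout concatenates per-layer means and ignores node order", {
  one <- list(rbind(c(1, 1), c(3, 3)))
  expect_equal(readoutMean(one), c(2, 2))

  stack <- suppressMessages(
    gnnStack("gin", inputDim = 4, hiddenDim = 256, nHidden = 3, seed = 3)
  )
  sim <- tinyGraph(n = 8, d = 4, seed = 6)
  vec <- readoutMean(stackForward(sim$graph, stack))
  expect_length(vec, 768L) # three layers of width 256

  perm <- sample(8)
  g <- sim$graph
  inv <- order(perm)
  gP <- FeaturedGraph(
    nodeIds(g)[perm],
    matrix(inv[edgeMatrix(g)], ncol = 2),
    nodeFeatures(g)[perm, ]
  )
  expect_equal(readoutMean(stackForward(gP, stack)), vec, tolerance = 1e-9)
  expect_error(readoutMean(list()), "at least one layer")
})

test_that("stack gradients agree with finite differences through every component", {
  set.seed(44)
  sim <- tinyGraph(n = 12, d = 4, seed = 9)
  X <- nodeFeatures(sim$graph)
  edges <- edgeMatrix(sim$graph)
  target <- matrix(rnorm(12 * 4), 12, 4)
  for (kind in c("gcn", "gin")) {
    stack <- suppressMessages(gnnStack(kind,
      inputDim = 4, hiddenDim = 5,
      nHidden = 2, outputDim = 4, finalLinear = TRUE, seed = 11
    ))
    lossFn <- function(s) {
      out <- GraphMaskAE:::.stackForwardCache(X, edges, s)$embeddings[[2]]
      sum((out - target)^2) / 2
    }
    fw <- GraphMaskAE:::.stackForwardCache(X, edges, stack)
    dOut <- fw$embeddings[[2]] - target
    bw <- GraphMaskAE:::.stackBackward(fw, edges, stack, dOut)
    for (li in 1:2) {
      for (nm in names(stack@layers[[li]])) {
        if (inherits(stack@layers[[li]][[nm]], "fixedParam")) next
        P <- stack@layers[[li]][[nm]]
        for (k in sample(length(P), min(3, length(P)))) {
          fd <- finiteDiffStack(stack, li, nm, k, lossFn)
          expect_lt(abs(fd - bw$grads[[li]][[nm]][k]), 1e-5)
        }
      }
    }
    # gradient w.r.t. the input features (feeds the mask token update)
    for (k in sample(length(X), 4)) {
      X2 <- X
      X2[k] <- X[k] + 1e-6
      X3 <- X
      X3[k] <- X[k] - 1e-6
      f2 <- sum((GraphMaskAE:::.stackForwardCache(X2, edges, stack)$embeddings[[2]] - target)^2) / 2
      f3 <- sum((GraphMaskAE:::.stackForwardCache(X3, edges, stack)$embeddings[[2]] - target)^2) / 2
      expect_lt(abs((f2 - f3) / 2e-6 - bw$dX[k]), 1e-5)
    }
  }
})
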