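test_that("masking replaces exactly the sampled rows and nothing else", {
  sim <- tinyGraph(n = 10, d = 4, seed = 3)
  g <- sim$graph
  X <- nodeFeatures(g)

  mg0 <- applyMask(g, maskSpec(0), seed = 1)
  expect_identical(nodeFeatures(mg0@graph), X)

  mg1 <- applyMask(g, maskSpec(1), seed = 1)
  expect_true(all(nodeFeatures(mg1@graph) == 0))
  expect_identical(edgeMatrix(mg1@graph), edgeMatrix(g))

  mg <- applyMask(g, maskSpec(0.5), seed = 5)
  idx <- maskedIndices(mg)
  expect_length(idx, 5L)
  expect_identical(
    nodeFeatures(mg@graph)[-idx, , drop = FALSE],
    X[-idx, , drop = FALSE]
  )
  expect_true(all(nodeFeatures(mg@graph)[idx, ] == 0))
  expect_error(maskSpec(1.5), "\\[0, 1\\]")
})

test_that("a custom token is substituted verbatim and the mask is seed-reproducible", {
  sim <- tinyGraph(n = 20, d = 3, seed = 8)
  tok <- c(-1, 0.5, 2)
  a <- applyMask(sim$graph, maskSpec(0.4, token = tok), seed = 9)
  b <- applyMask(sim$graph, maskSpec(0.4, token = tok), seed = 9)
  expect_identical(maskedIndices(a), maskedIndices(b))
  expect_true(all(t(nodeFeatures(a@graph)[maskedIndices(a), ]) == tok))
})

test_that("scaled cosine error matches hand and brute-force cosine computations", {
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(sceLoss(X, X), 0)
  expect_equal(sceLoss(-X, X), 2)

  # two-row hand example: rows (1,0) vs (1,1), and an identical second row
  R <- rbind(c(1, 0), c(2, 5))
  V <- rbind(c(1, 1), c(2, 5))
  expect_equal(sceLoss(R, V), mean(c(1 - 1 / sqrt(2), 0)), tolerance = 1e-12)

  # brute-force per-row cosine oracle
  set.seed(2)
  A <- matrix(rnorm(40), 10, 4)
  B <- matrix(rnorm(40), 10, 4)
  brute <- mean(sapply(1:10, function(i) {
    1 - sum(A[i, ] * B[i, ]) / (sqrt(sum(A[i, ]^2)) * sqrt(sum(B[i, ]^2)))
  }))
  expect_lt(abs(sceLoss(A, B) - brute), 1e-8)

  # scale invariance of the reconstruction rows
  pos <- runif(10, 0.1, 5)
  expect_equal(sceLoss(A * pos, B), sceLoss(A, B), tolerance = 1e-12)

  # gamma sharpening and the zero-norm error
  expect_equal(sceLoss(-X, X, gamma = 2), 4)
  Z <- A
  Z[3, ] <- 0
  expect_error(sceLoss(Z, B), "node 3")
})

test_that("the SCE gradient is exact against finite differences", {
  set.seed(9)
  A <- matrix(rnorm(24), 6, 4)
  B <- matrix(rnorm(24), 6, 4)
  for (gamma in c(1, 2)) {
    lg <- GraphMaskAE:::.sceLossGrad(A, B, scopeIndices = c(1, 3, 5), gamma = gamma)
    for (k in sample(24, 6)) {
      A2 <- A
      A2[k] <- A[k] + 1e-6
      A3 <- A
      A3[k] <- A[k] - 1e-6
      fd <- (sceLoss(A2, B, c(1, 3, 5), gamma) - sceLoss(A3, B, c(1, 3, 5), gamma)) / 2e-6
      expect_lt(abs(fd - lg$grad[k]), 1e-6)
    }
  }
})

test_that("pretraining reduces the reconstruction loss and is seed-deterministic", {
  cfg <- syntheticConfig(
    nNodes = 200, nFeatures = 8, effectSize = 2,
    homophilyRounds = 1, seed = 4
  )
  sim <- generateFeaturedGraph(cfg)
  enc <- suppressMessages(gnnStack("gcn", inputDim = 8, hiddenDim = 16, nHidden = 2, seed = 1))
  dec <- suppressMessages(gnnStack("gcn",
    inputDim = 16, hiddenDim = 16, nHidden = 2,
    outputDim = 8, finalLinear = TRUE, seed = 2
  ))
  cfg0 <- pretrainConfig(epochs = 0, seed = 3)
  same <- pretrain(sim$graph, enc, dec, maskSpec(0.5), cfg0)
  expect_identical(same$encoder@layers, enc@layers)
  expect_length(same$lossTrace, 0L)

  cfg30 <- pretrainConfig(epochs = 30, learningRate = 0.01, seed = 3)
  run1 <- pretrain(sim$graph, enc, dec, maskSpec(0.5), cfg30)
  expect_lt(run1$lossTrace[30], run1$lossTrace[1])
  run2 <- pretrain(sim$graph, enc, dec, maskSpec(0.5), cfg30)
  expect_identical(run1$lossTrace, run2$lossTrace)
  expect_false(all(run1$token == 0)) # the learnable token moved
})

test_that("masked-only loss scope restricts the objective to masked nodes", {
  sim <- tinyGraph(n = 30, d = 4, seed = 11)
  g <- sim$graph
  X <- nodeFeatures(g)
  R <- X
  R[1:5, ] <- -R[1:5, ] # perfect everywhere except five antipodal rows
  expect_equal(sceLoss(R, X, scopeIndices = 1:5), 2)
  expect_equal(sceLoss(R, X, scopeIndices = 6:30), 0)
  expect_equal(sceLoss(R, X), 2 * 5 / 30)
})
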