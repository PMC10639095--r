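test_that("weighted masked BCE matches hand-computed values", {
  expect_equal(wmbceLoss(0, 1, 1, 1), log(2), tolerance = 1e-12)
  # r multiplies only the positive term: a negative at p = 0 is unaffected
  expect_equal(wmbceLoss(0, 0, 1, 3), log(2), tolerance = 1e-12)
  expect_equal(wmbceLoss(2, 1, 1, 3), -3 * log(1 / (1 + exp(-2))),
    tolerance = 1e-12
  )
  expect_equal(wmbceLoss(2, 1, 1, 3), 0.380785, tolerance = 1e-5)
  expect_error(wmbceLoss(c(0, 1), c(1, 0), c(0, 0), 1), "weights are zero")
})

test_that("with r = 1 and full weights the loss reduces to standard mean BCE", {
  set.seed(4)
  p <- rnorm(50, sd = 3)
  y <- rbinom(50, 1, 0.5)
  ours <- wmbceLoss(p, y, rep(1, 50), 1)
  sig <- 1 / (1 + exp(-p))
  reference <- -mean(y * log(sig) + (1 - y) * log(1 - sig))
  expect_lt(abs(ours - reference), 1e-10)
})

test_that("zero-weight nodes contribute nothing to the loss or any gradient", {
  set.seed(6)
  n <- 30
  p <- rnorm(n)
  y <- rbinom(n, 1, 0.4)
  w <- rbinom(n, 1, 0.5)
  if (sum(w * y) == 0 || sum(w * (1 - y)) == 0) w[1:2] <- 1
  base <- GraphMaskAE:::.wmbceLossGrad(p, y, w, 2)
  yFlip <- y
  yFlip[w == 0] <- 1 - yFlip[w == 0] # perturb every unweighted label
  flip <- GraphMaskAE:::.wmbceLossGrad(p, yFlip, w, 2)
  expect_identical(base$loss, flip$loss)
  expect_identical(base$grad, flip$grad)
  expect_true(all(base$grad[w == 0] == 0))
})

test_that("the wmBCE gradient is exact against finite differences", {
  set.seed(7)
  p <- rnorm(12)
  y <- rbinom(12, 1, 0.5)
  w <- c(rep(1, 8), rep(0, 4))
  lg <- GraphMaskAE:::.wmbceLossGrad(p, y, w, 3)
  for (k in 1:12) {
    p2 <- p
    p2[k] <- p[k] + 1e-6
    p3 <- p
    p3[k] <- p[k] - 1e-6
    fd <- (wmbceLoss(p2, y, w, 3) - wmbceLoss(p3, y, w, 3)) / 2e-6
    expect_lt(abs(fd - lg$grad[k]), 1e-6)
  }
})

test_that("fine-tuning splits the training pool 4:1 and is deterministic", {
  cfg <- syntheticConfig(
    nNodes = 300, nFeatures = 8, effectSize = 2,
    homophilyRounds = 1, labelFraction = 0.5,
    posFraction = 0.25, seed = 19
  )
  sim <- generateFeaturedGraph(cfg)
  enc <- suppressMessages(gnnStack("gcn", inputDim = 8, hiddenDim = 16, nHidden = 2, seed = 1))
  ftCfg <- fineTuneConfig(epochs = 8, earlyStopPatience = 8, seed = 2)
  ft <- finetuneNode(sim$graph, sim$labels, enc, ftCfg)
  pool <- sum(ft$trainMask) + sum(ft$valMask)
  expect_equal(sum(ft$valMask), round(pool / 5))
  # no unlabelled node in any loss mask
  roles <- nodeRoles(sim$labels)
  expect_true(all(roles[ft$trainMask | ft$valMask] %in% c("positive", "negative")))
  ft2 <- finetuneNode(sim$graph, sim$labels, enc, ftCfg)
  expect_identical(ft$scores, ft2$scores)

  empty <- LabelAssignment(rep("unlabelled_intermediate", 300))
  expect_error(finetuneNode(sim$graph, empty, enc, ftCfg), "mask")
})

test_that("cross-validation folds partition the labelled nodes and report order statistics", {
  cfg <- syntheticConfig(
    nNodes = 250, nFeatures = 8, effectSize = 2,
    homophilyRounds = 1, labelFraction = 0.4,
    posFraction = 0.25, seed = 23
  )
  sim <- generateFeaturedGraph(cfg)
  roles <- nodeRoles(sim$labels)
  y <- ifelse(roles == "positive", 1, ifelse(roles == "negative", 0, NA))
  labIdx <- which(!is.na(y))
  fold <- GraphMaskAE:::.stratifiedFolds(labIdx, y, 5L, seed = 3)
  expect_setequal(which(fold > 0), labIdx)
  expect_equal(sort(unique(fold[labIdx])), 1:5)
  perFold <- table(fold[labIdx])
  expect_equal(sum(perFold), 100)
  expect_true(all(perFold == 20)) # 100 labelled, 5 folds
  expect_error(
    GraphMaskAE:::.stratifiedFolds(labIdx[1:6], y, 5L, seed = 3),
    "fewer than"
  )

  enc <- suppressMessages(gnnStack("gcn", inputDim = 8, hiddenDim = 16, nHidden = 2, seed = 1))
  rep <- crossValidate(sim$graph, sim$labels, enc,
    fineTuneConfig(epochs = 10, earlyStopPatience = 10, seed = 5),
    nFolds = 3
  )
  s <- foldSummary(rep)
  expect_true(s[["min"]] <= s[["median"]] && s[["median"]] <= s[["max"]])
  expect_length(foldMetrics(rep), 3L)
  expect_length(prCurves(rep), 3L)
})

test_that("transfer arms coincide when source equals target", {
  cfg <- syntheticConfig(
    nNodes = 250, nFeatures = 8, effectSize = 2,
    homophilyRounds = 1, labelFraction = 0.4,
    posFraction = 0.3, seed = 29
  )
  sim <- generateFeaturedGraph(cfg)
  enc <- suppressMessages(gnnStack("gcn", inputDim = 8, hiddenDim = 16, nHidden = 2, seed = 1))
  res <- transferEvaluate(sim$graph, sim$labels, sim$labels, enc,
    config = fineTuneConfig(epochs = 10, earlyStopPatience = 10, seed = 7)
  )
  expect_equal(res[["with_transfer"]], res[["without_transfer"]])
})

test_that("graph-level classification separates large effects and not null ones", {
  encG <- suppressMessages(gnnStack("gin", inputDim = 12, hiddenDim = 16, nHidden = 3, seed = 3))
  gs <- generateGraphSet(24, 25, 2, effectSize = 3, seed = 11, nFeatures = 12)
  res <- graphClassify(gs, encG, seed = 13)
  expect_equal(res$auprc, 1.0)
  expect_setequal(res$predictions$split, c("train", "test"))

  gs0 <- generateGraphSet(40, 25, 2, effectSize = 0, seed = 17, nFeatures = 12)
  res0 <- graphClassify(gs0, encG, seed = 13)
  expect_lt(abs(res0$auprc - 0.5), 0.35) # near prevalence on a null set

  # per-graph readout vectors do not depend on the other graphs in the set
  sub <- list(graphs = gs$graphs[1:4], classLabels = gs$classLabels[1:4])
  v1 <- readoutMean(stackForward(gs$graphs[[2]], encG))
  v2 <- readoutMean(stackForward(sub$graphs[[2]], encG))
  expect_identical(v1, v2)
})
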