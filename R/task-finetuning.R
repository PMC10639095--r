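# Task-specific fine-tuning: transductive node classification with the
# weighted masked binary cross-entropy (all nodes pass messages, only
# training nodes enter the loss, positives upweighted by the
# negatives-per-positive ratio r), stratified cross-validation with an inner
# 4:1 train/validation split and early stopping on validation AUPRC, a
# transfer protocol across label sets, and graph-level classification via
# concatenated mean readout plus a linear SVM.

#' Fine-tuning configuration
#'
#' @param epochs maximum optimization epochs (default 200).
#' @param learningRate Adam learning rate (default 0.01).
#' @param weightDecay L2 weight decay (default 0.001).
#' @param trainValRatio train:validation split of the training pool
#'   (default 4, i.e. 4:1).
#' @param earlyStopPatience epochs without validation AUPRC improvement
#'   before stopping (default 40; fine-tuning from an aggressively
#'   pretrained encoder shows a warm-up plateau that a short patience would
#'   mistake for convergence).
#' @param seed integer seed (head initialization and splits).
#' @param freezeEncoder keep the encoder fixed and train only the head
#'   (default `FALSE`: both are optimized).
#' @return list of class `FineTuneConfig`.
#' @export
fineTuneConfig <- function(epochs = 200L, learningRate = 0.01,
                           weightDecay = 0.001, trainValRatio = 4,
                           earlyStopPatience = 40L, seed = 1L,
                           freezeEncoder = FALSE) {
  if (epochs < 1L) .stopf("epochs must be positive")
  if (earlyStopPatience > epochs) .stopf("patience cannot exceed epochs")
  structure(
    list(
      epochs = as.integer(epochs), learningRate = learningRate,
      weightDecay = weightDecay, trainValRatio = trainValRatio,
      earlyStopPatience = as.integer(earlyStopPatience),
      seed = as.integer(seed), freezeEncoder = isTRUE(freezeEncoder)
    ),
    class = "FineTuneConfig"
  )
}

#' Weighted masked binary cross-entropy
#'
#' Mean over nodes with weight 1 of
#' `-(r * y * log(sigmoid(p)) + (1 - y) * log(1 - sigmoid(p)))`. Nodes with
#' weight 0 (validation, test, unlabelled intermediates) contribute nothing
#' to the value or to any gradient; `r` multiplies only the positive term,
#' counteracting class imbalance. With `r = 1` and all weights 1 this is the
#' standard mean binary cross-entropy on logits.
#'
#' @param logits per-node raw logits.
#' @param labels per-node 0/1 labels (ignored where `weights == 0`).
#' @param weights per-node 0/1 loss mask.
#' @param r positive-class weight (negatives per positive), `> 0`.
#' @return scalar loss.
#' @examples
#' wmbceLoss(0, 1, 1, 1) # log(2)
#' @export
wmbceLoss <- function(logits, labels, weights, r) {
  .wmbceLossGrad(logits, labels, weights, r, wantGrad = FALSE)$loss
}

.wmbceLossGrad <- function(logits, labels, weights, r, wantGrad = TRUE) {
  if (r <= 0) .stopf("r must be positive")
  w <- as.numeric(weights)
  if (!any(w == 1)) .stopf("all loss weights are zero; mean undefined")
  idx <- which(w == 1)
  p <- as.numeric(logits)[idx]
  y <- as.numeric(labels)[idx]
  perNode <- -(r * y * .logSigmoid(p) + (1 - y) * .log1mSigmoid(p))
  loss <- mean(perNode)
  if (!wantGrad) {
    return(list(loss = loss))
  }
  sig <- .sigmoid(p)
  g <- numeric(length(w))
  g[idx] <- ((1 - y) * sig - r * y * (1 - sig)) / length(idx)
  list(loss = loss, grad = g)
}

# stratified assignment of a subset into train/validation at ratio:1,
# validation size = roundHalfUp(pool / (ratio + 1)), allocated per class by
# largest remainder
.splitTrainVal <- function(poolIdx, y, ratio, seed) {
  nVal <- .roundHalfUp(length(poolIdx) / (ratio + 1))
  classes <- split(poolIdx, y[poolIdx])
  quota <- vapply(classes, function(ix) length(ix) * nVal / length(poolIdx), numeric(1))
  base <- floor(quota)
  rem <- nVal - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  valIdx <- .withSeed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      ix <- classes[[i]]
      if (base[i] == 0) integer(0) else sample(ix, min(base[i], length(ix)))
    }), use.names = FALSE)
  })
  list(train = setdiff(poolIdx, valIdx), val = valIdx)
}

# stratified fold ids over labelled indices (round-robin after shuffling)
.stratifiedFolds <- function(labIdx, y, nFolds, seed) {
  fold <- integer(length(y))
  .withSeed(seed, {
    for (cls in unique(y[labIdx])) {
      ix <- labIdx[y[labIdx] == cls]
      if (length(ix) < nFolds) {
        .stopf("class %s has %d members, fewer than %d folds", cls, length(ix), nFolds)
      }
      fold[sample(ix)] <- rep_len(seq_len(nFolds), length(ix))
    }
  })
  fold
}

#' Fine-tune the encoder for transductive node classification
#'
#' Trains the encoder (unless frozen) plus a single linear head with the
#' weighted masked binary cross-entropy. All nodes, labelled or not,
#' participate in message passing; only training-mask nodes enter the loss.
#' When the assignment carries no explicit train/validation masks, the
#' labelled nodes outside the test mask are split `trainValRatio`:1
#' (stratified, seeded). Validation AUPRC is monitored each epoch and the
#' best-validation checkpoint is returned (early stopping on patience).
#'
#' @param graph a [FeaturedGraph-class].
#' @param labels a [LabelAssignment-class]; nodes in its test mask are never
#'   trained on.
#' @param encoder a [GnnStack-class], typically pretrained.
#' @param config a [fineTuneConfig()].
#' @return list with `classifier` ([NodeClassifier-class]), `scores`
#'   (sigmoid probabilities for every node, named by gene), `valTrace`
#'   (per-epoch validation AUPRC, `NA` when unmonitored), `bestEpoch`,
#'   `trainMask`, `valMask` and the ratio `r` used.
#' @export
finetuneNode <- function(graph, labels, encoder, config = fineTuneConfig()) {
  roles <- nodeRoles(labels)
  n <- numNodes(graph)
  y <- ifelse(roles == "positive", 1, ifelse(roles == "negative", 0, NA))
  labelled <- !is.na(y)
  trainIdx <- which(trainMask(labels))
  valIdx <- which(valMask(labels))
  if (!length(trainIdx)) {
    pool <- which(labelled & !testMask(labels))
    if (!length(pool)) .stopf("empty training mask: no labelled nodes outside the test split")
    sp <- .splitTrainVal(pool, y, config$trainValRatio, config$seed)
    trainIdx <- sp$train
    valIdx <- sp$val
  }
  if (!length(trainIdx)) .stopf("empty training mask")
  w <- numeric(n)
  w[trainIdx] <- 1
  nPos <- sum(y[trainIdx] == 1)
  nNeg <- sum(y[trainIdx] == 0)
  if (nPos == 0L) .stopf("training mask contains no positives")
  r <- max(nNeg, 1) / nPos
  X <- nodeFeatures(graph)
  edges <- edgeMatrix(graph)
  hid <- encoder@outputDim
  head <- .withSeed(config$seed + 1L, {
    lim <- sqrt(6 / (hid + 1))
    list(W = stats::runif(hid, -lim, lim), b = 0)
  })
  params <- list(encoder = encoder@layers, headW = head$W, headB = head$b)
  state <- .adamInit(params)
  monitor <- length(valIdx) > 0 && length(unique(y[valIdx])) == 2L
  best <- list(params = params, metric = -Inf, epoch = 0L)
  sinceBest <- 0L
  valTrace <- rep(NA_real_, config$epochs)
  lastEpoch <- config$epochs
  for (epoch in seq_len(config$epochs)) {
    enc <- .setStackParams(encoder, params$encoder)
    fw <- .stackForwardCache(X, edges, enc)
    H <- fw$embeddings[[enc@nHidden]]
    logits <- as.numeric(H %*% params$headW + params$headB)
    lg <- .wmbceLossGrad(logits, ifelse(is.na(y), 0, y), w, r)
    if (!is.finite(lg$loss)) .stopf("fine-tuning diverged at epoch %d", epoch)
    dlog <- lg$grad
    gHeadW <- as.numeric(crossprod(H, dlog))
    gHeadB <- sum(dlog)
    gEnc <- if (config$freezeEncoder) {
      .zerosLike(params$encoder)
    } else {
      dH <- outer(dlog, params$headW)
      .stackBackward(fw, edges, enc, dH)$grads
    }
    upd <- .adamStep(
      params, list(encoder = gEnc, headW = gHeadW, headB = gHeadB),
      state, config$learningRate, config$weightDecay
    )
    params <- upd$params
    state <- upd$state
    if (monitor) {
      encNew <- .setStackParams(encoder, params$encoder)
      Hnew <- .stackForwardCache(X, edges, encNew)$embeddings[[encNew@nHidden]]
      logitsNew <- as.numeric(Hnew %*% params$headW + params$headB)
      m <- auprc(logitsNew[valIdx], y[valIdx])
      valTrace[epoch] <- m
      if (m > best$metric + 1e-12) {
        best <- list(params = params, metric = m, epoch = epoch)
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$earlyStopPatience) {
          lastEpoch <- epoch
          break
        }
      }
    } else {
      best <- list(params = params, metric = NA_real_, epoch = epoch)
    }
  }
  finalParams <- best$params
  encFinal <- .setStackParams(encoder, finalParams$encoder)
  Hf <- .stackForwardCache(X, edges, encFinal)$embeddings[[encFinal@nHidden]]
  scores <- .sigmoid(as.numeric(Hf %*% finalParams$headW + finalParams$headB))
  names(scores) <- nodeIds(graph)
  trainM <- logical(n)
  trainM[trainIdx] <- TRUE
  valM <- logical(n)
  valM[valIdx] <- TRUE
  list(
    classifier = new("NodeClassifier",
      encoder = encFinal,
      headW = finalParams$headW, headB = finalParams$headB
    ),
    scores = scores, valTrace = valTrace[seq_len(lastEpoch)],
    bestEpoch = best$epoch, trainMask = trainM, valMask = valM, r = r
  )
}

#' Sigmoid confidence scores for all nodes
#'
#' Applies the fine-tuned encoder and head to a graph and returns sigmoid
#' probabilities for every node, including unlabelled and unknown genes —
#' the scores used to rank candidate genes.
#'
#' @param classifier a [NodeClassifier-class].
#' @param graph a [FeaturedGraph-class].
#' @return named numeric vector of per-node scores in \[0, 1\].
#' @export
scoreNodes <- function(classifier, graph) {
  emb <- stackForward(graph, classifier@encoder)
  H <- emb[[length(emb)]]
  scores <- .sigmoid(as.numeric(H %*% classifier@headW + classifier@headB))
  names(scores) <- nodeIds(graph)
  scores
}

#' Stratified k-fold cross-validation of node classification
#'
#' Splits the labelled nodes into stratified folds; each fold in turn is
#' held out as the test set while the rest is re-split 4:1 into train and
#' validation for fine-tuning (each fold restarts from the supplied, e.g.
#' pretrained, encoder). Reports per-fold test AUPRC with the min/median/max
#' summary and per-fold PR curves.
#'
#' @param graph a [FeaturedGraph-class].
#' @param labels a [LabelAssignment-class] (roles only; masks are rebuilt
#'   per fold).
#' @param encoder starting [GnnStack-class].
#' @param config a [fineTuneConfig()].
#' @param nFolds number of folds (default 5).
#' @return a [FoldReport-class].
#' @export
crossValidate <- function(graph, labels, encoder, config = fineTuneConfig(),
                          nFolds = 5L) {
  roles <- nodeRoles(labels)
  y <- ifelse(roles == "positive", 1, ifelse(roles == "negative", 0, NA))
  labIdx <- which(!is.na(y))
  fold <- .stratifiedFolds(labIdx, y, nFolds, config$seed)
  metrics <- numeric(nFolds)
  curves <- vector("list", nFolds)
  for (k in seq_len(nFolds)) {
    testIdx <- which(fold == k)
    testM <- logical(length(y))
    testM[testIdx] <- TRUE
    labK <- LabelAssignment(roles, testMask = testM)
    cfgK <- config
    cfgK$seed <- config$seed + 101L * k
    ft <- finetuneNode(graph, labK, encoder, cfgK)
    metrics[k] <- auprc(ft$scores[testIdx], y[testIdx])
    curves[[k]] <- prCurve(ft$scores[testIdx], y[testIdx])
  }
  FoldReport(
    foldMetrics = metrics, prCurves = curves,
    runConfig = list(nFolds = nFolds, fineTune = unclass(config))
  )
}

#' Transfer evaluation across label sets
#'
#' Measures how much fine-tuning on the target task's own labels matters
#' versus fine-tuning on a different (source) label set, on an identical
#' held-out target test split. A fifth of the target's labelled nodes is
#' held out; the with-transfer arm fine-tunes on the remaining target
#' labels, the without-transfer arm on the source labels with any held-out
#' node demoted to unlabelled so no test node is ever trained on.
#'
#' @param graph a [FeaturedGraph-class].
#' @param labelsSource,labelsTarget [LabelAssignment-class] objects on the
#'   same graph.
#' @param encoder starting [GnnStack-class].
#' @param config a [fineTuneConfig()].
#' @return named numeric `c(with_transfer =, without_transfer =)` test
#'   AUPRCs.
#' @export
transferEvaluate <- function(graph, labelsSource, labelsTarget, encoder,
                             config = fineTuneConfig()) {
  n <- numNodes(graph)
  if (length(nodeRoles(labelsSource)) != n || length(nodeRoles(labelsTarget)) != n) {
    .stopf("both label sets must cover the graph's nodes")
  }
  rolesT <- nodeRoles(labelsTarget)
  yT <- ifelse(rolesT == "positive", 1, ifelse(rolesT == "negative", 0, NA))
  labT <- which(!is.na(yT))
  fold <- .stratifiedFolds(labT, yT, 5L, config$seed)
  testIdx <- which(fold == 1L)
  testM <- logical(n)
  testM[testIdx] <- TRUE

  cfgA <- config
  cfgA$seed <- config$seed + 1L
  armA <- finetuneNode(graph, LabelAssignment(rolesT, testMask = testM), encoder, cfgA)

  rolesS <- nodeRoles(labelsSource)
  rolesS[testIdx] <- "unlabelled_intermediate" # never train on a test node
  cfgB <- config
  cfgB$seed <- config$seed + 1L
  armB <- finetuneNode(graph, LabelAssignment(rolesS), encoder, cfgB)
  if (any((armA$trainMask | armA$valMask | armB$trainMask | armB$valMask)[testIdx])) {
    .stopf("leakage: a test node appeared in a training or validation mask")
  }
  c(
    with_transfer = auprc(armA$scores[testIdx], yT[testIdx]),
    without_transfer = auprc(armB$scores[testIdx], yT[testIdx])
  )
}

#' Graph-level classification via readout and a linear SVM
#'
#' Embeds each graph with the (GIN) encoder, pools node embeddings by the
#' concatenated per-layer mean readout, fits a linear support vector machine
#' on a stratified training split of the graph-level vectors, and scores the
#' held-out graphs. Decision values are mapped to \[0, 1\] with the sigmoid
#' for AUPRC.
#'
#' @param graphSet list with `graphs` (list of [FeaturedGraph-class]) and
#'   `classLabels` (0/1 integer vector), as from [generateGraphSet()].
#' @param encoder a [GnnStack-class] whose input width matches the graphs'
#'   feature width.
#' @param svmC SVM regularization constant (default 1).
#' @param trainFraction fraction of graphs used for training (default 0.7,
#'   stratified).
#' @param seed integer seed for the split.
#' @return list with `auprc` (test AUPRC), `predictions` (data frame with
#'   per-graph label, score and split) and `model` (the fitted SVM).
#' @export
graphClassify <- function(graphSet, encoder, svmC = 1, trainFraction = 0.7,
                          seed = 1L) {
  labels <- graphSet$classLabels
  if (length(unique(labels)) != 2L || !all(labels %in% c(0L, 1L))) {
    .stopf("graph classification requires two classes labelled 0/1")
  }
  outLen <- (encoder@nHidden - 1L) * encoder@hiddenDim + encoder@outputDim
  feats <- t(vapply(
    graphSet$graphs,
    function(g) readoutMean(stackForward(g, encoder)),
    numeric(outLen)
  ))
  nG <- length(labels)
  trainIdx <- .withSeed(seed, {
    unlist(lapply(c(0L, 1L), function(cls) {
      ix <- which(labels == cls)
      sample(ix, max(1L, .roundHalfUp(trainFraction * length(ix))))
    }), use.names = FALSE)
  })
  testIdx <- setdiff(seq_len(nG), trainIdx)
  if (length(unique(labels[trainIdx])) < 2L) {
    .stopf("training split contains a single class")
  }
  yf <- factor(labels, levels = c(0L, 1L))
  fit <- e1071::svm(
    x = feats[trainIdx, , drop = FALSE], y = yf[trainIdx],
    kernel = "linear", cost = svmC, scale = FALSE
  )
  dvm <- attr(
    stats::predict(fit, feats, decision.values = TRUE),
    "decision.values"
  )
  dvAll <- dvm[, 1L]
  # orient decision values so larger means class 1
  firstClass <- strsplit(colnames(dvm)[1L], "/")[[1L]][1L]
  if (firstClass == "0") dvAll <- -dvAll
  score <- .sigmoid(dvAll)
  predictions <- data.frame(
    graph = seq_len(nG), label = labels, score = score,
    predicted = as.integer(score > 0.5),
    split = ifelse(seq_len(nG) %in% trainIdx, "train", "test")
  )
  list(
    auprc = auprc(score[testIdx], labels[testIdx]),
    predictions = predictions, model = fit
  )
}
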