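# The pretext task: mask node features (topology untouched), reconstruct
# them with an encoder/decoder pair, and minimize the scaled cosine error.

#' Masking specification
#'
#' @param maskRatio fraction of nodes to mask (default 0.5, i.e. half the
#'   nodes are replaced by the mask token each epoch).
#' @param maskedIndices optional fixed set of node indices to mask; when
#'   `NULL`, indices are sampled uniformly without replacement.
#' @param token optional numeric mask token (feature width); defaults to the
#'   zero vector, which carries no semantic content.
#' @param learnable should the token be updated during pretraining (default
#'   `TRUE`; set `FALSE` for a fixed zero token).
#' @return a list of class `MaskSpec`.
#' @export
maskSpec <- function(maskRatio = 0.5, maskedIndices = NULL, token = NULL,
                     learnable = TRUE) {
  if (maskRatio < 0 || maskRatio > 1) .stopf("maskRatio must lie in [0, 1]")
  structure(
    list(
      maskRatio = maskRatio, maskedIndices = maskedIndices,
      token = token, learnable = isTRUE(learnable)
    ),
    class = "MaskSpec"
  )
}

#' Apply a feature mask to a graph
#'
#' Replaces the feature rows of `round(maskRatio * nNodes)` nodes (sampled
#' uniformly without replacement under `seed`, unless fixed indices are
#' given) with the mask token. Edges are never touched: masking hides what a
#' node looks like, not whom it interacts with.
#'
#' @param graph a [FeaturedGraph-class].
#' @param spec a [maskSpec()].
#' @param seed integer seed for index sampling (ignored when
#'   `spec$maskedIndices` is given).
#' @return a [MaskedGraph-class].
#' @examples
#' sim <- generateFeaturedGraph(syntheticConfig(nNodes = 20, seed = 1))
#' mg <- applyMask(sim$graph, maskSpec(0.5), seed = 7)
#' length(maskedIndices(mg))
#' @export
applyMask <- function(graph, spec = maskSpec(), seed = 1L) {
  n <- numNodes(graph)
  d <- ncol(nodeFeatures(graph))
  token <- spec$token
  if (is.null(token)) token <- numeric(d)
  if (length(token) != d) .stopf("mask token length must equal feature width")
  idx <- spec$maskedIndices
  if (is.null(idx)) {
    k <- .roundHalfUp(spec$maskRatio * n)
    idx <- .withSeed(seed, sample.int(n, k))
  }
  idx <- as.integer(idx)
  X <- nodeFeatures(graph)
  if (length(idx)) X[idx, ] <- rep(token, each = length(idx))
  masked <- FeaturedGraph(
    nodeIds = nodeIds(graph), edges = edgeMatrix(graph),
    features = X, featureNames = featureNames(graph)
  )
  new("MaskedGraph", graph = masked, maskedIndices = sort(idx), token = as.numeric(token))
}

#' Scaled cosine error reconstruction loss
#'
#' Mean over the scope of `(1 - cos(f_i, v_i))^gamma`, where `f_i` is the
#' reconstructed and `v_i` the original feature row of node `i`. With
#' `gamma = 1` and the scope equal to all nodes this is the plain average of
#' one-minus-cosine over the graph. The cosine is undefined for zero-norm
#' rows, which raise an error naming the node.
#'
#' @param reconstructed,original numeric matrices of matching shape.
#' @param scopeIndices node indices over which to average (`NULL` for all
#'   nodes).
#' @param gamma exponent `>= 1` (default 1).
#' @return non-negative scalar, at most `2^gamma`.
#' @examples
#' X <- matrix(rnorm(20), 5)
#' sceLoss(X, X) # identical -> 0
#' sceLoss(-X, X) # antipodal -> 2
#' @export
sceLoss <- function(reconstructed, original, scopeIndices = NULL, gamma = 1) {
  .sceLossGrad(reconstructed, original, scopeIndices, gamma,
    wantGrad = FALSE
  )$loss
}

.sceLossGrad <- function(reconstructed, original, scopeIndices = NULL,
                         gamma = 1, wantGrad = TRUE) {
  if (!all(dim(reconstructed) == dim(original))) {
    .stopf("reconstructed and original shapes differ")
  }
  if (gamma < 1) .stopf("gamma must be at least 1")
  scope <- if (is.null(scopeIndices)) seq_len(nrow(original)) else as.integer(scopeIndices)
  if (!length(scope)) .stopf("empty loss scope")
  Fm <- reconstructed[scope, , drop = FALSE]
  Vm <- original[scope, , drop = FALSE]
  nf <- sqrt(rowSums(Fm * Fm))
  nv <- sqrt(rowSums(Vm * Vm))
  bad <- which(nf == 0 | nv == 0)
  if (length(bad)) {
    .stopf("zero-norm feature row at node %d: cosine undefined", scope[bad[1L]])
  }
  dot <- rowSums(Fm * Vm)
  cosv <- dot / (nf * nv)
  one_m <- 1 - cosv
  loss <- mean(one_m^gamma)
  if (!wantGrad) {
    return(list(loss = loss))
  }
  # d cos/df = v/(|f||v|) - cos * f/|f|^2 ; dL/df = -gamma (1-cos)^(g-1) dcos/df / m
  coef <- gamma * one_m^(gamma - 1) / length(scope)
  dcos <- Vm / (nf * nv) - (cosv / (nf * nf)) * Fm
  G <- matrix(0, nrow(reconstructed), ncol(reconstructed))
  G[scope, ] <- -coef * dcos
  list(loss = loss, grad = G)
}

#' Pretraining configuration
#'
#' @param epochs optimization epochs (default 300).
#' @param learningRate Adam learning rate (default 0.1).
#' @param weightDecay L2 weight decay (default 0).
#' @param seed integer seed controlling mask resampling.
#' @param lossScope `"all_nodes"` (average the reconstruction error over the
#'   whole graph, the default) or `"masked_only"` (restrict it to masked
#'   nodes).
#' @param sceGamma scaled cosine error exponent (default 1).
#' @param freshMaskEachEpoch resample the masked set every epoch (default
#'   `TRUE`); `FALSE` fixes one mask for debugging.
#' @return a list of class `PretrainConfig`.
#' @export
pretrainConfig <- function(epochs = 300L, learningRate = 0.1,
                           weightDecay = 0, seed = 1L,
                           lossScope = c("all_nodes", "masked_only"),
                           sceGamma = 1, freshMaskEachEpoch = TRUE) {
  if (epochs < 0L) .stopf("epochs must be non-negative")
  if (learningRate <= 0) .stopf("learningRate must be positive")
  structure(
    list(
      epochs = as.integer(epochs), learningRate = learningRate,
      weightDecay = weightDecay, seed = as.integer(seed),
      lossScope = match.arg(lossScope), sceGamma = sceGamma,
      freshMaskEachEpoch = isTRUE(freshMaskEachEpoch)
    ),
    class = "PretrainConfig"
  )
}

#' Self-supervised masked-reconstruction pretraining
#'
#' Each epoch: sample a fresh masked node set, replace those feature rows
#' with the mask token, encode the masked graph, decode back to feature
#' space, compute the scaled cosine error against the original features, and
#' take one Adam step on the encoder, decoder and (when learnable) token.
#' No labels are used anywhere.
#'
#' @param graph a [FeaturedGraph-class]; feature rows must have non-zero
#'   norm (cosine reconstruction target).
#' @param encoder [GnnStack-class] with `inputDim` equal to the feature
#'   width.
#' @param decoder [GnnStack-class] mapping the encoder width back to the
#'   feature width (typically `finalLinear = TRUE`).
#' @param spec a [maskSpec()].
#' @param config a [pretrainConfig()].
#' @return list with `encoder` and `decoder` (trained stacks), `token` (the
#'   final mask token) and `lossTrace` (per-epoch loss).
#' @export
pretrain <- function(graph, encoder, decoder, spec = maskSpec(),
                     config = pretrainConfig()) {
  X <- nodeFeatures(graph)
  d <- ncol(X)
  if (encoder@inputDim != d) .stopf("encoder input width must equal feature width")
  if (decoder@outputDim != d) .stopf("decoder output width must equal feature width")
  if (decoder@inputDim != encoder@outputDim) {
    .stopf("decoder input width must equal encoder output width")
  }
  if (any(sqrt(rowSums(X * X)) == 0)) {
    .stopf("graph has zero-norm feature rows; cosine reconstruction undefined")
  }
  edges <- edgeMatrix(graph)
  n <- nrow(X)
  token <- spec$token
  if (is.null(token)) token <- numeric(d)
  params <- list(encoder = encoder@layers, decoder = decoder@layers, token = token)
  state <- .adamInit(params)
  trace <- numeric(config$epochs)
  if (config$epochs == 0L) {
    return(list(encoder = encoder, decoder = decoder, token = token, lossTrace = trace))
  }
  k <- .roundHalfUp(spec$maskRatio * n)
  fixedIdx <- spec$maskedIndices
  .withSeed(config$seed, {
    maskIdx <- if (is.null(fixedIdx)) sample.int(n, k) else as.integer(fixedIdx)
    for (epoch in seq_len(config$epochs)) {
      if (is.null(fixedIdx) && config$freshMaskEachEpoch && epoch > 1L) {
        maskIdx <- sample.int(n, k)
      }
      Xm <- X
      if (length(maskIdx)) {
        Xm[maskIdx, ] <- rep(params$token, each = length(maskIdx))
      }
      enc <- .setStackParams(encoder, params$encoder)
      dec <- .setStackParams(decoder, params$decoder)
      encFw <- .stackForwardCache(Xm, edges, enc)
      H <- encFw$embeddings[[enc@nHidden]]
      decFw <- .stackForwardCache(H, edges, dec)
      R <- decFw$embeddings[[dec@nHidden]]
      scope <- if (config$lossScope == "masked_only") maskIdx else NULL
      lg <- .sceLossGrad(R, X, scope, config$sceGamma)
      if (!is.finite(lg$loss)) .stopf("training diverged at epoch %d", epoch)
      trace[epoch] <- lg$loss
      decBw <- .stackBackward(decFw, edges, dec, lg$grad)
      encBw <- .stackBackward(encFw, edges, enc, decBw$dX)
      dToken <- if (spec$learnable && length(maskIdx)) {
        colSums(encBw$dX[maskIdx, , drop = FALSE])
      } else {
        numeric(d)
      }
      grads <- list(encoder = encBw$grads, decoder = decBw$grads, token = dToken)
      upd <- .adamStep(params, grads, state, config$learningRate, config$weightDecay)
      params <- upd$params
      state <- upd$state
    }
  })
  list(
    encoder = .setStackParams(encoder, params$encoder),
    decoder = .setStackParams(decoder, params$decoder),
    token = params$token, lossTrace = trace
  )
}
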