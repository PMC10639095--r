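#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t crossprod
NULL

.ROLE_LEVELS <- c("positive", "negative", "unlabelled_intermediate", "unknown")

#' FeaturedGraph: an undirected graph with node-aligned features
#'
#' Container for a simple undirected graph (gene symbols as nodes) together
#' with a numeric node-feature matrix, one row per node in node order. This
#' is the central data object: a protein-protein interaction network whose
#' nodes carry multi-omic feature vectors.
#'
#' @slot nodeIds character vector of unique gene symbols; defines node order.
#' @slot edges integer matrix with two columns; each row is an unordered
#'   node-index pair stored with the smaller index first, no self loops, no
#'   duplicates.
#' @slot features numeric matrix, one row per node in `nodeIds` order.
#' @slot featureNames character vector naming the feature columns.
#'
#' @examples
#' g <- FeaturedGraph(
#'   nodeIds = c("TP53", "EGFR", "BRCA1"),
#'   edges = rbind(c(1L, 2L)),
#'   features = matrix(rnorm(6), nrow = 3),
#'   featureNames = c("mut", "expr")
#' )
#' numNodes(g)
#' @export
setClass("FeaturedGraph",
  representation(
    nodeIds = "character",
    edges = "matrix",
    features = "matrix",
    featureNames = "character"
  )
)

setValidity("FeaturedGraph", function(object) {
  msgs <- character()
  n <- length(object@nodeIds)
  if (anyDuplicated(object@nodeIds)) {
    msgs <- c(msgs, "nodeIds must be unique")
  }
  e <- object@edges
  if (ncol(e) != 2L) {
    msgs <- c(msgs, "edges must have exactly two columns")
  } else if (nrow(e) > 0L) {
    if (!is.numeric(e)) msgs <- c(msgs, "edges must be numeric indices")
    else {
      if (any(e < 1L) || any(e > n)) {
        msgs <- c(msgs, "edge endpoints must index nodes")
      }
      if (any(e[, 1L] == e[, 2L])) msgs <- c(msgs, "edges contain self pairs")
      if (any(e[, 1L] > e[, 2L])) {
        msgs <- c(msgs, "edges must be stored with smaller index first")
      }
      key <- paste(e[, 1L], e[, 2L])
      if (anyDuplicated(key)) msgs <- c(msgs, "edges contain duplicates")
    }
  }
  if (nrow(object@features) != n) {
    msgs <- c(msgs, "features must have one row per node")
  }
  if (ncol(object@features) != length(object@featureNames)) {
    msgs <- c(msgs, "featureNames length must equal feature column count")
  }
  if (length(object@features) && !all(is.finite(object@features))) {
    msgs <- c(msgs, "features contain missing or non-finite values")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname FeaturedGraph-class
#' @param nodeIds,edges,features,featureNames see slot documentation.
#' @return a validated `FeaturedGraph`.
#' @export
FeaturedGraph <- function(nodeIds, edges, features,
                          featureNames = colnames(features)) {
  if (is.null(featureNames)) {
    featureNames <- paste0("f", seq_len(ncol(features)))
  }
  edges <- .canonicalEdges(edges)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  rownames(features) <- nodeIds
  colnames(features) <- featureNames
  new("FeaturedGraph",
    nodeIds = as.character(nodeIds), edges = edges,
    features = features, featureNames = as.character(featureNames)
  )
}

# sort each pair, drop self loops and duplicates
.canonicalEdges <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  storage.mode(edges) <- "integer"
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  keep <- lo != hi
  lo <- lo[keep]
  hi <- hi[keep]
  key <- !duplicated(paste(lo, hi))
  m <- cbind(lo[key], hi[key])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' LabelAssignment: per-node roles and train/validation/test masks
#'
#' Partitions the nodes of a [FeaturedGraph] into positives, negatives and
#' unlabelled intermediates (nodes that pass messages but never enter a
#' loss), plus optional unknowns, and carries the boolean split masks used
#' during fine-tuning. The positive:negative imbalance ratio `posNegRatio`
#' (negatives per positive on the training mask) reweights the positive term
#' of the masked binary cross-entropy.
#'
#' @slot roles character vector, one of `"positive"`, `"negative"`,
#'   `"unlabelled_intermediate"`, `"unknown"` per node.
#' @slot trainMask,valMask,testMask disjoint logicals over nodes; `TRUE` only
#'   on labelled (positive/negative) nodes.
#' @slot posNegRatio numeric; negatives / positives among training nodes (or
#'   among all labelled nodes when no mask is set).
#' @export
setClass("LabelAssignment",
  representation(
    roles = "character",
    trainMask = "logical",
    valMask = "logical",
    testMask = "logical",
    posNegRatio = "numeric"
  )
)

setValidity("LabelAssignment", function(object) {
  msgs <- character()
  n <- length(object@roles)
  if (!all(object@roles %in% .ROLE_LEVELS)) {
    msgs <- c(msgs, "roles must be one of the four role levels")
  }
  if (length(object@trainMask) != n || length(object@valMask) != n ||
    length(object@testMask) != n) {
    msgs <- c(msgs, "split masks must have one entry per node")
  } else {
    if (any(object@trainMask & object@valMask) ||
      any(object@trainMask & object@testMask) ||
      any(object@valMask & object@testMask)) {
      msgs <- c(msgs, "split masks must be disjoint")
    }
    labelled <- object@roles %in% c("positive", "negative")
    anyMask <- object@trainMask | object@valMask | object@testMask
    if (any(anyMask & !labelled)) {
      msgs <- c(msgs, "split masks may only cover labelled nodes")
    }
  }
  # NA is allowed: the ratio is undefined until positives exist
  if (length(object@posNegRatio) != 1L) {
    msgs <- c(msgs, "posNegRatio must be a single number")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname LabelAssignment-class
#' @param roles,trainMask,valMask,testMask,posNegRatio see slots; masks
#'   default to all-`FALSE` and `posNegRatio` is recomputed from the training
#'   mask (falling back to all labelled nodes) when not supplied.
#' @export
LabelAssignment <- function(roles, trainMask = NULL, valMask = NULL,
                            testMask = NULL, posNegRatio = NULL) {
  n <- length(roles)
  if (is.null(trainMask)) trainMask <- rep(FALSE, n)
  if (is.null(valMask)) valMask <- rep(FALSE, n)
  if (is.null(testMask)) testMask <- rep(FALSE, n)
  if (is.null(posNegRatio)) {
    posNegRatio <- .posNegRatioFrom(roles, trainMask)
  }
  new("LabelAssignment",
    roles = as.character(roles), trainMask = trainMask, valMask = valMask,
    testMask = testMask, posNegRatio = as.numeric(posNegRatio)
  )
}

# negatives per positive on the given mask; falls back to all labelled nodes
.posNegRatioFrom <- function(roles, mask) {
  scope <- if (any(mask)) mask else roles %in% c("positive", "negative")
  nPos <- sum(roles == "positive" & scope)
  nNeg <- sum(roles == "negative" & scope)
  if (nPos == 0L) {
    return(NA_real_)
  }
  nNeg / nPos
}

#' MaskedGraph: a featured graph with masked node features
#'
#' A [FeaturedGraph] whose feature rows at `maskedIndices` have been replaced
#' by the mask token. Topology is untouched: masking hides what a node looks
#' like, never whom it talks to, so reconstruction must come from the
#' neighbourhood.
#'
#' @slot graph the masked `FeaturedGraph` (token already substituted).
#' @slot maskedIndices integer indices of masked nodes.
#' @slot token numeric mask token of feature width.
#' @export
setClass("MaskedGraph",
  representation(
    graph = "FeaturedGraph",
    maskedIndices = "integer",
    token = "numeric"
  )
)

setValidity("MaskedGraph", function(object) {
  msgs <- character()
  n <- length(object@graph@nodeIds)
  idx <- object@maskedIndices
  if (anyDuplicated(idx)) msgs <- c(msgs, "maskedIndices must be unique")
  if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
    msgs <- c(msgs, "maskedIndices out of range")
  }
  if (length(object@token) != ncol(object@graph@features)) {
    msgs <- c(msgs, "token length must equal feature width")
  }
  if (length(msgs)) msgs else TRUE
})

#' GnnStack: an ordered stack of message-passing layers
#'
#' Holds the parameters of a GCN or GIN stack: per-layer weights, fixed GIN
#' epsilon, layer-normalization scale/shift, and residual projection matrices
#' where consecutive widths differ. Built by [gnnStack()]; run with
#' [stackForward()].
#'
#' @slot layerKind `"gcn"` or `"gin"`.
#' @slot layers list of per-layer parameter lists.
#' @slot inputDim,hiddenDim,outputDim,nHidden architecture integers.
#' @slot useResidual,useLayernorm,finalLinear,symNorm wiring flags.
#' @export
setClass("GnnStack",
  representation(
    layerKind = "character",
    layers = "list",
    inputDim = "integer",
    hiddenDim = "integer",
    outputDim = "integer",
    nHidden = "integer",
    useResidual = "logical",
    useLayernorm = "logical",
    finalLinear = "logical",
    symNorm = "logical"
  )
)

setValidity("GnnStack", function(object) {
  msgs <- character()
  if (!object@layerKind %in% c("gcn", "gin")) {
    msgs <- c(msgs, "layerKind must be 'gcn' or 'gin'")
  }
  if (length(object@layers) != object@nHidden) {
    msgs <- c(msgs, "layers length must equal nHidden")
  }
  ok <- vapply(object@layers, function(l) {
    all(vapply(
      l[vapply(l, is.numeric, logical(1))],
      function(x) all(is.finite(x)), logical(1)
    ))
  }, logical(1))
  if (!all(ok)) msgs <- c(msgs, "layer parameters must be finite")
  if (length(msgs)) msgs else TRUE
})

#' NodeClassifier: fine-tuned encoder plus linear classification head
#'
#' The downstream node-classification model: a (typically pretrained) GCN
#' encoder and a single learnable linear layer mapping the final embedding to
#' a raw logit. Probabilities are obtained only through the sigmoid.
#'
#' @slot encoder the fine-tuned [GnnStack-class].
#' @slot headW numeric weight vector of length `hiddenDim`.
#' @slot headB numeric scalar bias.
#' @export
setClass("NodeClassifier",
  representation(encoder = "GnnStack", headW = "numeric", headB = "numeric")
)

#' FoldReport: cross-validation fold scores and summaries
#'
#' Per-fold area under the precision-recall curve with the min/median/max
#' summary used for benchmark reporting, plus per-fold PR curves and a frozen
#' snapshot of the run configuration.
#'
#' @slot foldMetrics numeric AUPRC per fold, each in \[0, 1\].
#' @slot summary named numeric `(min, median, max)` of `foldMetrics`.
#' @slot prCurves list of per-fold data frames with `recall`, `precision`.
#' @slot runConfig list snapshot of configs and seeds.
#' @export
setClass("FoldReport",
  representation(
    foldMetrics = "numeric",
    summary = "numeric",
    prCurves = "list",
    runConfig = "list"
  )
)

setValidity("FoldReport", function(object) {
  msgs <- character()
  fm <- object@foldMetrics
  if (any(fm < 0 | fm > 1)) msgs <- c(msgs, "AUPRC values must lie in [0,1]")
  if (length(fm)) {
    want <- c(min = min(fm), median = stats::median(fm), max = max(fm))
    if (length(object@summary) != 3L ||
      any(abs(object@summary - want) > 1e-12)) {
      msgs <- c(msgs, "summary inconsistent with foldMetrics")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname FoldReport-class
#' @param foldMetrics,prCurves,runConfig see slots.
#' @export
FoldReport <- function(foldMetrics, prCurves = list(), runConfig = list()) {
  new("FoldReport",
    foldMetrics = as.numeric(foldMetrics),
    summary = summarizeFolds(foldMetrics),
    prCurves = prCurves, runConfig = runConfig
  )
}
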