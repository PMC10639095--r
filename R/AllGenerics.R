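#' @describeIn FeaturedGraph-class node identifiers in node order.
#' @param x,object a `FeaturedGraph`.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @describeIn FeaturedGraph-class number of nodes.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @describeIn FeaturedGraph-class number of undirected edges.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @describeIn FeaturedGraph-class two-column integer edge matrix.
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @describeIn FeaturedGraph-class node-by-feature numeric matrix.
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @describeIn FeaturedGraph-class feature column names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @describeIn LabelAssignment-class per-node role vector.
#' @param x a `LabelAssignment`.
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @describeIn LabelAssignment-class training mask.
#' @export
setGeneric("trainMask", function(x) standardGeneric("trainMask"))

#' @describeIn LabelAssignment-class validation mask.
#' @export
setGeneric("valMask", function(x) standardGeneric("valMask"))

#' @describeIn LabelAssignment-class test mask.
#' @export
setGeneric("testMask", function(x) standardGeneric("testMask"))

#' @describeIn LabelAssignment-class negatives-per-positive ratio on the
#'   training mask.
#' @export
setGeneric("posNegRatio", function(x) standardGeneric("posNegRatio"))

#' @describeIn MaskedGraph-class indices of masked nodes.
#' @param x a `MaskedGraph`.
#' @export
setGeneric("maskedIndices", function(x) standardGeneric("maskedIndices"))

#' @describeIn FoldReport-class per-fold AUPRC vector.
#' @param x a `FoldReport`.
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @describeIn FoldReport-class named `(min, median, max)` summary.
#' @export
setGeneric("foldSummary", function(x) standardGeneric("foldSummary"))

#' @describeIn FoldReport-class list of per-fold PR curves.
#' @export
setGeneric("prCurves", function(x) standardGeneric("prCurves"))

#' @rdname FeaturedGraph-class
#' @export
setMethod("nodeIds", "FeaturedGraph", function(x) x@nodeIds)

#' @rdname FeaturedGraph-class
#' @export
setMethod("numNodes", "FeaturedGraph", function(x) length(x@nodeIds))

#' @rdname FeaturedGraph-class
#' @export
setMethod("numEdges", "FeaturedGraph", function(x) nrow(x@edges))

#' @rdname FeaturedGraph-class
#' @export
setMethod("edgeMatrix", "FeaturedGraph", function(x) x@edges)

#' @rdname FeaturedGraph-class
#' @export
setMethod("nodeFeatures", "FeaturedGraph", function(x) x@features)

#' @rdname FeaturedGraph-class
#' @export
setMethod("featureNames", "FeaturedGraph", function(x) x@featureNames)

#' @rdname FeaturedGraph-class
#' @export
setMethod("show", "FeaturedGraph", function(object) {
  cat(
    "FeaturedGraph with", length(object@nodeIds), "nodes,",
    nrow(object@edges), "edges,", ncol(object@features), "features\n"
  )
  if (length(object@nodeIds)) {
    head_ids <- utils::head(object@nodeIds, 4L)
    cat("  nodes:", paste(head_ids, collapse = ", "),
      if (length(object@nodeIds) > 4L) "..." else "", "\n"
    )
  }
  invisible(NULL)
})

#' @rdname LabelAssignment-class
#' @export
setMethod("nodeRoles", "LabelAssignment", function(x) x@roles)

#' @rdname LabelAssignment-class
#' @export
setMethod("trainMask", "LabelAssignment", function(x) x@trainMask)

#' @rdname LabelAssignment-class
#' @export
setMethod("valMask", "LabelAssignment", function(x) x@valMask)

#' @rdname LabelAssignment-class
#' @export
setMethod("testMask", "LabelAssignment", function(x) x@testMask)

#' @rdname LabelAssignment-class
#' @export
setMethod("posNegRatio", "LabelAssignment", function(x) x@posNegRatio)

#' @rdname LabelAssignment-class
#' @param object a `LabelAssignment`.
#' @export
setMethod("show", "LabelAssignment", function(object) {
  tab <- table(factor(object@roles, levels = .ROLE_LEVELS))
  cat("LabelAssignment over", length(object@roles), "nodes\n")
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(
    "  masks: train", sum(object@trainMask), "| val", sum(object@valMask),
    "| test", sum(object@testMask), "\n"
  )
  cat("  pos:neg ratio r =", format(object@posNegRatio, digits = 4), "\n")
  invisible(NULL)
})

#' @rdname MaskedGraph-class
#' @export
setMethod("maskedIndices", "MaskedGraph", function(x) x@maskedIndices)

#' @rdname MaskedGraph-class
#' @param object a `MaskedGraph`.
#' @export
setMethod("show", "MaskedGraph", function(object) {
  cat(
    "MaskedGraph:", length(object@maskedIndices), "of",
    length(object@graph@nodeIds), "nodes masked\n"
  )
  invisible(NULL)
})

#' @rdname GnnStack-class
#' @param object a `GnnStack`.
#' @export
setMethod("show", "GnnStack", function(object) {
  dims <- c(
    object@inputDim,
    rep(object@hiddenDim, max(object@nHidden - 1L, 0L)), object@outputDim
  )
  cat(
    toupper(object@layerKind), "stack:", object@nHidden, "layers,",
    paste(dims, collapse = " -> "), "\n"
  )
  cat(
    "  residual:", object@useResidual, "| layernorm:", object@useLayernorm,
    "| final linear:", object@finalLinear, "\n"
  )
  invisible(NULL)
})

#' @rdname FoldReport-class
#' @export
setMethod("foldMetrics", "FoldReport", function(x) x@foldMetrics)

#' @rdname FoldReport-class
#' @export
setMethod("foldSummary", "FoldReport", function(x) x@summary)

#' @rdname FoldReport-class
#' @export
setMethod("prCurves", "FoldReport", function(x) x@prCurves)

#' @rdname FoldReport-class
#' @param object a `FoldReport`.
#' @export
setMethod("show", "FoldReport", function(object) {
  cat("FoldReport over", length(object@foldMetrics), "folds\n")
  cat("  AUPRC:", paste(sprintf("%.4f", object@foldMetrics), collapse = ", "), "\n")
  s <- object@summary
  cat(sprintf(
    "  min/median/max: %.4f/%.4f/%.4f\n", s[["min"]], s[["median"]],
    s[["max"]]
  ))
  invisible(NULL)
})
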