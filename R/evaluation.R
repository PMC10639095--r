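# Precision-recall evaluation. AUPRC is the step-wise average precision:
# ties share a single threshold (group semantics), so the metric is
# invariant to permutations within tied scores, and the PR curve integrates
# exactly to the AUPRC.

.prPoints <- function(scores, labels) {
  if (length(scores) != length(labels)) .stopf("scores and labels must be aligned")
  if (!all(labels %in% c(0, 1))) .stopf("labels must be 0/1")
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) {
    .stopf("AUPRC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # last index of each tied-score group
  groupEnd <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[groupEnd]
  count <- groupEnd
  precision <- tp / count
  recall <- tp / nPos
  list(recall = recall, precision = precision, prevalence = nPos / length(y))
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: the sum over descending unique score
#' thresholds of `(R_k - R_{k-1}) * P_k`. Tied scores are grouped at one
#' threshold, so all-equal scores give exactly the positive prevalence.
#'
#' @param scores numeric prediction scores (higher means more positive).
#' @param labels 0/1 vector aligned to `scores`; both classes must occur.
#' @return AUPRC in \[0, 1\].
#' @examples
#' auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)) # 5/6
#' @export
auprc <- function(scores, labels) {
  p <- .prPoints(scores, labels)
  sum(diff(c(0, p$recall)) * p$precision)
}

#' Precision-recall curve points
#'
#' One point per unique score threshold (ties grouped), preceded by the
#' anchor `(0, precision at the top threshold)`. Recall is non-decreasing
#' and reaches 1 at the final point, whose precision is the positive
#' prevalence. Step-wise integration of these points reproduces [auprc()]
#' exactly.
#'
#' @inheritParams auprc
#' @return data frame with columns `recall` and `precision`.
#' @export
prCurve <- function(scores, labels) {
  p <- .prPoints(scores, labels)
  data.frame(
    recall = c(0, p$recall),
    precision = c(p$precision[1L], p$precision)
  )
}

#' Min/median/max fold summary
#'
#' The order statistics used for cross-validation benchmark reporting; the
#' median of an even fold count is the mean of the middle two values.
#'
#' @param foldMetrics numeric vector of per-fold scores (non-empty).
#' @return named numeric `(min, median, max)`.
#' @export
summarizeFolds <- function(foldMetrics) {
  if (!length(foldMetrics)) .stopf("no fold metrics to summarize")
  c(
    min = min(foldMetrics), median = stats::median(foldMetrics),
    max = max(foldMetrics)
  )
}

#' Write a fold report to JSON and PR points to CSV
#'
#' @param report a [FoldReport-class].
#' @param jsonPath output JSON path
#'   (`{"folds": [...], "summary": {...}, "runConfig": {...}}`).
#' @param prPath optional CSV path for the concatenated per-fold PR points
#'   (columns `fold`, `recall`, `precision`).
#' @return `jsonPath`, invisibly.
#' @export
writeFoldReport <- function(report, jsonPath, prPath = NULL) {
  s <- foldSummary(report)
  obj <- list(
    folds = foldMetrics(report),
    summary = list(min = unname(s[["min"]]), median = unname(s[["median"]]), max = unname(s[["max"]])),
    runConfig = report@runConfig
  )
  jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(prPath) && length(prCurves(report))) {
    pts <- do.call(rbind, lapply(seq_along(prCurves(report)), function(i) {
      cbind(fold = i, prCurves(report)[[i]])
    }))
    utils::write.csv(pts, prPath, row.names = FALSE)
  }
  invisible(jsonPath)
}
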