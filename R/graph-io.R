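# Tabular readers/writers and graph assembly.
#
# File formats (all plain TSV, '#' comment lines allowed):
#   edges:    gene_a <TAB> gene_b [<TAB> confidence]
#   features: header row of feature names, first column 'gene'
#   labels:   gene <TAB> label, label in {0,1}
#   scores:   gene <TAB> role <TAB> score <TAB> rank

.readTsvLines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineNumbers = which(keep))
}

#' Read a PPI edge list with optional confidence filtering
#'
#' Reads a two- or three-column TSV of gene-symbol pairs. When a confidence
#' threshold is given, only interactions with confidence strictly greater
#' than the threshold are kept (the convention used when pruning
#' low-confidence interactions from scored PPI databases such as CPDB at 0.5
#' or STRING at 0.85). Self interactions are dropped, and duplicate
#' unordered pairs are collapsed keeping the maximum confidence.
#'
#' @param path TSV file: `gene_a<TAB>gene_b[<TAB>confidence]`; `#` comments
#'   allowed.
#' @param minConfidence numeric threshold or `NULL` for no filtering. Rows
#'   with confidence `<= minConfidence` are removed.
#' @return data frame with columns `geneA`, `geneB`, `confidence`
#'   (`NA` when the file has no confidence column). Symbols are
#'   canonicalized to uppercase with whitespace stripped.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("TP53\tEGFR\t0.9", "EGFR\tTP53\t0.7", "MYC\tMYC\t0.8"), f)
#' readEdgeList(f, minConfidence = 0.5)
#' @export
readEdgeList <- function(path, minConfidence = NULL) {
  tsv <- .readTsvLines(path)
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    .stopf(
      "malformed edge row at line %d: expected 2-3 tab-separated fields, got %d",
      tsv$lineNumbers[bad[1L]], nf[bad[1L]]
    )
  }
  geneA <- .canonSymbol(vapply(fields, `[`, character(1), 1L))
  geneB <- .canonSymbol(vapply(fields, `[`, character(1), 2L))
  confidence <- rep(NA_real_, length(fields))
  hasConf <- nf == 3L
  if (any(hasConf)) {
    raw <- vapply(fields[hasConf], `[`, character(1), 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      first <- which(is.na(val))[1L]
      .stopf(
        "unparseable confidence at line %d: '%s'",
        tsv$lineNumbers[hasConf][first], raw[first]
      )
    }
    confidence[hasConf] <- val
  }
  if (!is.null(minConfidence)) {
    if (!any(hasConf)) {
      .stopf("minConfidence given but the file has no confidence column")
    }
    keep <- !is.na(confidence) & confidence > minConfidence
    geneA <- geneA[keep]
    geneB <- geneB[keep]
    confidence <- confidence[keep]
  }
  selfPair <- geneA == geneB
  if (any(selfPair)) {
    message(sprintf("readEdgeList: dropped %d self-interaction(s)", sum(selfPair)))
    geneA <- geneA[!selfPair]
    geneB <- geneB[!selfPair]
    confidence <- confidence[!selfPair]
  }
  lo <- pmin(geneA, geneB)
  hi <- pmax(geneA, geneB)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    # collapse duplicates keeping max confidence (NA treated as lowest)
    ord <- order(key, -ifelse(is.na(confidence), -Inf, confidence))
    lo <- lo[ord]
    hi <- hi[ord]
    confidence <- confidence[ord]
    keep <- !duplicated(key[ord])
    lo <- lo[keep]
    hi <- hi[keep]
    confidence <- confidence[keep]
  }
  data.frame(
    geneA = lo, geneB = hi, confidence = confidence,
    stringsAsFactors = FALSE
  )
}

#' Read a node feature matrix
#'
#' Reads a TSV whose first column holds gene symbols and whose header names
#' the feature columns (e.g. per-cancer-type mutation rate, copy-number,
#' methylation and expression summaries). Missing cells (empty, `NA`, `NaN`)
#' are imputed by the column median, with the imputation count reported.
#'
#' @param path TSV file path.
#' @return list with `nodeIds` (canonicalized symbols, file order),
#'   `features` (numeric matrix) and `featureNames`.
#' @export
readFeatureMatrix <- function(path) {
  tsv <- .readTsvLines(path)
  if (length(tsv$lines) < 2L) .stopf("feature file needs a header and at least one row")
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) .stopf("feature file header must name at least one feature")
  featureNames <- header[-1L]
  body <- fields[-1L]
  nc <- length(header)
  badRow <- which(lengths(body) != nc)
  if (length(badRow)) {
    .stopf(
      "malformed feature row at line %d: expected %d fields, got %d",
      tsv$lineNumbers[-1L][badRow[1L]], nc, lengths(body)[badRow[1L]]
    )
  }
  nodeIds <- .canonSymbol(vapply(body, `[`, character(1), 1L))
  if (anyDuplicated(nodeIds)) {
    .stopf(
      "duplicate gene symbol in feature matrix: %s",
      nodeIds[duplicated(nodeIds)][1L]
    )
  }
  n <- length(body)
  d <- nc - 1L
  features <- matrix(NA_real_, nrow = n, ncol = d)
  missingTokens <- c("", "NA", "NaN", "nan", ".")
  for (i in seq_len(n)) {
    raw <- body[[i]][-1L]
    isMissing <- trimws(raw) %in% missingTokens
    val <- suppressWarnings(as.numeric(raw))
    badCell <- which(is.na(val) & !isMissing)
    if (length(badCell)) {
      .stopf(
        "non-numeric feature value '%s' at line %d, column '%s'",
        raw[badCell[1L]], tsv$lineNumbers[-1L][i], featureNames[badCell[1L]]
      )
    }
    val[isMissing] <- NA_real_
    features[i, ] <- val
  }
  nImputed <- sum(is.na(features))
  if (nImputed > 0L) {
    for (j in seq_len(d)) {
      miss <- is.na(features[, j])
      if (any(miss)) {
        med <- stats::median(features[!miss, j])
        if (is.na(med)) .stopf("feature column '%s' is entirely missing", featureNames[j])
        features[miss, j] <- med
      }
    }
    message(sprintf("readFeatureMatrix: imputed %d missing cell(s) by column median", nImputed))
  }
  rownames(features) <- nodeIds
  colnames(features) <- featureNames
  list(nodeIds = nodeIds, features = features, featureNames = featureNames)
}

#' Read a binary label table
#'
#' @param path TSV file `gene<TAB>label` with label in `{0,1}`.
#' @return data frame with columns `gene` (canonicalized) and `label`
#'   (integer 0/1).
#' @export
readLabels <- function(path) {
  tsv <- .readTsvLines(path)
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1L]][1L]), "gene")) {
    tsv$lineNumbers <- tsv$lineNumbers[-1L]
    fields <- fields[-1L]
  }
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    .stopf("malformed label row at line %d", tsv$lineNumbers[bad[1L]])
  }
  gene <- .canonSymbol(vapply(fields, `[`, character(1), 1L))
  lab <- vapply(fields, `[`, character(1), 2L)
  if (!all(lab %in% c("0", "1"))) {
    .stopf("labels must be 0 or 1; offending value '%s'", setdiff(lab, c("0", "1"))[1L])
  }
  data.frame(gene = gene, label = as.integer(lab), stringsAsFactors = FALSE)
}

#' Assemble a featured graph from edges and a feature matrix
#'
#' The node universe is the feature matrix: every featurized gene becomes a
#' node, and edges whose endpoints both occur in that universe are kept.
#' Edges touching genes without features are dropped with a warning
#' (`strict = FALSE`) or raise an error naming the first offending gene
#' (`strict = TRUE`).
#'
#' @param edges data frame from [readEdgeList()] (columns `geneA`, `geneB`).
#' @param nodeIds,features,featureNames node universe as returned by
#'   [readFeatureMatrix()].
#' @param strict error on out-of-universe endpoints instead of dropping.
#' @return a [FeaturedGraph-class].
#' @export
assembleGraph <- function(edges, nodeIds, features,
                          featureNames = colnames(features), strict = FALSE) {
  nodeIds <- .canonSymbol(nodeIds)
  idx <- stats::setNames(seq_along(nodeIds), nodeIds)
  ia <- idx[edges$geneA]
  ib <- idx[edges$geneB]
  outside <- is.na(ia) | is.na(ib)
  if (any(outside)) {
    missing <- unique(c(
      edges$geneA[is.na(ia)],
      edges$geneB[is.na(ib)]
    ))
    if (strict) {
      .stopf("edge endpoint not in feature universe: %s", missing[1L])
    }
    warning(sprintf(
      "assembleGraph: dropped %d edge(s) with endpoints outside the feature universe",
      sum(outside)
    ), call. = FALSE)
    ia <- ia[!outside]
    ib <- ib[!outside]
  }
  em <- if (length(ia)) cbind(as.integer(ia), as.integer(ib)) else matrix(integer(0), ncol = 2L)
  FeaturedGraph(
    nodeIds = nodeIds, edges = em, features = features,
    featureNames = featureNames
  )
}

#' Build a label assignment with sampled negatives
#'
#' Positives come from a curated list (e.g. known cancer genes); negatives
#' are either supplied or sampled uniformly without replacement from the
#' non-positive nodes at `negRatio` negatives per positive (default 1:3
#' positives:negatives; use `negRatio = 1` for the label-scarce equal
#' sampling setting). All remaining nodes get the role
#' `unlabelled_intermediate`: they carry messages during training but never
#' enter the loss.
#'
#' @param graph a [FeaturedGraph-class].
#' @param positives character vector of positive gene symbols (must occur in
#'   the graph).
#' @param negatives optional character vector of negative symbols; when
#'   `NULL` they are sampled.
#' @param negRatio negatives sampled per positive (ignored when `negatives`
#'   given).
#' @param seed integer seed for the negative sampling.
#' @return a [LabelAssignment-class] with empty split masks and
#'   `posNegRatio` set to negatives/positives.
#' @export
buildLabelAssignment <- function(graph, positives, negatives = NULL,
                                 negRatio = 3, seed = 1L) {
  ids <- nodeIds(graph)
  positives <- unique(.canonSymbol(positives))
  if (!length(positives)) .stopf("positives must be non-empty")
  missing <- setdiff(positives, ids)
  if (length(missing)) {
    .stopf("positive gene not present in graph: %s", missing[1L])
  }
  roles <- rep("unlabelled_intermediate", length(ids))
  names(roles) <- ids
  roles[positives] <- "positive"
  if (is.null(negatives)) {
    pool <- setdiff(ids, positives)
    nNeg <- as.integer(ceiling(negRatio * length(positives)))
    if (length(pool) < nNeg) {
      .stopf(
        "cannot sample %d negatives from %d candidates (short by %d)",
        nNeg, length(pool), nNeg - length(pool)
      )
    }
    negatives <- .withSeed(seed, sample(pool, nNeg))
  } else {
    negatives <- unique(.canonSymbol(negatives))
    missing <- setdiff(negatives, ids)
    if (length(missing)) .stopf("negative gene not present in graph: %s", missing[1L])
    if (length(intersect(negatives, positives))) {
      .stopf("gene labelled both positive and negative: %s", intersect(negatives, positives)[1L])
    }
  }
  roles[negatives] <- "negative"
  LabelAssignment(roles = unname(roles))
}

#' Write per-node prediction scores
#'
#' Writes a ranked score table for all nodes (sigmoid-scale confidence
#' scores in \[0, 1\]). Rows are ordered by descending score, ties by gene
#' symbol; ranks use competition ("min") ranking so tied scores share a
#' rank.
#'
#' @param nodeIds character gene symbols.
#' @param scores numeric in \[0, 1\], aligned to `nodeIds`.
#' @param roles character roles aligned to `nodeIds`.
#' @param path output TSV path.
#' @return the written path, invisibly.
#' @export
writeScores <- function(nodeIds, scores, roles, path) {
  if (length(scores) != length(nodeIds) || length(roles) != length(nodeIds)) {
    .stopf("nodeIds, scores and roles must be aligned")
  }
  if (length(scores) && (any(!is.finite(scores)) || any(scores < 0 | scores > 1))) {
    .stopf("scores must lie in [0, 1]")
  }
  ord <- order(-scores, nodeIds)
  rank <- rank(-scores[ord], ties.method = "min")
  df <- data.frame(
    gene = nodeIds[ord], role = roles[ord],
    score = scores[ord], rank = as.integer(rank),
    stringsAsFactors = FALSE
  )
  utils::write.table(df,
    file = path, sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Write a featured graph back to edge-list and feature TSVs
#'
#' Inverse of [readEdgeList()] + [readFeatureMatrix()] +
#' [assembleGraph()]: the written files read back to an identical graph
#' (node order, edges and features preserved exactly).
#'
#' @param graph a [FeaturedGraph-class].
#' @param edgePath,featurePath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeFeaturedGraph <- function(graph, edgePath, featurePath) {
  ids <- nodeIds(graph)
  em <- edgeMatrix(graph)
  edgeLines <- if (nrow(em)) {
    paste(ids[em[, 1L]], ids[em[, 2L]], sep = "\t")
  } else {
    character(0)
  }
  writeLines(edgeLines, edgePath)
  X <- nodeFeatures(graph)
  # %.17g round-trips doubles exactly through as.numeric
  body <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(ids[i], sprintf("%.17g", X[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("gene", featureNames(graph)), collapse = "\t"), body),
    con = featurePath
  )
  invisible(c(edgePath, featurePath))
}

#' Write a label table
#'
#' @param labels a [LabelAssignment-class].
#' @param nodeIds gene symbols aligned to the assignment.
#' @param path output TSV path.
#' @return the written path, invisibly. Only labelled (positive/negative)
#'   nodes are written.
#' @export
writeLabelTable <- function(labels, nodeIds, path) {
  roles <- nodeRoles(labels)
  keep <- roles %in% c("positive", "negative")
  df <- data.frame(
    gene = nodeIds[keep],
    label = as.integer(roles[keep] == "positive")
  )
  utils::write.table(df, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
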