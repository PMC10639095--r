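# Synthetic featured-graph generator with planted two-class structure.
#
# Emulates the statistical shape of a multi-omic featured PPI network:
# heavy-tailed degree distribution (preferential attachment) or controlled
# community structure (stochastic block model), Gaussian node features whose
# mean differs between two hidden classes on a random half of the columns,
# optional neighbour-mean smoothing (homophily), and a sparse label reveal
# with a configurable positive fraction. Hidden classes are returned
# separately and never stored inside the FeaturedGraph, so they cannot leak
# into training.

#' Configuration for the synthetic featured-graph generator
#'
#' @param nNodes number of nodes.
#' @param topology `"preferential_attachment"` (heavy-tailed, PPI-like
#'   degrees) or `"stochastic_block"` (controlled homophily).
#' @param topologyParams for preferential attachment, `list(m = 2)` edges
#'   added per new node; for the block model,
#'   `list(blockSizes =, pWithin =, pBetween =)`.
#' @param nFeatures feature dimensionality.
#' @param effectSize class-mean separation, in units of the unit feature
#'   standard deviation, applied to a random half of the columns.
#' @param homophilyRounds rounds of averaging each node's features with its
#'   neighbour mean.
#' @param labelFraction fraction of nodes receiving a revealed label.
#' @param posFraction fraction of labelled nodes that are positive (also the
#'   hidden class-1 prevalence).
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return validated config list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nNodes = 2000L,
                            topology = c("preferential_attachment", "stochastic_block"),
                            topologyParams = list(m = 2L),
                            nFeatures = 32L,
                            effectSize = 2,
                            homophilyRounds = 1L,
                            labelFraction = 0.5,
                            posFraction = 0.25,
                            seed = 1L) {
  topology <- match.arg(topology)
  if (nNodes < 2L) .stopf("nNodes must be at least 2")
  if (nFeatures < 1L) .stopf("nFeatures must be positive")
  if (effectSize < 0) .stopf("effectSize must be non-negative")
  if (homophilyRounds < 0L) .stopf("homophilyRounds must be non-negative")
  if (labelFraction <= 0 || labelFraction > 1) .stopf("labelFraction must be in (0, 1]")
  if (posFraction <= 0 || posFraction >= 1) .stopf("posFraction must be in (0, 1)")
  if (topology == "preferential_attachment") {
    m <- topologyParams$m
    if (is.null(m) || m < 1L) .stopf("topologyParams$m must be a positive integer")
    if (nNodes < m + 1L) .stopf("nNodes must exceed attachment degree m")
  } else {
    p <- topologyParams
    if (is.null(p$blockSizes) || is.null(p$pWithin) || is.null(p$pBetween)) {
      .stopf("stochastic_block needs blockSizes, pWithin and pBetween")
    }
    if (sum(p$blockSizes) != nNodes) .stopf("blockSizes must sum to nNodes")
    if (any(c(p$pWithin, p$pBetween) < 0) || any(c(p$pWithin, p$pBetween) > 1)) {
      .stopf("block probabilities must lie in [0, 1]")
    }
  }
  structure(
    list(
      nNodes = as.integer(nNodes), topology = topology,
      topologyParams = topologyParams, nFeatures = as.integer(nFeatures),
      effectSize = effectSize, homophilyRounds = as.integer(homophilyRounds),
      labelFraction = labelFraction, posFraction = posFraction,
      seed = as.integer(seed)
    ),
    class = "SyntheticConfig"
  )
}

#' Generate a random topology
#'
#' Preferential attachment grows the graph from `m` seed nodes, each new
#' node attaching `m` edges to distinct existing nodes chosen with
#' probability proportional to degree + 1, giving exactly `m * (nNodes - m)`
#' edges. The stochastic block model draws each within/between-block pair
#' independently.
#'
#' @param config a [syntheticConfig()].
#' @return two-column integer edge matrix (canonical form).
#' @export
generateTopology <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  .withSeed(config$seed, {
    if (config$topology == "preferential_attachment") {
      .paTopology(config$nNodes, config$topologyParams$m)
    } else {
      .sbmTopology(
        config$topologyParams$blockSizes,
        config$topologyParams$pWithin, config$topologyParams$pBetween
      )
    }
  })
}

.paTopology <- function(n, m) {
  deg <- integer(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  k <- 0L
  for (v in (m + 1L):n) {
    existing <- seq_len(v - 1L)
    w <- deg[existing] + 1
    targets <- if (length(existing) == m) {
      existing
    } else {
      sample(existing, m, prob = w)
    }
    for (u in targets) {
      k <- k + 1L
      from[k] <- u
      to[k] <- v
      deg[u] <- deg[u] + 1L
    }
    deg[v] <- deg[v] + m
  }
  .canonicalEdges(cbind(from, to))
}

.sbmTopology <- function(blockSizes, pWithin, pBetween) {
  n <- sum(blockSizes)
  block <- rep(seq_along(blockSizes), blockSizes)
  offsets <- cumsum(c(0L, blockSizes))
  edges <- list()
  nb <- length(blockSizes)
  for (a in seq_len(nb)) {
    for (b in a:nb) {
      p <- if (a == b) pWithin else pBetween
      if (p <= 0) next
      if (a == b) {
        sz <- blockSizes[a]
        nPairs <- sz * (sz - 1) / 2
      } else {
        nPairs <- blockSizes[a] * blockSizes[b]
      }
      if (nPairs == 0) next
      nEdges <- stats::rbinom(1L, nPairs, p)
      if (nEdges == 0L) next
      pick <- sample(nPairs, nEdges)
      if (a == b) {
        # pair index -> (i, j) with i < j within the block
        j <- floor((1 + sqrt(8 * (pick - 1) + 1)) / 2) + 1
        i <- pick - (j - 1) * (j - 2) / 2
        edges[[length(edges) + 1L]] <-
          cbind(offsets[a] + i, offsets[a] + j)
      } else {
        i <- ((pick - 1) %% blockSizes[a]) + 1
        j <- ((pick - 1) %/% blockSizes[a]) + 1
        edges[[length(edges) + 1L]] <-
          cbind(offsets[a] + i, offsets[b] + j)
      }
    }
  }
  if (!length(edges)) {
    return(matrix(integer(0), ncol = 2L))
  }
  .canonicalEdges(do.call(rbind, edges))
}

# one round of homophily smoothing: average own features with neighbour mean
.smoothFeatures <- function(X, A) {
  deg <- Matrix::rowSums(A)
  nm <- as.matrix(A %*% X)
  pos <- deg > 0
  nm[pos, ] <- nm[pos, , drop = FALSE] / deg[pos]
  nm[!pos, ] <- X[!pos, , drop = FALSE] # isolated nodes keep their own value
  (X + nm) / 2
}

#' Generate a featured graph with planted two-class structure
#'
#' Assigns each node a hidden class (class 1 with probability
#' `posFraction`), draws unit-variance Gaussian features with a mean shift
#' of `effectSize` for class-1 nodes on a random half of the columns,
#' applies `homophilyRounds` rounds of neighbour-mean smoothing, and reveals
#' labels for `labelFraction` of the nodes such that the positive fraction
#' among labelled nodes matches `posFraction` up to rounding. Unlabelled
#' nodes get the role `unlabelled_intermediate`.
#'
#' @param config a [syntheticConfig()].
#' @return list with `graph` ([FeaturedGraph-class]), `labels`
#'   ([LabelAssignment-class]), `trueClasses` (0/1 integer vector, for
#'   evaluation only) and `shiftedColumns` (which columns carry signal).
#' @export
generateFeaturedGraph <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$nNodes
  d <- config$nFeatures
  edges <- generateTopology(config)
  nLab <- .roundHalfUp(config$labelFraction * n)
  nPosLab <- .roundHalfUp(config$posFraction * nLab)
  res <- .withSeed(config$seed + 1L, {
    classes <- stats::rbinom(n, 1L, config$posFraction)
    # guarantee enough members of each class to label
    if (sum(classes == 1L) < nPosLab || sum(classes == 0L) < nLab - nPosLab) {
      .stopf("class draw too skewed to reveal %d labels; enlarge the graph", nLab)
    }
    shifted <- sort(sample(d, max(1L, floor(d / 2))))
    X <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    X[classes == 1L, shifted] <- X[classes == 1L, shifted] + config$effectSize
    list(classes = classes, shifted = shifted, X = X)
  })
  X <- res$X
  if (config$homophilyRounds > 0L) {
    A <- .adjacency(n, edges)
    for (r in seq_len(config$homophilyRounds)) X <- .smoothFeatures(X, A)
  }
  ids <- sprintf("G%05d", seq_len(n))
  graph <- FeaturedGraph(
    nodeIds = ids, edges = edges, features = X,
    featureNames = sprintf("f%03d", seq_len(d))
  )
  roles <- .withSeed(config$seed + 2L, {
    roles <- rep("unlabelled_intermediate", n)
    posIdx <- sample(which(res$classes == 1L), nPosLab)
    negIdx <- sample(which(res$classes == 0L), nLab - nPosLab)
    roles[posIdx] <- "positive"
    roles[negIdx] <- "negative"
    roles
  })
  list(
    graph = graph, labels = LabelAssignment(roles),
    trueClasses = res$classes, shiftedColumns = res$shifted
  )
}

#' Generate a set of small labelled graphs
#'
#' For graph-level classification: each class shares the topology model but
#' carries a feature-mean signature of magnitude `effectSize` on its own
#' disjoint block of columns, so at `effectSize = 0` the classes are
#' indistinguishable. Class sizes are balanced up to remainder.
#'
#' @param nGraphs number of graphs (at least `2 * nClasses`).
#' @param nodesPerGraph nodes in each graph.
#' @param nClasses number of classes.
#' @param effectSize per-class feature mean shift in SD units.
#' @param seed integer seed.
#' @param nFeatures feature dimensionality (default 16).
#' @param m preferential-attachment degree (default 2).
#' @return list with elements `graphs` (list of [FeaturedGraph-class]) and
#'   `classLabels` (integer vector, classes `0..nClasses-1`).
#' @export
generateGraphSet <- function(nGraphs, nodesPerGraph, nClasses = 2L,
                             effectSize = 1, seed = 1L, nFeatures = 16L,
                             m = 2L) {
  if (nGraphs < 2L * nClasses) .stopf("need at least 2 graphs per class")
  if (nClasses < 2L) .stopf("need at least 2 classes")
  if (nFeatures < nClasses) .stopf("need at least one feature column per class")
  classLabels <- rep(seq_len(nClasses) - 1L, length.out = nGraphs)
  blocks <- split(seq_len(nFeatures), cut(seq_len(nFeatures), nClasses, labels = FALSE))
  graphs <- vector("list", nGraphs)
  for (g in seq_len(nGraphs)) {
    cfg <- syntheticConfig(
      nNodes = nodesPerGraph, topologyParams = list(m = m),
      nFeatures = nFeatures, effectSize = 0, homophilyRounds = 0L,
      labelFraction = 1, posFraction = 0.5, seed = seed + 17L * g
    )
    edges <- generateTopology(cfg)
    X <- .withSeed(seed + 17L * g + 1L, {
      matrix(stats::rnorm(nodesPerGraph * nFeatures),
        nrow = nodesPerGraph
      )
    })
    cols <- blocks[[classLabels[g] + 1L]]
    X[, cols] <- X[, cols] + effectSize
    graphs[[g]] <- FeaturedGraph(
      nodeIds = sprintf("N%04d", seq_len(nodesPerGraph)), edges = edges,
      features = X, featureNames = sprintf("f%03d", seq_len(nFeatures))
    )
  }
  list(graphs = graphs, classLabels = classLabels)
}
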