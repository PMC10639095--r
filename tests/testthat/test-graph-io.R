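test_that("edge list filtering, dedup and self-pair removal follow the documented rules", {
  f <- writeTsv(c(
    "A\tB\t0.9",
    "B\tA\t0.9",
    "C\tC\t0.7",
    "A\tC\t0.4"
  ))
  rec <- suppressMessages(readEdgeList(f, minConfidence = 0.5))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$geneA, "A")
  expect_equal(rec$geneB, "B")
  expect_equal(rec$confidence, 0.9)

  # no threshold: three distinct valid rows survive
  f2 <- writeTsv(c("A\tB", "B\tC", "A\tC"))
  expect_equal(nrow(readEdgeList(f2)), 3L)

  # "higher than" is strict: a row at exactly the threshold is removed
  f3 <- writeTsv(c("A\tB\t0.85", "A\tC\t0.86"))
  kept <- readEdgeList(f3, minConfidence = 0.85)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$geneB, "C")
})

test_that("edge list parse errors name the offending line and configuration", {
  f <- writeTsv(c("A\tB", "onlyonefield"))
  expect_error(readEdgeList(f), "line 2")
  f2 <- writeTsv(c("A\tB", "B\tC"))
  expect_error(readEdgeList(f2, minConfidence = 0.5), "no confidence column")
  f3 <- writeTsv(c("A\tB\tnotanumber"))
  expect_error(readEdgeList(f3), "confidence")
})

test_that("raising the confidence threshold never increases surviving edges", {
  set.seed(7)
  lines <- sprintf(
    "G%d\tG%d\t%.3f", sample(20, 60, TRUE), sample(20, 60, TRUE),
    runif(60)
  )
  f <- writeTsv(lines)
  counts <- vapply(
    seq(0, 1, by = 0.1),
    function(th) nrow(suppressMessages(readEdgeList(f, minConfidence = th))),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("feature matrix reading imputes by column median and rejects bad input", {
  f <- writeTsv(c(
    "gene\tmut\texpr",
    "TP53\t1\t0.5",
    "EGFR\t\t0.2",
    "MYC\t3\t0.9"
  ))
  fm <- suppressMessages(readFeatureMatrix(f))
  expect_equal(dim(fm$features), c(3L, 2L))
  expect_equal(fm$featureNames, c("mut", "expr"))
  expect_equal(fm$features["EGFR", "mut"], 2) # median of {1, 3}

  fd <- writeTsv(c("gene\tx", "A\t1", "A\t2"))
  expect_error(readFeatureMatrix(fd), "duplicate")
  fb <- writeTsv(c("gene\tx", "A\toops"))
  expect_error(readFeatureMatrix(fb), "non-numeric")
})

test_that("graph assembly keeps in-universe edges and honours strict mode", {
  feats <- matrix(rnorm(6), nrow = 3, dimnames = list(NULL, c("a", "b")))
  edges <- data.frame(geneA = "A", geneB = "B", confidence = NA_real_)
  g <- assembleGraph(edges, c("A", "B", "C"), feats)
  expect_equal(numNodes(g), 3L)
  expect_equal(numEdges(g), 1L)

  out <- data.frame(geneA = "A", geneB = "D", confidence = NA_real_)
  expect_warning(
    g2 <- assembleGraph(out, c("A", "B"), feats[1:2, ]),
    "dropped 1 edge"
  )
  expect_equal(numEdges(g2), 0L)
  expect_error(
    assembleGraph(out, c("A", "B"), feats[1:2, ], strict = TRUE),
    "D"
  )
})

test_that("written graphs read back identically (round trip)", {
  sim <- tinyGraph(n = 30, d = 3, seed = 5)
  g <- sim$graph
  ep <- tempfile(fileext = ".tsv")
  fp <- tempfile(fileext = ".tsv")
  writeFeaturedGraph(g, ep, fp)
  fm <- readFeatureMatrix(fp)
  rec <- readEdgeList(ep)
  g2 <- assembleGraph(rec, fm$nodeIds, fm$features, fm$featureNames)
  expect_identical(nodeIds(g2), nodeIds(g))
  expect_identical(edgeMatrix(g2), edgeMatrix(g))
  expect_identical(nodeFeatures(g2), nodeFeatures(g))
})

test_that("negative sampling respects the ratio, the seed, and the role partition", {
  sim <- tinyGraph(n = 1000, d = 2, seed = 9)
  g <- sim$graph
  pos <- nodeIds(g)[1:100]
  la <- buildLabelAssignment(g, pos, negRatio = 3, seed = 4)
  tab <- table(nodeRoles(la))
  expect_equal(unname(tab[["positive"]]), 100L)
  expect_equal(unname(tab[["negative"]]), 300L)
  expect_equal(unname(tab[["unlabelled_intermediate"]]), 600L)
  expect_equal(posNegRatio(la), 3)
  expect_equal(length(nodeRoles(la)), numNodes(g)) # roles partition V

  # equal sampling mode for the label-scarce task
  pos95 <- nodeIds(g)[1:95]
  la1 <- buildLabelAssignment(g, pos95, negRatio = 1, seed = 4)
  expect_equal(sum(nodeRoles(la1) == "negative"), 95L)

  # determinism and shortfall error
  la2 <- buildLabelAssignment(g, pos, negRatio = 3, seed = 4)
  expect_identical(nodeRoles(la), nodeRoles(la2))
  expect_error(
    buildLabelAssignment(g, nodeIds(g)[1:900], negRatio = 3, seed = 1),
    "short by"
  )
})

test_that("score tables rank by descending score with shared ranks for ties", {
  f <- tempfile(fileext = ".tsv")
  writeScores(c("A", "B", "C"), c(0.9, 0.1, 0.9), rep("unknown", 3), f)
  tab <- read.delim(f)
  expect_equal(tab$gene, c("A", "C", "B")) # ties broken by symbol
  expect_equal(tab$rank, c(1L, 1L, 3L)) # competition ranking
  expect_error(
    writeScores("A", 1.2, "unknown", tempfile()),
    "\\[0, 1\\]"
  )
  fe <- tempfile(fileext = ".tsv")
  writeScores(character(0), numeric(0), character(0), fe)
  expect_equal(readLines(fe), "gene\trole\tscore\trank")
})
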