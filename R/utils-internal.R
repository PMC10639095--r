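# Internal helpers shared across modules. All randomness in the package is
# routed through .withSeed so no function disturbs the caller's RNG stream.

# evaluate `code` under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# conventional half-up rounding; R's round() is banker's
.roundHalfUp <- function(x) as.integer(floor(x + 0.5))

.sigmoid <- function(x) 1 / (1 + exp(-x))

# log(sigmoid(x)) and log(1 - sigmoid(x)), numerically stable
.logSigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
.log1mSigmoid <- function(x) .logSigmoid(-x)

# sparse symmetric 0/1 adjacency from a canonical edge matrix
.adjacency <- function(nNodes, edges) {
  if (nrow(edges) == 0L) {
    return(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(nNodes, nNodes)
    ))
  }
  Matrix::sparseMatrix(
    i = c(edges[, 1L], edges[, 2L]),
    j = c(edges[, 2L], edges[, 1L]),
    x = 1,
    dims = c(nNodes, nNodes)
  )
}

# neighbour list from edges (used by brute-force oracles and smoothing)
.neighbourList <- function(nNodes, edges) {
  nb <- vector("list", nNodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]
    j <- edges[k, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# apply f elementwise over a nested parameter list (matching shapes);
# entries of class "fixedParam" (e.g. GIN epsilon) pass through untouched
.mapParams <- function(f, a, b = NULL) {
  if (inherits(a, "fixedParam")) {
    return(a)
  }
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- .mapParams(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    return(out)
  }
  if (!is.numeric(a)) {
    return(a)
  }
  if (is.null(b)) f(a) else f(a, b)
}

# reduce a nested parameter list to a single numeric via f (e.g. max abs)
.reduceParams <- function(f, a, init = numeric(0)) {
  acc <- init
  walk <- function(x) {
    if (inherits(x, "fixedParam")) {
      return(invisible(NULL))
    }
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.numeric(x)) acc <<- f(acc, x)
  }
  walk(a)
  acc
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# canonicalize gene symbols: uppercase, strip surrounding whitespace
.canonSymbol <- function(x) toupper(trimws(x))
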