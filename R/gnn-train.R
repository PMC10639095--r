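# Adam optimizer over nested parameter lists. Parameters and gradients share
# the same nesting (layers -> named numeric arrays); entries of class
# "fixedParam" are never updated. Weight decay is applied as an L2 term added
# to the gradient.

.zerosLike <- function(params) .mapParams(function(x) x * 0, params)

.adamInit <- function(params) {
  list(m = .zerosLike(params), v = .zerosLike(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, weightDecay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (inherits(p, "fixedParam")) {
      return(list(p = p, m = m, v = v))
    }
    if (is.list(p)) {
      out <- list(
        p = vector("list", length(p)), m = vector("list", length(p)),
        v = vector("list", length(p))
      )
      names(out$p) <- names(p)
      names(out$m) <- names(p)
      names(out$v) <- names(p)
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        out$p[[i]] <- r$p
        out$m[[i]] <- r$m
        out$v[[i]] <- r$v
      }
      return(out)
    }
    g <- g + weightDecay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# replace the parameter list of a stack (after an optimizer step)
.setStackParams <- function(stack, layers) {
  stack@layers <- layers
  stack
}
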