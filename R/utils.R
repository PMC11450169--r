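# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG with `seed`, evaluates `expr`, then restores the caller's
#' RNG state, so package functions are deterministic without clobbering the
#' session seed.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise numerically stable softmax
#' @param x Matrix; softmax taken across columns within each row.
#' @keywords internal
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' GELU activation (exact Gaussian form) and its derivative
#' @keywords internal
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# X: n x in, W: in x out, b: length out
linear_fwd <- function(X, W, b) {
  sweep(X %*% W, 2L, b, "+")
}

# returns list(dX, dW, db)
linear_bwd <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
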