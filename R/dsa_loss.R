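# Dynamic-margin sub-center ArcFace loss.
#
# Class logits are cosines between the L2-normalized embedding and the
# nearest of K unit-norm prototype sub-centers per class; the target class
# receives an additive angular margin m_c before the scaled softmax, with
# m_c derived per class from its training-set count so that rare classes
# get larger margins.

COS_EPS <- 1e-7

#' Per-class dynamic margins from class counts
#'
#' `m_c = (a - b) * n_c^lambda + b` with the default exponent
#' `lambda = -0.5`: a class with a single example gets the upper bound `a`
#' and the margin decays monotonically towards the lower bound `b` as the
#' class count grows.
#'
#' @param class_counts Positive integer vector of per-class training-set
#'   image counts.
#' @param a Upper margin bound in radians (margin of a singleton class).
#' @param b Lower margin bound in radians (asymptotic margin of an
#'   arbitrarily large class).
#' @param lambda Exponent applied to the class count; must be negative so
#'   margins shrink with class size.
#' @return A `margin_table` list `(margins, class_counts, a, b, lambda)`.
#' @export
compute_margins <- function(class_counts, a = 0.5, b = 0.05, lambda = -0.5) {
  class_counts <- as.numeric(class_counts)
  if (any(class_counts < 1) || any(class_counts != round(class_counts))) {
    stopf("all class counts must be >= 1 and integer-valued")
  }
  if (b >= a) stopf("margin bounds must satisfy b < a")
  if (lambda >= 0) stopf("lambda must be negative so rare classes get larger margins")
  structure(
    list(margins = (a - b) * class_counts^lambda + b,
         class_counts = class_counts, a = a, b = b, lambda = lambda),
    class = "margin_table"
  )
}

#' Loss-head configuration
#' @param s Feature re-scale applied to the cosine logits.
#' @param eps Clamp applied to cosines before angle computations.
#' @return A `loss_config` list.
#' @export
loss_config <- function(s = 64, eps = COS_EPS) {
  if (s <= 0) stopf("scale s must be positive")
  structure(list(s = s, eps = eps), class = "loss_config")
}

# rows of W are sub-centers, class-major: row (j-1)*K + k is class j's k-th.
normalize_rows <- function(W) W / sqrt(rowSums(W^2))

#' Per-class cosines via the nearest sub-center
#'
#' L2-normalizes the embedding and every sub-center, computes all
#' `N_classes * K` dot products, and takes the maximum over each class's K
#' sub-centers (ties broken by the lowest sub-center index). Cosines are
#' clamped to `[-1 + eps, 1 - eps]`.
#'
#' @param embedding Non-zero length-D vector.
#' @param W `(N_classes * K) x D` sub-center matrix, class-major rows.
#' @param K Sub-centers per class.
#' @param eps Clamp width.
#' @return List `(cosines, which_k, clamped)`: the length-N cosine vector,
#'   the selected sub-center index per class, and the clamp mask.
#' @export
subcenter_cosines <- function(embedding, W, K, eps = COS_EPS) {
  nx <- sqrt(sum(embedding^2))
  if (nx == 0) stopf("embedding must be non-zero")
  xn <- embedding / nx
  Wn <- normalize_rows(W)
  all_cos <- as.vector(Wn %*% xn)
  C <- nrow(W) %/% K
  cm <- matrix(all_cos, nrow = C, ncol = K, byrow = TRUE)
  which_k <- max.col(cm, ties.method = "first")
  raw <- cm[cbind(seq_len(C), which_k)]
  cosines <- clamp(raw, -1 + eps, 1 - eps)
  list(cosines = cosines, which_k = which_k, clamped = raw != cosines)
}

#' Margin-adjusted scaled logits
#'
#' The target class's logit is `s * cos(theta_y + m)`, computed stably via
#' the angle-addition identity
#' `s * (cos(theta_y) cos(m) - sin(theta_y) sin(m))`; all other logits are
#' `s * cos(theta_j)`. The margin is applied unconditionally.
#'
#' @param cosines Length-N cosine vector (already clamped).
#' @param target 1-based target class index.
#' @param m Margin in radians for the target class.
#' @param s Logit scale.
#' @return Length-N logit vector.
#' @export
margin_logits <- function(cosines, target, m, s = 64) {
  z <- s * cosines
  cy <- cosines[target]
  sy <- sqrt(1 - cy^2)
  z[target] <- s * (cy * cos(m) - sy * sin(m))
  z
}

#' Dynamic-margin sub-center ArcFace loss over a batch
#'
#' Mean over the batch of the negative log-softmax of the margin-adjusted
#' logits at the true label. Also returns analytic gradients with respect
#' to the (un-normalized) embeddings and the sub-center bank, used by the
#' trainer.
#'
#' @param embeddings `B x D` matrix of classification features.
#' @param labels Length-B vector of 1-based class indices.
#' @param W `(N_classes * K) x D` sub-center bank.
#' @param margin_table A [compute_margins()] table (length N_classes).
#' @param cfg A [loss_config()].
#' @param K Sub-centers per class.
#' @param grads Also compute gradients.
#' @return List `(loss, dembeddings, dW)`; gradient entries NULL unless
#'   requested.
#' @export
dsa_loss <- function(embeddings, labels, W, margin_table, cfg = loss_config(),
                     K = 3L, grads = FALSE) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  B <- nrow(embeddings)
  C <- nrow(W) %/% K
  if (any(labels < 1L | labels > C)) stopf("label out of range 1..%d", C)
  s <- cfg$s
  m_all <- margin_table$margins
  Wn <- normalize_rows(W)
  nw <- sqrt(rowSums(W^2))

  total <- 0
  demb <- if (grads) matrix(0, B, ncol(embeddings)) else NULL
  dWn <- if (grads) matrix(0, nrow(W), ncol(W)) else NULL

  for (i in seq_len(B)) {
    x <- embeddings[i, ]
    nx <- sqrt(sum(x^2))
    if (nx == 0) stopf("embedding must be non-zero")
    xn <- x / nx
    all_cos <- as.vector(Wn %*% xn)
    cm <- matrix(all_cos, nrow = C, ncol = K, byrow = TRUE)
    which_k <- max.col(cm, ties.method = "first")
    raw <- cm[cbind(seq_len(C), which_k)]
    cosines <- clamp(raw, -1 + cfg$eps, 1 - cfg$eps)
    y <- labels[i]
    m <- m_all[y]
    z <- margin_logits(cosines, y, m, s)
    p <- softmax_vec(z)
    total <- total - (z[y] - max(z) - log(sum(exp(z - max(z)))))

    if (grads) {
      dz <- p
      dz[y] <- dz[y] - 1
      dz <- dz / B
      dcos <- s * dz
      cy <- cosines[y]
      sy <- sqrt(1 - cy^2)
      dcos[y] <- s * dz[y] * (cos(m) + cy / sy * sin(m))
      dcos[raw != cosines] <- 0
      sel <- (seq_len(C) - 1L) * K + which_k   # selected bank rows
      dxn <- as.vector(crossprod(Wn[sel, , drop = FALSE], dcos))
      demb[i, ] <- (dxn - xn * sum(dxn * xn)) / nx
      dWn[sel, ] <- dWn[sel, ] + outer(dcos, xn)
    }
  }

  res <- list(loss = total / B)
  if (grads) {
    # back through the row normalization of W
    rowdot <- rowSums(dWn * Wn)
    res$dembeddings <- demb
    res$dW <- (dWn - Wn * rowdot) / nw
  }
  res
}

#' Softmax cross-entropy on linear logits (the `ce` ablation head)
#'
#' @param embeddings `B x D` features.
#' @param labels 1-based class indices.
#' @param Wh `D x N_classes` weights, `bh` length-N bias.
#' @param grads Also compute gradients.
#' @return List `(loss, dembeddings, dWh, dbh)`.
#' @export
ce_head_loss <- function(embeddings, labels, Wh, bh, grads = FALSE) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  B <- nrow(embeddings)
  Z <- linear_fwd(embeddings, Wh, bh)
  Zs <- Z - apply(Z, 1L, max)
  logp <- Zs - log(rowSums(exp(Zs)))
  loss <- -mean(logp[cbind(seq_len(B), labels)])
  res <- list(loss = loss)
  if (grads) {
    P <- exp(logp)
    P[cbind(seq_len(B), labels)] <- P[cbind(seq_len(B), labels)] - 1
    dZ <- P / B
    lb <- linear_bwd(embeddings, Wh, dZ)
    res$dembeddings <- lb$dX
    res$dWh <- lb$dW
    res$dbh <- lb$db
  }
  res
}
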