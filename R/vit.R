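# Class-token-free Vision Transformer backbone with per-layer feature
# fusion through a Squeeze-and-Excitation (SE) gate.
#
# The model is a plain named list: `cfg` (architecture), `params` (named
# parameter arrays, schema documented in R/checkpoint.R) and `fixed_keys`
# (parameter-map entries excluded from optimizer updates, e.g. the fixed
# sine-cosine positional table). All forward passes cache what their
# backward passes need; gradients are computed by hand-written
# reverse-mode passes validated against finite differences in the tests.

LN_EPS <- 1e-6

#' Backbone architecture configuration
#'
#' @param image_size Input side length in pixels; must be divisible by
#'   `patch_size`.
#' @param patch_size Patch side length in pixels.
#' @param depth Number of encoder blocks L.
#' @param dim Embedding width D; must be divisible by `heads` and by 4
#'   (sine-cosine positions split the width over two axes and sin/cos).
#' @param heads Number of attention heads.
#' @param mlp_ratio MLP hidden-width multiplier.
#' @param use_cls_token Prepend a learnable class token (the vanilla ViT
#'   convention); the fusion model runs without one.
#' @return A `backbone_config` list with derived fields `n_patches` and
#'   `grid` attached.
#' @export
backbone_config <- function(image_size = 224L, patch_size = 16L, depth = 12L,
                            dim = 768L, heads = 12L, mlp_ratio = 4,
                            use_cls_token = FALSE) {
  image_size <- as.integer(image_size)
  patch_size <- as.integer(patch_size)
  if (image_size %% patch_size != 0L) {
    stopf("image_size (%d) must be divisible by patch_size (%d)",
          image_size, patch_size)
  }
  if (dim %% heads != 0L) stopf("dim must be divisible by heads")
  if (dim %% 4L != 0L) stopf("dim must be divisible by 4 for sine-cosine positions")
  grid <- image_size %/% patch_size
  structure(
    list(image_size = image_size, patch_size = patch_size,
         depth = as.integer(depth), dim = as.integer(dim),
         heads = as.integer(heads), mlp_ratio = mlp_ratio,
         use_cls_token = isTRUE(use_cls_token),
         grid = grid, n_patches = grid * grid),
    class = "backbone_config"
  )
}

#' The ViT-Base/16 preset (224 input, patch 16, depth 12, width 768, 12 heads)
#' @param use_cls_token See [backbone_config()].
#' @return A `backbone_config`.
#' @export
vit_base_config <- function(use_cls_token = FALSE) {
  backbone_config(224L, 16L, 12L, 768L, 12L, 4, use_cls_token)
}

#' 2D sine-cosine positional encodings
#'
#' Fixed (non-learned) encodings on an `h x w` patch grid, row-major with
#' the row index slowest. Half the width encodes the row coordinate and
#' half the column coordinate; each half splits into sine and cosine parts
#' over a geometric frequency ladder. All values lie in `[-1, 1]`; position
#' (0, 0) has all-zero sine and all-one cosine components.
#'
#' @param grid Integer `(h, w)` patch-grid shape.
#' @param dim Encoding width; must be divisible by 4.
#' @return `(h*w) x dim` matrix.
#' @export
sincos_positions <- function(grid, dim) {
  if (dim %% 4L != 0L) stopf("dim must be divisible by 4, got %d", dim)
  h <- grid[1]; w <- grid[2]
  quarter <- dim %/% 4L
  omega <- 1 / 10000^((seq_len(quarter) - 1) / quarter)
  axis_embed <- function(pos) {
    ang <- outer(pos, omega)           # n x quarter
    cbind(sin(ang), cos(ang))          # n x dim/2
  }
  rows <- rep(0:(h - 1), each = w)
  cols <- rep(0:(w - 1), times = h)
  cbind(axis_embed(rows), axis_embed(cols))
}

init_weight <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

#' Build a classifier model
#'
#' Constructs the parameter map for either the fusion classifier (no class
#' token, fixed sine-cosine positions, SE layer gate, sub-center prototype
#' bank) or the vanilla ViT classifier (class token, learned positions,
#' linear head).
#'
#' @param cfg A [backbone_config()].
#' @param n_classes Number of classes.
#' @param n_subcenters Sub-centers per class K for the `"dsa"` head.
#' @param fusion Fuse all layer outputs through the SE gate (`TRUE`) or use
#'   only the final layer's pooled output (`FALSE`).
#' @param head `"dsa"` (dynamic-margin sub-center ArcFace prototype bank)
#'   or `"linear"` (plain linear logits, softmax cross-entropy).
#' @param seed Integer seed for weight initialization.
#' @return A model list `(cfg, n_classes, n_subcenters, fusion, head,
#'   params, fixed_keys)`.
#' @export
build_classifier <- function(cfg, n_classes, n_subcenters = 3L,
                             fusion = !cfg$use_cls_token, head = c("dsa", "linear"),
                             seed = 0L) {
  head <- match.arg(head)
  with_seed(as.integer(seed), {
    p <- list()
    fixed <- character()
    D <- cfg$dim
    P <- cfg$patch_size^2 * 3L
    N <- cfg$n_patches
    L <- cfg$depth

    p[["patch_embed.weight"]] <- init_weight(P, D)
    p[["patch_embed.bias"]] <- numeric(D)
    if (cfg$use_cls_token) {
      p[["cls_token"]] <- init_weight(1L, D)
      p[["pos_embed"]] <- init_weight(N + 1L, D)
    } else {
      p[["pos_embed"]] <- sincos_positions(c(cfg$grid, cfg$grid), D)
      fixed <- c(fixed, "pos_embed")
    }
    for (l in seq_len(L)) {
      pre <- sprintf("blocks.%d.", l)
      p[[paste0(pre, "ln1.weight")]] <- rep(1, D)
      p[[paste0(pre, "ln1.bias")]] <- numeric(D)
      p[[paste0(pre, "attn.qkv.weight")]] <- init_weight(D, 3L * D)
      p[[paste0(pre, "attn.qkv.bias")]] <- numeric(3L * D)
      p[[paste0(pre, "attn.proj.weight")]] <- init_weight(D, D)
      p[[paste0(pre, "attn.proj.bias")]] <- numeric(D)
      p[[paste0(pre, "ln2.weight")]] <- rep(1, D)
      p[[paste0(pre, "ln2.bias")]] <- numeric(D)
      hmlp <- as.integer(round(D * cfg$mlp_ratio))
      p[[paste0(pre, "mlp.fc1.weight")]] <- init_weight(D, hmlp)
      p[[paste0(pre, "mlp.fc1.bias")]] <- numeric(hmlp)
      p[[paste0(pre, "mlp.fc2.weight")]] <- init_weight(hmlp, D)
      p[[paste0(pre, "mlp.fc2.bias")]] <- numeric(D)
    }
    p[["norm.weight"]] <- rep(1, D)
    p[["norm.bias"]] <- numeric(D)

    if (fusion) {
      rh <- max(1L, L %/% 4L)
      p[["se.fc1.weight"]] <- init_weight(L, rh)
      p[["se.fc1.bias"]] <- numeric(rh)
      # zero-initialized excitation: every gate starts at exactly 0.5
      p[["se.fc2.weight"]] <- matrix(0, rh, L)
      p[["se.fc2.bias"]] <- numeric(L)
    }
    if (head == "dsa") {
      W <- init_weight(as.integer(n_classes) * as.integer(n_subcenters), D)
      p[["subcenters"]] <- W / sqrt(rowSums(W^2))
    } else {
      p[["head.weight"]] <- init_weight(D, as.integer(n_classes))
      p[["head.bias"]] <- numeric(n_classes)
    }

    list(cfg = cfg, n_classes = as.integer(n_classes),
         n_subcenters = as.integer(n_subcenters), fusion = fusion,
         head = head, params = p, fixed_keys = fixed)
  })
}

# --- patch embedding ---------------------------------------------------------

#' Split an image into flattened patches
#'
#' `S x S x 3` array to `N x (p*p*3)` matrix, patches enumerated grid
#' row-major (grid row slowest), each patch flattened in R's column-major
#' array order. [unpatchify()] is the exact inverse.
#'
#' @param image `S x S x 3` numeric array with `S` divisible by `patch_size`.
#' @param patch_size Patch side length in pixels.
#' @return `N x (patch_size^2 * 3)` matrix.
#' @export
patchify <- function(image, patch_size) {
  S <- dim(image)[1]
  g <- S %/% patch_size
  N <- g * g
  P <- patch_size^2 * 3L
  out <- matrix(0, N, P)
  n <- 0L
  for (gr in seq_len(g)) {
    rows <- ((gr - 1L) * patch_size + 1L):(gr * patch_size)
    for (gc in seq_len(g)) {
      cols <- ((gc - 1L) * patch_size + 1L):(gc * patch_size)
      n <- n + 1L
      out[n, ] <- as.vector(image[rows, cols, ])
    }
  }
  out
}

#' Reassemble patches into an image
#' @param patches `N x (patch_size^2 * 3)` matrix from [patchify()].
#' @param patch_size Patch side length.
#' @param image_size Output side length.
#' @return `image_size x image_size x 3` array.
#' @export
unpatchify <- function(patches, patch_size, image_size) {
  g <- image_size %/% patch_size
  out <- array(0, dim = c(image_size, image_size, 3L))
  n <- 0L
  for (gr in seq_len(g)) {
    rows <- ((gr - 1L) * patch_size + 1L):(gr * patch_size)
    for (gc in seq_len(g)) {
      cols <- ((gc - 1L) * patch_size + 1L):(gc * patch_size)
      n <- n + 1L
      out[rows, cols, ] <- array(patches[n, ], dim = c(patch_size, patch_size, 3L))
    }
  }
  out
}

#' Embed an image as a token sequence
#'
#' Splits the image into non-overlapping patches, projects each linearly to
#' the embedding width, prepends the class token when the configuration has
#' one, and adds the positional encodings.
#'
#' @param image Standardized `S x S x 3` array with `S = cfg$image_size`.
#' @param model A model from [build_classifier()].
#' @return Token matrix (`n_patches` or `n_patches + 1` rows) x `dim`.
#' @export
patchify_embed <- function(image, model) {
  cfg <- model$cfg
  d <- dim(image)
  if (d[1] != cfg$image_size || d[2] != cfg$image_size) {
    stopf("image is %dx%d but the backbone expects %dx%d",
          d[1], d[2], cfg$image_size, cfg$image_size)
  }
  patches <- patchify(image, cfg$patch_size)
  tok <- linear_fwd(patches, model$params[["patch_embed.weight"]],
                    model$params[["patch_embed.bias"]])
  if (cfg$use_cls_token) tok <- rbind(model$params[["cls_token"]], tok)
  tok + model$params[["pos_embed"]]
}

# --- layer norm --------------------------------------------------------------

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

# --- attention ---------------------------------------------------------------

attn_fwd <- function(x, p, pre, heads) {
  D <- ncol(x)
  dh <- D %/% heads
  qkv <- linear_fwd(x, p[[paste0(pre, "attn.qkv.weight")]],
                    p[[paste0(pre, "attn.qkv.bias")]])
  Q <- qkv[, 1:D, drop = FALSE]
  K <- qkv[, (D + 1):(2 * D), drop = FALSE]
  V <- qkv[, (2 * D + 1):(3 * D), drop = FALSE]
  A <- vector("list", heads)
  O <- matrix(0, nrow(x), D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  out <- linear_fwd(O, p[[paste0(pre, "attn.proj.weight")]],
                    p[[paste0(pre, "attn.proj.bias")]])
  list(out = out, x = x, Q = Q, K = K, V = V, A = A, O = O)
}

attn_bwd <- function(dout, cache, p, pre, heads) {
  D <- ncol(cache$x)
  dh <- D %/% heads
  g <- list()
  lb <- linear_bwd(cache$O, p[[paste0(pre, "attn.proj.weight")]], dout)
  g[[paste0(pre, "attn.proj.weight")]] <- lb$dW
  g[[paste0(pre, "attn.proj.bias")]] <- lb$db
  dO <- lb$dX
  dQ <- matrix(0, nrow(dout), D)
  dK <- matrix(0, nrow(dout), D)
  dV <- matrix(0, nrow(dout), D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  dqkv <- cbind(dQ, dK, dV)
  lb2 <- linear_bwd(cache$x, p[[paste0(pre, "attn.qkv.weight")]], dqkv)
  g[[paste0(pre, "attn.qkv.weight")]] <- lb2$dW
  g[[paste0(pre, "attn.qkv.bias")]] <- lb2$db
  list(dx = lb2$dX, grads = g)
}

# --- encoder block (pre-norm) ------------------------------------------------

block_fwd <- function(x, p, pre, heads) {
  ln1 <- ln_fwd(x, p[[paste0(pre, "ln1.weight")]], p[[paste0(pre, "ln1.bias")]])
  att <- attn_fwd(ln1$y, p, pre, heads)
  h <- x + att$out
  ln2 <- ln_fwd(h, p[[paste0(pre, "ln2.weight")]], p[[paste0(pre, "ln2.bias")]])
  fc1 <- linear_fwd(ln2$y, p[[paste0(pre, "mlp.fc1.weight")]],
                    p[[paste0(pre, "mlp.fc1.bias")]])
  act <- gelu(fc1)
  fc2 <- linear_fwd(act, p[[paste0(pre, "mlp.fc2.weight")]],
                    p[[paste0(pre, "mlp.fc2.bias")]])
  out <- h + fc2
  list(out = out, ln1 = ln1, att = att, h = h, ln2 = ln2, fc1 = fc1, act = act)
}

block_bwd <- function(dout, cache, p, pre, heads) {
  g <- list()
  # MLP branch
  lb2 <- linear_bwd(cache$act, p[[paste0(pre, "mlp.fc2.weight")]], dout)
  g[[paste0(pre, "mlp.fc2.weight")]] <- lb2$dW
  g[[paste0(pre, "mlp.fc2.bias")]] <- lb2$db
  dfc1 <- lb2$dX * gelu_grad(cache$fc1)
  lb1 <- linear_bwd(cache$ln2$y, p[[paste0(pre, "mlp.fc1.weight")]], dfc1)
  g[[paste0(pre, "mlp.fc1.weight")]] <- lb1$dW
  g[[paste0(pre, "mlp.fc1.bias")]] <- lb1$db
  l2 <- ln_bwd(lb1$dX, cache$ln2, p[[paste0(pre, "ln2.weight")]])
  g[[paste0(pre, "ln2.weight")]] <- l2$dg
  g[[paste0(pre, "ln2.bias")]] <- l2$db
  dh <- dout + l2$dx
  # attention branch
  ab <- attn_bwd(dh, cache$att, p, pre, heads)
  g <- c(g, ab$grads)
  l1 <- ln_bwd(ab$dx, cache$ln1, p[[paste0(pre, "ln1.weight")]])
  g[[paste0(pre, "ln1.weight")]] <- l1$dg
  g[[paste0(pre, "ln1.bias")]] <- l1$db
  dx <- dh + l1$dx
  list(dx = dx, grads = g)
}

#' Run the encoder and collect every layer's output
#'
#' @param tokens Token matrix from [patchify_embed()].
#' @param model A model from [build_classifier()].
#' @param keep_caches Keep per-block caches for a backward pass.
#' @return List with `outputs` (length-`depth` list of token matrices, one
#'   per block, the fusion taps) and, when requested, `caches`.
#' @export
encoder_forward <- function(tokens, model, keep_caches = FALSE) {
  L <- model$cfg$depth
  heads <- model$cfg$heads
  outs <- vector("list", L)
  caches <- if (keep_caches) vector("list", L) else NULL
  x <- tokens
  for (l in seq_len(L)) {
    bc <- block_fwd(x, model$params, sprintf("blocks.%d.", l), heads)
    outs[[l]] <- bc$out
    if (keep_caches) caches[[l]] <- bc
    x <- bc$out
  }
  list(outputs = outs, caches = caches)
}

#' Pool each layer's tokens into a layer-by-feature stack
#'
#' Mean over the token axis for each of the L per-layer outputs, giving the
#' `L x D` stack the SE gate operates on.
#'
#' @param layer_outputs List of token matrices (all `N x D`).
#' @return `L x D` matrix.
#' @export
pool_layers <- function(layer_outputs) {
  t(vapply(layer_outputs, colMeans, numeric(ncol(layer_outputs[[1]]))))
}

#' Fuse a layer stack through the SE gate
#'
#' Squeeze: mean over the feature axis per layer. Excitation: two affine
#' maps (L -> r_h -> L) with ReLU between and a sigmoid gate, giving
#' per-layer weights in (0, 1). The output is the gate-weighted sum of the
#' stack's rows (the sum over the layer axis).
#'
#' @param stack `L x D` matrix from [pool_layers()].
#' @param se List with `fc1.weight` (L x r_h), `fc1.bias`, `fc2.weight`
#'   (r_h x L), `fc2.bias`; a model's SE parameters can be extracted with
#'   [se_params()].
#' @param keep_cache Keep intermediates for the backward pass.
#' @return Length-D fused feature vector; with `keep_cache`, a list
#'   `(out, cache)` where `cache$w` holds the gate weights.
#' @export
se_fuse <- function(stack, se, keep_cache = FALSE) {
  z <- rowMeans(stack)
  h1pre <- as.vector(z %*% se$fc1.weight) + se$fc1.bias
  h1 <- pmax(h1pre, 0)
  wpre <- as.vector(h1 %*% se$fc2.weight) + se$fc2.bias
  w <- sigmoid(wpre)
  out <- as.vector(crossprod(stack, w))
  if (!keep_cache) return(out)
  list(out = out, cache = list(stack = stack, z = z, h1pre = h1pre,
                               h1 = h1, w = w))
}

se_fuse_bwd <- function(dout, cache, se) {
  stack <- cache$stack
  L <- nrow(stack); D <- ncol(stack)
  dw <- as.vector(stack %*% dout)
  dstack <- outer(cache$w, dout)
  dwpre <- dw * cache$w * (1 - cache$w)
  dW2 <- outer(cache$h1, dwpre)
  db2 <- dwpre
  dh1 <- as.vector(se$fc2.weight %*% dwpre)
  dh1pre <- dh1 * (cache$h1pre > 0)
  dW1 <- outer(cache$z, dh1pre)
  db1 <- dh1pre
  dz <- as.vector(se$fc1.weight %*% dh1pre)
  dstack <- dstack + matrix(dz / D, L, D)
  list(dstack = dstack,
       grads = list("se.fc1.weight" = dW1, "se.fc1.bias" = db1,
                    "se.fc2.weight" = dW2, "se.fc2.bias" = db2))
}

#' Extract a model's SE-gate parameters
#' @param model A fusion model from [build_classifier()].
#' @return List `(fc1.weight, fc1.bias, fc2.weight, fc2.bias)`.
#' @export
se_params <- function(model) {
  list(fc1.weight = model$params[["se.fc1.weight"]],
       fc1.bias = model$params[["se.fc1.bias"]],
       fc2.weight = model$params[["se.fc2.weight"]],
       fc2.bias = model$params[["se.fc2.bias"]])
}

# --- full feature extractor --------------------------------------------------

#' Compute the classification feature for one image
#'
#' Runs patch embedding and the full encoder. With fusion, each block's
#' output is mean-pooled over tokens (the final block after the terminal
#' layer norm), stacked `L x D`, and fused by the SE gate. Without fusion,
#' the feature is the final normalized layer's pooled tokens (or its class
#' token when the configuration has one).
#'
#' @param model A model from [build_classifier()].
#' @param image Standardized `S x S x 3` array.
#' @param keep_caches Keep every cache needed for a backward pass.
#' @return List with `feature` (length-D vector), `stack` (`L x D` or NULL),
#'   `gates` (SE gate weights or NULL) and, when requested, internal caches.
#' @export
forward_features <- function(model, image, keep_caches = FALSE) {
  tokens <- patchify_embed(image, model)
  enc <- encoder_forward(tokens, model, keep_caches = keep_caches)
  L <- model$cfg$depth
  lnf <- ln_fwd(enc$outputs[[L]], model$params[["norm.weight"]],
                model$params[["norm.bias"]])
  if (model$fusion) {
    stack <- pool_layers(c(enc$outputs[seq_len(L - 1L)], list(lnf$y)))
    fused <- se_fuse(stack, se_params(model), keep_cache = TRUE)
    res <- list(feature = fused$out, stack = stack, gates = fused$cache$w)
    if (keep_caches) {
      res$caches <- list(tokens = tokens, enc = enc, lnf = lnf,
                         se = fused$cache, image = image)
    }
    res
  } else {
    feat <- if (model$cfg$use_cls_token) lnf$y[1L, ] else colMeans(lnf$y)
    res <- list(feature = feat, stack = NULL, gates = NULL)
    if (keep_caches) {
      res$caches <- list(tokens = tokens, enc = enc, lnf = lnf, image = image)
    }
    res
  }
}

# Backward from d(feature) to gradients of every backbone parameter.
# Returns a named gradient list aligned with model$params keys.
features_backward <- function(model, fwd, dfeature) {
  cfg <- model$cfg
  L <- cfg$depth
  caches <- fwd$caches
  grads <- list()
  ntok <- nrow(caches$tokens)

  if (model$fusion) {
    sb <- se_fuse_bwd(dfeature, caches$se, se_params(model))
    grads <- c(grads, sb$grads)
    dstack <- sb$dstack
  } else {
    dstack <- NULL
  }

  # gradient flowing into each block output
  dx <- matrix(0, ntok, cfg$dim)
  # final layer tap goes through the terminal layer norm
  dlnf_y <- if (model$fusion) {
    matrix(dstack[L, ] / ntok, ntok, cfg$dim, byrow = TRUE)
  } else if (cfg$use_cls_token) {
    m <- matrix(0, ntok, cfg$dim)
    m[1L, ] <- dfeature
    m
  } else {
    matrix(dfeature / ntok, ntok, cfg$dim, byrow = TRUE)
  }
  lnb <- ln_bwd(dlnf_y, caches$lnf, model$params[["norm.weight"]])
  grads[["norm.weight"]] <- lnb$dg
  grads[["norm.bias"]] <- lnb$db
  dx <- dx + lnb$dx

  for (l in rev(seq_len(L))) {
    if (model$fusion && l < L) {
      dx <- dx + matrix(dstack[l, ] / ntok, ntok, cfg$dim, byrow = TRUE)
    }
    bb <- block_bwd(dx, caches$enc$caches[[l]], model$params,
                    sprintf("blocks.%d.", l), cfg$heads)
    grads <- c(grads, bb$grads)
    dx <- bb$dx
  }

  # dx is now the gradient w.r.t. tokens (= patch embedding + positions)
  if (cfg$use_cls_token) {
    grads[["cls_token"]] <- dx[1L, , drop = FALSE]
    grads[["pos_embed"]] <- dx
    dpatch_tok <- dx[-1L, , drop = FALSE]
  } else {
    grads[["pos_embed"]] <- dx   # dropped for fixed tables by the optimizer
    dpatch_tok <- dx
  }
  patches <- patchify(caches$image, cfg$patch_size)
  lb <- linear_bwd(patches, model$params[["patch_embed.weight"]], dpatch_tok)
  grads[["patch_embed.weight"]] <- lb$dW
  grads[["patch_embed.bias"]] <- lb$db
  grads
}
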