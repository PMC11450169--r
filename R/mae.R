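# Masked-autoencoder self-supervised pre-training.
#
# A large fraction of image patches is masked; the encoder (the same
# class-token-free ViT as the classifier backbone) sees only the visible
# patches plus their positions; a narrower decoder restores the full-length
# sequence with a shared learned mask token, adds its own positional
# encodings, and linearly maps each token to the patch's pixel values.
# The reconstruction loss is mean squared error over masked patches only.

#' Build an MAE model
#'
#' Encoder parameters follow the classifier backbone's key schema exactly
#' (so weights transfer by name); decoder parameters live under `decoder.*`
#' and are never transferred downstream.
#'
#' @param cfg Encoder [backbone_config()] (must be class-token-free; the
#'   pre-trained encoder has to match the fusion classifier).
#' @param dec_depth Decoder blocks (lighter than the encoder).
#' @param dec_dim Decoder width; divisible by `dec_heads` and 4.
#' @param dec_heads Decoder attention heads.
#' @param seed Integer seed for weight initialization.
#' @return A model list `(cfg, dec_cfg, params, fixed_keys)`.
#' @export
build_mae <- function(cfg, dec_depth = 1L, dec_dim = 32L, dec_heads = 4L,
                      seed = 0L) {
  if (cfg$use_cls_token) {
    stopf("MAE pre-training runs without a class token so the encoder matches the fusion classifier")
  }
  if (dec_dim %% dec_heads != 0L || dec_dim %% 4L != 0L) {
    stopf("dec_dim must be divisible by dec_heads and by 4")
  }
  with_seed(as.integer(seed), {
    D <- cfg$dim
    P <- cfg$patch_size^2 * 3L
    N <- cfg$n_patches
    Dd <- as.integer(dec_dim)

    p <- list()
    p[["patch_embed.weight"]] <- init_weight(P, D)
    p[["patch_embed.bias"]] <- numeric(D)
    p[["pos_embed"]] <- sincos_positions(c(cfg$grid, cfg$grid), D)
    for (l in seq_len(cfg$depth)) {
      pre <- sprintf("blocks.%d.", l)
      hmlp <- as.integer(round(D * cfg$mlp_ratio))
      p[[paste0(pre, "ln1.weight")]] <- rep(1, D)
      p[[paste0(pre, "ln1.bias")]] <- numeric(D)
      p[[paste0(pre, "attn.qkv.weight")]] <- init_weight(D, 3L * D)
      p[[paste0(pre, "attn.qkv.bias")]] <- numeric(3L * D)
      p[[paste0(pre, "attn.proj.weight")]] <- init_weight(D, D)
      p[[paste0(pre, "attn.proj.bias")]] <- numeric(D)
      p[[paste0(pre, "ln2.weight")]] <- rep(1, D)
      p[[paste0(pre, "ln2.bias")]] <- numeric(D)
      p[[paste0(pre, "mlp.fc1.weight")]] <- init_weight(D, hmlp)
      p[[paste0(pre, "mlp.fc1.bias")]] <- numeric(hmlp)
      p[[paste0(pre, "mlp.fc2.weight")]] <- init_weight(hmlp, D)
      p[[paste0(pre, "mlp.fc2.bias")]] <- numeric(D)
    }
    p[["norm.weight"]] <- rep(1, D)
    p[["norm.bias"]] <- numeric(D)

    p[["decoder.embed.weight"]] <- init_weight(D, Dd)
    p[["decoder.embed.bias"]] <- numeric(Dd)
    p[["decoder.mask_token"]] <- init_weight(1L, Dd)
    p[["decoder.pos_embed"]] <- sincos_positions(c(cfg$grid, cfg$grid), Dd)
    for (l in seq_len(dec_depth)) {
      pre <- sprintf("decoder.blocks.%d.", l)
      hmlp <- as.integer(round(Dd * cfg$mlp_ratio))
      p[[paste0(pre, "ln1.weight")]] <- rep(1, Dd)
      p[[paste0(pre, "ln1.bias")]] <- numeric(Dd)
      p[[paste0(pre, "attn.qkv.weight")]] <- init_weight(Dd, 3L * Dd)
      p[[paste0(pre, "attn.qkv.bias")]] <- numeric(3L * Dd)
      p[[paste0(pre, "attn.proj.weight")]] <- init_weight(Dd, Dd)
      p[[paste0(pre, "attn.proj.bias")]] <- numeric(Dd)
      p[[paste0(pre, "ln2.weight")]] <- rep(1, Dd)
      p[[paste0(pre, "ln2.bias")]] <- numeric(Dd)
      p[[paste0(pre, "mlp.fc1.weight")]] <- init_weight(Dd, hmlp)
      p[[paste0(pre, "mlp.fc1.bias")]] <- numeric(hmlp)
      p[[paste0(pre, "mlp.fc2.weight")]] <- init_weight(hmlp, Dd)
      p[[paste0(pre, "mlp.fc2.bias")]] <- numeric(Dd)
    }
    p[["decoder.norm.weight"]] <- rep(1, Dd)
    p[["decoder.norm.bias"]] <- numeric(Dd)
    p[["decoder.pred.weight"]] <- init_weight(Dd, P)
    p[["decoder.pred.bias"]] <- numeric(P)

    list(cfg = cfg,
         dec_cfg = list(depth = as.integer(dec_depth), dim = Dd,
                        heads = as.integer(dec_heads)),
         params = p,
         fixed_keys = c("pos_embed", "decoder.pos_embed"))
  })
}

#' Draw a random masking plan
#'
#' Masks `round(ratio * N)` patch indices, chosen uniformly without
#' replacement.
#'
#' @param N Token (patch) count, >= 2.
#' @param ratio Masked fraction, strictly between 0 and 1.
#' @param seed Optional integer; when given, the draw comes from a
#'   temporary RNG stream, otherwise the current stream is consumed.
#' @return A `mask_plan` list `(visible_idx, masked_idx, ratio)` with
#'   sorted, disjoint 1-based index vectors covering `1..N`.
#' @export
random_mask <- function(N, ratio = 0.75, seed = NULL) {
  if (ratio <= 0 || ratio >= 1) stopf("mask ratio must be in (0, 1)")
  if (N < 2L) stopf("need at least 2 tokens")
  draw <- function() {
    n_mask <- as.integer(round(ratio * N))
    n_mask <- min(max(n_mask, 1L), N - 1L)
    masked <- sort(sample.int(N, n_mask))
    structure(list(visible_idx = setdiff(seq_len(N), masked),
                   masked_idx = masked, ratio = ratio),
              class = "mask_plan")
  }
  if (is.null(seed)) draw() else with_seed(as.integer(seed), draw())
}

#' MAE forward pass
#'
#' @param model A model from [build_mae()].
#' @param patches `N x P` patch matrix (standardized pixel space), from
#'   [patchify()] applied to a [preprocess_eval()] image.
#' @param plan A [random_mask()] plan consistent with N.
#' @param keep_caches Keep intermediates for the backward pass.
#' @return List with `pred` (`N x P` per-patch pixel predictions) and
#'   `enc_out` (encoder outputs on the visible tokens, after the terminal
#'   layer norm); plus caches when requested.
#' @export
mae_forward <- function(model, patches, plan, keep_caches = FALSE) {
  cfg <- model$cfg
  N <- cfg$n_patches
  if (nrow(patches) != N) {
    stopf("plan/patch mismatch: %d patches but the encoder expects %d",
          nrow(patches), N)
  }
  if (length(plan$visible_idx) + length(plan$masked_idx) != N) {
    stopf("mask plan does not cover %d tokens", N)
  }
  p <- model$params
  vis <- plan$visible_idx

  tok <- linear_fwd(patches[vis, , drop = FALSE],
                    p[["patch_embed.weight"]], p[["patch_embed.bias"]])
  tok <- tok + p[["pos_embed"]][vis, , drop = FALSE]

  L <- cfg$depth
  caches_enc <- if (keep_caches) vector("list", L) else NULL
  x <- tok
  for (l in seq_len(L)) {
    bc <- block_fwd(x, p, sprintf("blocks.%d.", l), cfg$heads)
    if (keep_caches) caches_enc[[l]] <- bc
    x <- bc$out
  }
  lnf <- ln_fwd(x, p[["norm.weight"]], p[["norm.bias"]])
  enc_out <- lnf$y

  demb <- linear_fwd(enc_out, p[["decoder.embed.weight"]],
                     p[["decoder.embed.bias"]])
  Dd <- model$dec_cfg$dim
  full <- matrix(p[["decoder.mask_token"]], N, Dd, byrow = TRUE)
  full[vis, ] <- demb
  full <- full + p[["decoder.pos_embed"]]

  caches_dec <- if (keep_caches) vector("list", model$dec_cfg$depth) else NULL
  y <- full
  for (l in seq_len(model$dec_cfg$depth)) {
    bc <- block_fwd(y, p, sprintf("decoder.blocks.%d.", l), model$dec_cfg$heads)
    if (keep_caches) caches_dec[[l]] <- bc
    y <- bc$out
  }
  lnd <- ln_fwd(y, p[["decoder.norm.weight"]], p[["decoder.norm.bias"]])
  pred <- linear_fwd(lnd$y, p[["decoder.pred.weight"]], p[["decoder.pred.bias"]])

  res <- list(pred = pred, enc_out = enc_out)
  if (keep_caches) {
    res$caches <- list(patches = patches, plan = plan, tok = tok,
                       enc = caches_enc, lnf = lnf, demb = demb, full = full,
                       dec = caches_dec, lnd = lnd)
  }
  res
}

#' Masked-patch reconstruction loss
#'
#' Mean squared error over the masked patches only; predictions at visible
#' positions do not enter the loss.
#'
#' @param pred,target `N x P` matrices.
#' @param plan The [random_mask()] plan.
#' @return Scalar MSE.
#' @export
reconstruction_loss <- function(pred, target, plan) {
  if (!all(dim(pred) == dim(target))) stopf("pred/target shapes differ")
  if (length(plan$masked_idx) == 0L) stopf("mask plan has no masked patches")
  d <- pred[plan$masked_idx, , drop = FALSE] -
    target[plan$masked_idx, , drop = FALSE]
  mean(d^2)
}

# Full forward + backward, returning loss and named parameter gradients.
mae_loss_and_grads <- function(model, patches, plan, norm_pix = FALSE) {
  target <- patches
  if (norm_pix) {
    mu <- rowMeans(target)
    sd <- sqrt(rowMeans((target - mu)^2) + 1e-6)
    target <- (target - mu) / sd
  }
  fwd <- mae_forward(model, patches, plan, keep_caches = TRUE)
  loss <- reconstruction_loss(fwd$pred, target, plan)

  p <- model$params
  cfg <- model$cfg
  ca <- fwd$caches
  nm <- length(plan$masked_idx)
  P <- ncol(patches)

  dpred <- matrix(0, nrow(patches), P)
  dpred[plan$masked_idx, ] <-
    2 * (fwd$pred[plan$masked_idx, , drop = FALSE] -
           target[plan$masked_idx, , drop = FALSE]) / (nm * P)

  grads <- list()
  lb <- linear_bwd(ca$lnd$y, p[["decoder.pred.weight"]], dpred)
  grads[["decoder.pred.weight"]] <- lb$dW
  grads[["decoder.pred.bias"]] <- lb$db
  lnb <- ln_bwd(lb$dX, ca$lnd, p[["decoder.norm.weight"]])
  grads[["decoder.norm.weight"]] <- lnb$dg
  grads[["decoder.norm.bias"]] <- lnb$db
  dy <- lnb$dx
  for (l in rev(seq_len(model$dec_cfg$depth))) {
    bb <- block_bwd(dy, ca$dec[[l]], p, sprintf("decoder.blocks.%d.", l),
                    model$dec_cfg$heads)
    grads <- c(grads, bb$grads)
    dy <- bb$dx
  }
  # dy is d(full); mask-token rows share one parameter
  msk <- plan$masked_idx
  vis <- plan$visible_idx
  grads[["decoder.mask_token"]] <-
    matrix(colSums(dy[msk, , drop = FALSE]), 1L)
  ddemb <- dy[vis, , drop = FALSE]
  lb2 <- linear_bwd(ca$lnf$y, p[["decoder.embed.weight"]], ddemb)
  grads[["decoder.embed.weight"]] <- lb2$dW
  grads[["decoder.embed.bias"]] <- lb2$db

  lnb2 <- ln_bwd(lb2$dX, ca$lnf, p[["norm.weight"]])
  grads[["norm.weight"]] <- lnb2$dg
  grads[["norm.bias"]] <- lnb2$db
  dx <- lnb2$dx
  for (l in rev(seq_len(cfg$depth))) {
    bb <- block_bwd(dx, ca$enc[[l]], p, sprintf("blocks.%d.", l), cfg$heads)
    grads <- c(grads, bb$grads)
    dx <- bb$dx
  }
  lb3 <- linear_bwd(ca$patches[vis, , drop = FALSE],
                    p[["patch_embed.weight"]], dx)
  grads[["patch_embed.weight"]] <- lb3$dW
  grads[["patch_embed.bias"]] <- lb3$db

  list(loss = loss, grads = grads)
}

#' Transfer pre-trained MAE encoder weights into a classifier
#'
#' Copies the patch embedding, every encoder block, the terminal layer norm
#' and the positional table into the classifier by key name; decoder
#' parameters and the mask token are discarded; the SE gate and the loss
#' head keep their fresh initialization. Encoder shapes must match exactly.
#'
#' @param mae_model A (trained) model from [build_mae()], or any checkpoint
#'   list with `params`.
#' @param classifier A model from [build_classifier()].
#' @return The classifier with copied weights; the transfer report is
#'   attached as `attr(, "transfer_report")`, a list of `copied`, `ignored`
#'   and `initialized` key vectors.
#' @export
transfer_weights <- function(mae_model, classifier) {
  src <- mae_model$params
  dst <- classifier$params
  copied <- character()
  ignored <- character()
  for (key in names(src)) {
    if (startsWith(key, "decoder.")) {
      ignored <- c(ignored, key)
      next
    }
    if (!key %in% names(dst)) {
      stopf("encoder key '%s' has no counterpart in the classifier (depth/width mismatch?)", key)
    }
    sdim <- dim(src[[key]]) %||% length(src[[key]])
    ddim <- dim(dst[[key]]) %||% length(dst[[key]])
    if (!identical(as.integer(sdim), as.integer(ddim))) {
      stopf("shape mismatch for key '%s': MAE %s vs classifier %s", key,
            paste(sdim, collapse = "x"), paste(ddim, collapse = "x"))
    }
    dst[[key]] <- src[[key]]
    copied <- c(copied, key)
  }
  extra <- setdiff(
    grep("^blocks\\.", names(dst), value = TRUE),
    names(src)
  )
  if (length(extra) > 0L) {
    stopf("classifier encoder key '%s' missing from the MAE checkpoint (depth mismatch?)", extra[1])
  }
  classifier$params <- dst
  attr(classifier, "transfer_report") <- list(
    copied = copied, ignored = ignored,
    initialized = setdiff(names(dst), copied)
  )
  classifier
}

#' Render a 4-panel reconstruction composite
#'
#' Panels, left to right: original image; masked image (masked patches as a
#' constant mid-gray fill); raw reconstruction; reconstruction with the
#' true visible patches pasted back in.
#'
#' @param image `S x S x 3` array in `[0, 1]` display space.
#' @param plan The [random_mask()] plan.
#' @param pred `N x P` predicted patches in the same display space.
#' @param patch_size Patch side length.
#' @return `S x (4 S) x 3` array in `[0, 1]`, writable with `png::writePNG`.
#' @export
render_reconstruction <- function(image, plan, pred, patch_size) {
  S <- dim(image)[1]
  patches <- patchify(image, patch_size)
  masked_img <- patches
  masked_img[plan$masked_idx, ] <- 0.5
  recon <- clamp(pred, 0, 1)
  combo <- recon
  combo[plan$visible_idx, ] <- patches[plan$visible_idx, ]
  panels <- list(
    image,
    unpatchify(masked_img, patch_size, S),
    unpatchify(recon, patch_size, S),
    unpatchify(combo, patch_size, S)
  )
  out <- array(0, dim = c(S, 4L * S, 3L))
  for (i in 1:4) out[, ((i - 1L) * S + 1L):(i * S), ] <- panels[[i]]
  out
}
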