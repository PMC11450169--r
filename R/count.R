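# Architecture accounting: parameter and multiply-accumulate (MAC) counts.

#' Count model parameters
#'
#' Sums the sizes of every array in the model's parameter map. The fixed
#' sine-cosine positional table is stored in the map and therefore counted,
#' matching the common convention of registering it as a (frozen) model
#' parameter; `include_head = FALSE` drops the classification head (linear
#' head or sub-center prototype bank) from the count.
#'
#' @param model A model from [build_classifier()] or [build_mae()].
#' @param include_head Include the loss head's parameters.
#' @return Integer-valued double: total number of scalars.
#' @export
count_params <- function(model, include_head = TRUE) {
  keys <- names(model$params)
  if (!include_head) {
    keys <- setdiff(keys, c("subcenters", "head.weight", "head.bias"))
  }
  sum(vapply(model$params[keys], length, integer(1)))
}

#' Count forward-pass multiply-accumulates
#'
#' Analytic MAC count for one `image_size x image_size x 3` input under the
#' following convention: every affine map contributes
#' `tokens * (fan_in * fan_out + fan_out)` MACs (the bias add counted as
#' one MAC per output element) and each layer-norm application one MAC per
#' element; the attention score and value matrix products, softmax, GELU,
#' residual adds, token pooling and the loss head are excluded. Under this
#' convention the ViT-Base/16 encoder costs 16.87 GMACs with a class token
#' (197 tokens) and 16.78 GMACs without one (196 tokens).
#'
#' @param model A model from [build_classifier()].
#' @param input_size Input side length; defaults to the configured size.
#' @return Total MACs (double).
#' @export
count_flops <- function(model, input_size = model$cfg$image_size) {
  cfg <- model$cfg
  if (input_size %% cfg$patch_size != 0L) {
    stopf("input_size must be divisible by patch_size")
  }
  g <- input_size %/% cfg$patch_size
  N <- g * g
  ntok <- N + as.integer(cfg$use_cls_token)
  D <- cfg$dim
  H <- round(D * cfg$mlp_ratio)
  P <- cfg$patch_size^2 * 3

  lin <- function(n, fi, fo) n * (fi * fo + fo)

  total <- lin(N, P, D)                     # patch embedding
  per_block <- lin(ntok, D, 3 * D) +        # qkv projection
    lin(ntok, D, D) +                       # attention output projection
    lin(ntok, D, H) + lin(ntok, H, D) +     # MLP
    2 * ntok * D                            # two layer norms
  total <- total + cfg$depth * per_block
  total <- total + ntok * D                 # terminal layer norm
  if (isTRUE(model$fusion)) {
    L <- cfg$depth
    rh <- max(1L, L %/% 4L)
    total <- total + lin(1, L, rh) + lin(1, rh, L)   # SE excitation
  }
  total
}
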