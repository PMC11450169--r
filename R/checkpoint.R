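# Checkpoint I/O.
#
# A checkpoint is the model list itself: `cfg` (and `dec_cfg` for MAE
# models), `params` and `fixed_keys`. The parameter-map key schema, stable
# across versions and matched by name (never by position) at transfer:
#
#   patch_embed.weight            (p*p*3) x D     patch projection
#   patch_embed.bias              D
#   pos_embed                     N x D           positional table (fixed
#                                                 sine-cosine unless the
#                                                 config uses a class token,
#                                                 then learned, (N+1) x D)
#   cls_token                     1 x D           vanilla configs only
#   blocks.<l>.ln1.weight/.bias   D               l = 1..depth
#   blocks.<l>.attn.qkv.weight    D x 3D
#   blocks.<l>.attn.qkv.bias      3D
#   blocks.<l>.attn.proj.weight   D x D
#   blocks.<l>.attn.proj.bias     D
#   blocks.<l>.ln2.weight/.bias   D
#   blocks.<l>.mlp.fc1.weight     D x (mlp_ratio*D)
#   blocks.<l>.mlp.fc1.bias       mlp_ratio*D
#   blocks.<l>.mlp.fc2.weight     (mlp_ratio*D) x D
#   blocks.<l>.mlp.fc2.bias       D
#   norm.weight/.bias             D               terminal layer norm
#   se.fc1.weight                 L x r_h         SE gate (fusion models)
#   se.fc1.bias                   r_h
#   se.fc2.weight                 r_h x L
#   se.fc2.bias                   L
#   subcenters                    (C*K) x D       dsa head prototype bank,
#                                                 class-major rows
#   head.weight / head.bias       D x C / C       linear head
#   decoder.*                     MAE decoder; never transferred downstream
#     decoder.embed.weight/.bias, decoder.mask_token, decoder.pos_embed,
#     decoder.blocks.<l>.*, decoder.norm.*, decoder.pred.weight/.bias

#' Save a model checkpoint
#' @param model A model list from [build_classifier()] or [build_mae()].
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path File written by [save_checkpoint()].
#' @return The model list.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
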