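# Run configuration: one YAML file with sections
# {data, augment, backbone, fusion, loss, mae, schedule, train}; any key can
# be omitted (defaults below) or overridden programmatically / by CLI flags.

#' Default run configuration
#'
#' The full-scale defaults mirror the reference training setup: ViT-Base/16
#' backbone without class token, SE layer fusion, dynamic-margin sub-center
#' ArcFace loss (s = 64, K = 3, a = 0.5, b = 0.05, lambda = -0.5), 75%
#' masking for MAE, AdamW at base lr 6.25e-5 with 20 warmup epochs, cosine
#' annealing to 0 over 400 epochs, weight decay 5e-4.
#'
#' @return Nested list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    data = list(root = NULL, image_size_range = c(64L, 256L), seed = 1L),
    augment = list(target_size = 224L, n_rand_ops = 2L, magnitude = 9L,
                   magnitude_bins = 10L, erase_prob = 0.25,
                   erase_area = c(0.02, 0.33), hflip_prob = 0.5),
    backbone = list(image_size = 224L, patch_size = 16L, depth = 12L,
                    dim = 768L, heads = 12L, mlp_ratio = 4,
                    use_cls_token = FALSE),
    fusion = TRUE,
    loss = list(type = "dynamic-subcenter", s = 64, K = 3L, a = 0.5,
                b = 0.05, lambda = -0.5),
    mae = list(mask_ratio = 0.75, dec_depth = 8L, dec_dim = 512L,
               dec_heads = 16L, steps = 200L, batch_size = 16L,
               norm_pix = TRUE),
    schedule = list(base_lr = 6.25e-5, warmup_epochs = 20L,
                    total_epochs = 400L, weight_decay = 5e-4, min_lr = 0),
    train = list(epochs = 400L, batch_size = 64L)
  )
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Read a run configuration file
#'
#' Loads a YAML configuration and merges it over [default_run_config()];
#' keys in `overrides` (e.g. parsed CLI flags) take final precedence.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides Nested list merged last.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    cfg <- modify_list(cfg, yaml::read_yaml(path))
  }
  modify_list(cfg, overrides)
}

#' Instantiate the typed sub-configurations of a run configuration
#' @param cfg List from [read_run_config()].
#' @return List with `backbone` ([backbone_config()]), `augment`
#'   ([augment_config()]), `schedule` ([schedule_config()]) and `loss`
#'   ([loss_config()] plus the margin/ablation keys).
#' @export
build_configs <- function(cfg) {
  b <- cfg$backbone
  list(
    backbone = backbone_config(b$image_size, b$patch_size, b$depth, b$dim,
                               b$heads, b$mlp_ratio, b$use_cls_token),
    augment = do.call(augment_config, cfg$augment),
    schedule = do.call(schedule_config, cfg$schedule),
    loss = loss_config(s = cfg$loss$s)
  )
}
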