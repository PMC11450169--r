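# Shared toy fixtures, built in code at test time.

# 32x32 input, 8px patches (16 tokens), width 32, 2 blocks: small enough for
# exhaustive numerical checks, large enough to learn the synthetic classes.
toy_cfg <- function(use_cls_token = FALSE) {
  backbone_config(image_size = 32L, patch_size = 8L, depth = 2L, dim = 32L,
                  heads = 4L, mlp_ratio = 2, use_cls_token = use_cls_token)
}

# Four well-separated synthetic cell classes (blue lymphoid, orange
# eosinophilic, magenta segmented, green monocytoid).
toy_specs4 <- function(n = 50L) {
  list(
    cell_class_spec("lymph", n, hue = 220, nucleus_lobes = 1L,
                    nucleus_fraction = 0.6, granularity = 2),
    cell_class_spec("eos", n, hue = 20, nucleus_lobes = 2L,
                    nucleus_fraction = 0.35, granularity = 10),
    cell_class_spec("neut", n, hue = 300, nucleus_lobes = 4L,
                    nucleus_fraction = 0.35, granularity = 4),
    cell_class_spec("mono", n, hue = 120, nucleus_lobes = 1L,
                    nucleus_fraction = 0.45, granularity = 3)
  )
}

toy_dataset4 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(toy_specs4(), image_size_range = c(48L, 96L),
                                 seed = 11L)
    }
    cache
  }
})

rand_image <- function(size, seed, lo = 0, hi = 255) {
  withr::with_seed(seed,
    array(runif(size * size * 3, lo, hi), dim = c(size, size, 3)))
}

# standardized-space random image for direct backbone inputs
rand_std_image <- function(size, seed) {
  withr::with_seed(seed,
    array(runif(size * size * 3, -1, 1), dim = c(size, size, 3)))
}
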