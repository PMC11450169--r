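test_that("patch counts follow the grid and indivisible sizes are rejected", {
  img224 <- array(0.5, dim = c(224, 224, 3))
  expect_equal(nrow(patchify(img224, 16L)), 196L)

  cfg <- backbone_config(32L, 16L, 1L, 8L, 2L, 2)
  m <- build_classifier(cfg, 2L, head = "linear", fusion = FALSE, seed = 1)
  tok <- patchify_embed(array(0.1, dim = c(32, 32, 3)), m)
  expect_equal(dim(tok), c(4L, 8L))

  expect_error(backbone_config(225L, 16L, 1L, 8L, 2L), "divisible")
})

test_that("patchify and unpatchify are exact inverses", {
  img <- rand_std_image(32, seed = 2)
  p <- patchify(img, 8L)
  expect_equal(dim(p), c(16L, 192L))
  expect_identical(unpatchify(p, 8L, 32L), img)
})

test_that("sine-cosine positions are bounded, anchored at the origin, and distinct", {
  pe <- sincos_positions(c(14L, 14L), 768L)
  expect_equal(dim(pe), c(196L, 768L))
  expect_true(all(pe >= -1 & pe <= 1))

  q <- 768L / 4L
  sin_cols <- c(seq_len(q), 2 * q + seq_len(q))
  cos_cols <- c(q + seq_len(q), 3 * q + seq_len(q))
  expect_equal(unname(pe[1, sin_cols]), rep(0, 2 * q))
  expect_equal(unname(pe[1, cos_cols]), rep(1, 2 * q))

  expect_equal(nrow(unique(round(pe, 10))), 196L)
  expect_error(sincos_positions(c(4L, 4L), 6L), "divisible by 4")
})

test_that("encoder_forward returns one tap per block at any depth", {
  img <- rand_std_image(32, seed = 3)
  deep <- build_classifier(backbone_config(32L, 8L, 12L, 16L, 4L, 2), 2L,
                           seed = 4)
  enc <- encoder_forward(patchify_embed(img, deep), deep)
  expect_length(enc$outputs, 12L)
  expect_true(all(vapply(enc$outputs, function(o) all(dim(o) == c(16L, 16L)),
                         logical(1))))

  toy <- build_classifier(toy_cfg(), 4L, seed = 5)
  expect_length(encoder_forward(patchify_embed(img, toy), toy)$outputs, 2L)
})

test_that("zeroed residual branches make every block the identity", {
  model <- build_classifier(toy_cfg(), 4L, seed = 6)
  for (l in 1:2) {
    pre <- sprintf("blocks.%d.", l)
    model$params[[paste0(pre, "attn.proj.weight")]][] <- 0
    model$params[[paste0(pre, "attn.proj.bias")]][] <- 0
    model$params[[paste0(pre, "mlp.fc2.weight")]][] <- 0
    model$params[[paste0(pre, "mlp.fc2.bias")]][] <- 0
  }
  tok <- patchify_embed(rand_std_image(32, seed = 7), model)
  enc <- encoder_forward(tok, model)
  expect_equal(enc$outputs[[1]], tok, tolerance = 1e-12)
  expect_equal(enc$outputs[[2]], tok, tolerance = 1e-12)
})

test_that("pool_layers averages tokens layer by layer", {
  outs <- list(matrix(1:12, 3, 4), matrix(13:24, 3, 4))
  stack <- pool_layers(outs)
  expect_equal(dim(stack), c(2L, 4L))
  expect_equal(stack[1, ], colMeans(outs[[1]]))

  const <- matrix(7, 5, 3)
  expect_equal(pool_layers(list(const))[1, ], rep(7, 3))

  single <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(pool_layers(list(single))[1, ], c(1, 2, 3))
})

test_that("se_fuse matches the brute-force weighted row sum", {
  stack <- withr::with_seed(8, matrix(rnorm(12), 3, 4))
  gates <- c(0.2, 0.7, 0.9)
  # excitation forced to produce exactly `gates`: zero squeeze path, bias
  # set to the logit of each gate
  se <- list(fc1.weight = matrix(0, 3, 1), fc1.bias = 0,
             fc2.weight = matrix(0, 1, 3), fc2.bias = log(gates / (1 - gates)))
  out <- se_fuse(stack, se)
  brute <- rep(0, 4)
  for (l in 1:3) brute <- brute + gates[l] * stack[l, ]
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("unit and one-hot gates reduce se_fuse to sums and row selection", {
  stack <- withr::with_seed(9, matrix(rnorm(20), 4, 5))
  se_ones <- list(fc1.weight = matrix(0, 4, 1), fc1.bias = 0,
                  fc2.weight = matrix(0, 1, 4), fc2.bias = rep(1e9, 4))
  expect_equal(se_fuse(stack, se_ones), colSums(stack), tolerance = 1e-9)

  onehot_bias <- rep(-1e9, 4); onehot_bias[3] <- 1e9
  se_hot <- list(fc1.weight = matrix(0, 4, 1), fc1.bias = 0,
                 fc2.weight = matrix(0, 1, 4), fc2.bias = onehot_bias)
  expect_equal(se_fuse(stack, se_hot), stack[3, ], tolerance = 1e-9)
})

test_that("se_fuse is permutation-covariant in the feature axis", {
  model <- build_classifier(toy_cfg(), 4L, seed = 10)
  stack <- withr::with_seed(11, matrix(rnorm(2 * 32), 2, 32))
  se <- se_params(model)
  perm <- withr::with_seed(12, sample(32))
  expect_equal(se_fuse(stack[, perm], se), se_fuse(stack, se)[perm])
})

test_that("freshly built models gate every layer at exactly one half", {
  model <- build_classifier(toy_cfg(), 4L, seed = 13)
  f <- forward_features(model, rand_std_image(32, seed = 14))
  expect_identical(f$gates, rep(0.5, 2))
  expect_true(all(f$gates > 0 & f$gates < 1))
})

test_that("fusion taps do not perturb the underlying forward pass", {
  model <- build_classifier(toy_cfg(), 4L, seed = 15)
  tok <- patchify_embed(rand_std_image(32, seed = 16), model)
  with_caches <- encoder_forward(tok, model, keep_caches = TRUE)
  without <- encoder_forward(tok, model, keep_caches = FALSE)
  expect_identical(with_caches$outputs[[2]], without$outputs[[2]])
})
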