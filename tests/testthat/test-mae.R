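toy_mae <- function(seed = 4L) {
  build_mae(toy_cfg(), dec_depth = 1L, dec_dim = 16L, dec_heads = 4L,
            seed = seed)
}

test_that("mask plans have the exact masked count and partition the indices", {
  p <- random_mask(196L, 0.75, seed = 1)
  expect_length(p$masked_idx, 147L)
  expect_length(p$visible_idx, 49L)
  expect_identical(sort(c(p$masked_idx, p$visible_idx)), 1:196)

  p4 <- random_mask(4L, 0.5, seed = 2)
  expect_length(p4$masked_idx, 2L)
  expect_length(p4$visible_idx, 2L)

  expect_identical(random_mask(16L, 0.75, seed = 3),
                   random_mask(16L, 0.75, seed = 3))
  expect_error(random_mask(16L, 0), "ratio")
  expect_error(random_mask(16L, 1), "ratio")
  expect_error(random_mask(1L, 0.5), "at least 2")
})

test_that("masking is uniform over positions", {
  N <- 196L
  hits <- numeric(N)
  withr::with_seed(5, {
    for (i in 1:10000) {
      p <- random_mask(N, 0.75)
      hits[p$masked_idx] <- hits[p$masked_idx] + 1
    }
  })
  freq <- hits / 10000
  expect_true(all(abs(freq - 0.75) < 0.03))
})

test_that("the forward pass reconstructs a full-length patch sequence", {
  mae <- toy_mae()
  img <- rand_std_image(32, seed = 6)
  patches <- patchify(img, 8L)
  for (ratio in c(0.25, 0.5, 0.75)) {
    plan <- random_mask(16L, ratio, seed = 7)
    out <- mae_forward(mae, patches, plan)
    expect_equal(dim(out$pred), c(16L, 192L))
    expect_true(all(is.finite(out$pred)))
  }
  plan <- random_mask(16L, 0.75, seed = 8)
  expect_identical(mae_forward(mae, patches, plan)$pred,
                   mae_forward(mae, patches, plan)$pred)
  bad_plan <- random_mask(4L, 0.5, seed = 9)
  expect_error(mae_forward(mae, patches, bad_plan), "plan")
})

test_that("the reconstruction loss sees masked patches only", {
  plan <- list(visible_idx = 1L, masked_idx = 2L, ratio = 0.5)
  target <- matrix(rnorm(2 * 6), 2, 6)
  pred <- target
  pred[1, ] <- 999  # garbage at the visible position
  expect_equal(reconstruction_loss(pred, target, plan), 0)

  # perturbing visible-position targets changes nothing
  target2 <- target
  target2[1, ] <- target2[1, ] + rnorm(6)
  expect_equal(reconstruction_loss(pred, target, plan),
               reconstruction_loss(pred, target2, plan))

  # hand-built case: all-ones error on the single masked patch
  pred2 <- target
  pred2[2, ] <- target[2, ] + 1
  expect_equal(reconstruction_loss(pred2, target, plan), 1)

  empty <- list(visible_idx = 1:2, masked_idx = integer(), ratio = 0)
  expect_error(reconstruction_loss(pred, target, empty), "no masked")
})

test_that("loss gradients vanish identically at visible positions", {
  mae <- toy_mae()
  img <- rand_std_image(32, seed = 10)
  patches <- patchify(img, 8L)
  plan <- random_mask(16L, 0.75, seed = 11)
  f0 <- mae_forward(mae, patches, plan)
  base <- reconstruction_loss(f0$pred, patches, plan)
  # any perturbation confined to visible rows leaves the loss bit-identical
  pred2 <- f0$pred
  pred2[plan$visible_idx, ] <- pred2[plan$visible_idx, ] + 100
  expect_identical(reconstruction_loss(pred2, patches, plan), base)
})

test_that("transferred encoders are forward-equivalent on full sequences", {
  mae <- toy_mae(seed = 12)
  clf <- build_classifier(toy_cfg(), 4L, 3L, head = "dsa", seed = 13)
  clf2 <- transfer_weights(mae, clf)
  rep <- attr(clf2, "transfer_report")
  expect_true(all(startsWith(rep$ignored, "decoder.")))
  expect_true(all(grepl("^(se\\.|subcenters)", rep$initialized)))

  img <- rand_std_image(32, seed = 14)
  tok <- patchify_embed(img, clf2)
  out_clf <- encoder_forward(tok, clf2)$outputs

  # the MAE encoder, run through the same exported surface
  mae_as_backbone <- list(cfg = mae$cfg, params = mae$params,
                          fusion = FALSE, head = "linear")
  out_mae <- encoder_forward(tok, mae_as_backbone)$outputs
  for (l in seq_along(out_clf)) {
    expect_equal(out_clf[[l]], out_mae[[l]], tolerance = 1e-5)
  }
})

test_that("incompatible encoder shapes fail transfer with the offending key", {
  mae <- toy_mae()
  deep_cfg <- backbone_config(32L, 8L, 4L, 32L, 4L, 2)
  clf_deep <- build_classifier(deep_cfg, 4L, seed = 15)
  expect_error(transfer_weights(mae, clf_deep), "blocks")

  wide_cfg <- backbone_config(32L, 8L, 2L, 64L, 4L, 2)
  clf_wide <- build_classifier(wide_cfg, 4L, seed = 16)
  expect_error(transfer_weights(mae, clf_wide), "mismatch")
})

test_that("reconstruction composites tile four panels with visible patches pasted", {
  img <- rand_image(32, seed = 17) / 255
  plan <- random_mask(16L, 0.75, seed = 18)
  pred <- matrix(runif(16 * 192), 16, 192)
  comp <- render_reconstruction(img, plan, pred, 8L)
  expect_equal(dim(comp), c(32L, 128L, 3L))

  panel1 <- comp[, 1:32, ]
  panel2 <- comp[, 33:64, ]
  panel4 <- comp[, 97:128, ]
  expect_equal(panel1, img)
  p4 <- patchify(panel4, 8L)
  p1 <- patchify(panel1, 8L)
  expect_equal(p4[plan$visible_idx, ], p1[plan$visible_idx, ])
  p2 <- patchify(panel2, 8L)
  expect_true(all(p2[plan$masked_idx, ] == 0.5))
})
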