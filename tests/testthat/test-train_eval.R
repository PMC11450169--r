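test_that("the schedule ramps linearly then anneals with a cosine", {
  cfg <- schedule_config(base_lr = 6.25e-5, warmup_epochs = 20L,
                         total_epochs = 420L)
  expect_equal(lr_at(0, cfg), 6.25e-5 / 20)
  expect_equal(lr_at(20, cfg), 6.25e-5)
  # halfway through the annealing phase: exact midpoint of base and min
  expect_equal(lr_at(20 + 200, cfg), 6.25e-5 / 2, tolerance = 1e-10)
  expect_error(lr_at(-1, cfg), "out of range")
  expect_error(lr_at(420, cfg), "out of range")
})

test_that("the schedule is continuous at the boundary and non-increasing after it", {
  cfg <- schedule_config(base_lr = 1e-3, warmup_epochs = 5L,
                         total_epochs = 50L, min_lr = 1e-5)
  lrs <- vapply(0:49, lr_at, numeric(1), cfg = cfg)
  expect_lt(abs(lrs[6] - lrs[5]), abs(lrs[5] - lrs[4]) + 1e-12)  # no jump
  expect_true(all(diff(lrs[6:50]) <= 0))
  expect_gte(lrs[50], 1e-5)
  expect_lt(lrs[50], 2e-5)   # closes on min_lr by the final epoch
  expect_error(schedule_config(warmup_epochs = 10L, total_epochs = 10L))
})

test_that("classification metrics match hand-computed values", {
  # 2-class case: TP = 3, FP = 1, FN = 2, TN = 4 for class 1
  truth <- c(rep(1L, 5), rep(2L, 5))
  preds <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 1L)
  rep2 <- classification_report(truth, preds, 2L)
  expect_equal(rep2$precision[1], 75)
  expect_equal(rep2$recall[1], 60)
  expect_equal(rep2$f1[1], 200 / 3, tolerance = 1e-10)
  expect_equal(sum(rep2$confusion), 10L)
  expect_equal(rowSums(rep2$confusion), c(5, 5), ignore_attr = TRUE)

  perfect <- classification_report(truth, truth, 2L)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, c(100, 100))
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))
})

test_that("accuracy equals the confusion-matrix trace over total for random inputs", {
  withr::with_seed(31, {
    for (i in 1:10) {
      C <- sample(2:6, 1)
      n <- sample(10:60, 1)
      truth <- sample(C, n, replace = TRUE)
      preds <- sample(C, n, replace = TRUE)
      r <- classification_report(truth, preds, C)
      expect_equal(r$accuracy, sum(diag(r$confusion)) / n * 100)
      expect_equal(sum(r$confusion), n)
    }
  })
})

test_that("absent classes are flagged and scored zero recall", {
  r <- classification_report(c(1L, 1L, 2L), c(1L, 2L, 2L), 3L)
  expect_equal(r$undefined_recall, 3L)
  expect_equal(r$recall[3], 0)
})

test_that("embedding export is one row per record with the backbone width", {
  model <- build_classifier(toy_cfg(), 4L, 3L, head = "dsa", seed = 20)
  recs <- toy_dataset4()[1:6]
  df <- export_embeddings(model, recs)
  expect_equal(dim(df), c(6L, 33L))
  expect_equal(df$label, vapply(recs, `[[`, integer(1), "label"))

  dup <- export_embeddings(model, list(recs[[1]], recs[[1]]))
  expect_equal(unlist(dup[1, ]), unlist(dup[2, ]), ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".tsv")
  export_embeddings(model, recs[1:2], path = path)
  back <- utils::read.delim(path)
  expect_equal(dim(back), c(2L, 33L))
})

test_that("training is deterministic given a seed and validates its inputs", {
  recs <- toy_dataset4()
  train_all <- records_split(recs, "train")
  labs <- vapply(train_all, `[[`, integer(1), "label")
  tr <- train_all[unlist(lapply(1:4, function(c) which(labs == c)[1:6]))]
  va <- records_split(recs, "val")[1:8]
  model <- build_classifier(toy_cfg(), 4L, 3L, head = "dsa", seed = 21)
  sched <- schedule_config(base_lr = 1e-3, warmup_epochs = 1L,
                           total_epochs = 2L, weight_decay = 5e-4)
  run <- function() {
    train_classifier(model, tr, va, loss_type = "dynamic-subcenter",
                     epochs = 1L, batch_size = 12L, schedule = sched,
                     augment = augment_config(target_size = 32L), seed = 22)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$log$loss, r2$log$loss)

  single <- Filter(function(r) r$label == 1L, tr)
  expect_error(
    train_classifier(model, single, va, epochs = 1L, schedule = sched,
                     augment = augment_config(target_size = 32L)),
    "at least 2 classes"
  )
  expect_error(
    train_classifier(build_classifier(toy_cfg(), 4L, head = "linear",
                                      fusion = TRUE, seed = 1),
                     tr, va, loss_type = "dynamic-subcenter", epochs = 1L,
                     schedule = sched,
                     augment = augment_config(target_size = 32L)),
    "requires a model"
  )
  expect_warning(
    train_classifier(model, tr, list(), epochs = 1L, batch_size = 12L,
                     schedule = sched,
                     augment = augment_config(target_size = 32L), seed = 22),
    "validation split is empty"
  )
})

test_that("the loss switch changes only the head, never the backbone", {
  m_dsa <- build_classifier(toy_cfg(), 4L, 3L, head = "dsa", seed = 23)
  m_ce <- build_classifier(toy_cfg(), 4L, head = "linear", fusion = TRUE,
                           seed = 23)
  expect_equal(count_params(m_dsa, include_head = FALSE),
               count_params(m_ce, include_head = FALSE))
  backbone_keys <- setdiff(names(m_dsa$params),
                           c("subcenters", "head.weight", "head.bias"))
  expect_identical(m_dsa$params[backbone_keys], m_ce$params[backbone_keys])
})

test_that("checkpoints round-trip through disk", {
  model <- build_classifier(toy_cfg(), 4L, 3L, head = "dsa", seed = 24)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$cfg, model$cfg)
})
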