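test_that("make_split partitions subjects by the requested proportions, reproducibly", {
  ids <- sprintf("P%03d", 1:602)
  sp <- make_split(ids, c(482, 48, 72) / 602, seed = 7)
  expect_length(sp$train, 482)
  expect_length(sp$validation, 48)
  expect_length(sp$test, 72)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$validation, sp$test), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_identical(sp, make_split(ids, c(482, 48, 72) / 602, seed = 7))
  expect_false(identical(sp, make_split(ids, c(482, 48, 72) / 602, seed = 8)))

  all_train <- make_split(letters[1:10], c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 10)
  expect_length(all_train$test, 0)
  expect_error(make_split(c("a", "b"), c(0.4, 0.3, 0.3)),
               class = "somnostage_input_error")
  expect_error(make_split(ids, c(0.5, 0.5, 0.5)), class = "somnostage_config_error")
})

test_that("training on separable synthetic features reaches high validation kappa for every variant", {
  cohort <- make_feature_cohort(10, 80, seed = 3)
  tr <- cohort[1:8]; va <- cohort[9:10]
  for (v in c("conv", "recurrent", "conv_recurrent")) {
    m <- train_stager(tr, stager_config(variant = v, seed = 4), va)
    expect_gte(m$validation_kappa, 0.7)
    # training loss decreases over the run
    expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
    # capacity check: near-perfect recall of a training subject
    pred <- predict_hypnogram(m, tr[[1]]$features)
    expect_gte(mean(as.character(pred) == as.character(tr[[1]]$labels)), 0.9)
  }
})

test_that("training is deterministic for a fixed seed and errors on degenerate labels", {
  cohort <- make_feature_cohort(4, 40, seed = 5)
  cfg <- stager_config(variant = "conv", seed = 11, train_epochs = 30)
  m1 <- train_stager(cohort[1:3], cfg, cohort[4])
  m2 <- train_stager(cohort[1:3], cfg, cohort[4])
  expect_identical(m1$validation_kappa, m2$validation_kappa)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_hypnogram(m1, cohort[[4]]$features),
                   predict_hypnogram(m2, cohort[[4]]$features))

  single <- cohort[1:2]
  for (i in seq_along(single)) {
    single[[i]]$labels <- hypnogram(rep("N2", length(single[[i]]$labels)))
  }
  expect_error(train_stager(single, cfg), class = "somnostage_input_error")
})

test_that("prediction enforces the layout fingerprint and preserves epoch count", {
  cohort <- make_feature_cohort(3, 40, seed = 9)
  m <- train_stager(cohort[1:2], stager_config(variant = "conv", seed = 2,
                                               train_epochs = 30))
  pred <- predict_hypnogram(m, cohort[[3]]$features)
  expect_length(pred, nrow(cohort[[3]]$features))
  bad <- cohort[[3]]$features
  colnames(bad)[1] <- "renamed"
  expect_error(predict_hypnogram(m, bad), class = "somnostage_config_error")
  empty <- cohort[[3]]$features[0, , drop = FALSE]
  expect_length(predict_hypnogram(m, empty), 0)
})

test_that("model bundles round-trip through disk with identical predictions", {
  cohort <- make_feature_cohort(3, 40, seed = 13)
  m <- train_stager(cohort[1:2], stager_config(variant = "conv_recurrent", seed = 2,
                                               train_epochs = 30))
  path <- withr::local_tempfile(fileext = ".rds")
  save_stager(m, path)
  m2 <- load_stager(path)
  expect_identical(m$params, m2$params)
  expect_identical(predict_hypnogram(m, cohort[[3]]$features),
                   predict_hypnogram(m2, cohort[[3]]$features))
})

test_that("best-model selection maximises validation kappa with size then order tie-breaks", {
  fake <- function(kappa, np) structure(list(validation_kappa = kappa, n_params = np),
                                        class = "trained_stager")
  a <- fake(0.70, 100); b <- fake(0.84, 5000); c_ <- fake(0.80, 10)
  expect_identical(select_best_model(list(a, b, c_)), b)
  expect_identical(select_best_model(list(a)), a)
  tie_small <- fake(0.80, 1e3); tie_big <- fake(0.80, 1e4)
  expect_identical(select_best_model(list(tie_big, tie_small)), tie_small)
  first <- fake(0.8, 10); second <- fake(0.8, 10)
  expect_identical(select_best_model(list(first, second)), first)
  expect_error(select_best_model(list()), class = "somnostage_input_error")
})

test_that("continuity smoothing relabels only isolated N1 epochs inside N2/R runs, idempotently", {
  expect_identical(as.character(apply_continuity_smoothing(hypnogram(c("N2", "N1", "N2")))),
                   c("N2", "N2", "N2"))
  expect_identical(as.character(apply_continuity_smoothing(hypnogram(c("R", "N1", "R")))),
                   c("R", "R", "R"))
  h <- hypnogram(c("N2", "N1", "N1", "N2"))
  expect_identical(as.character(apply_continuity_smoothing(h)), c("N2", "N1", "N1", "N2"))
  h2 <- hypnogram(c("W", "N1", "W", "N2", "N1", "R"))
  expect_identical(as.character(apply_continuity_smoothing(h2)), as.character(h2))
  set.seed(3)
  h3 <- generate_hypnogram(epochs = 300, seed = 17)
  once <- apply_continuity_smoothing(h3)
  expect_identical(as.character(apply_continuity_smoothing(once)), as.character(once))
})
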