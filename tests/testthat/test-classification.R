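# Sub-model training, dual-model scoring, the cascade, and serialization.

separable_blobs <- function(n = 50L, shift = 6) {
  withr::with_seed(21, {
    x <- rbind(matrix(stats::rnorm(n * 4), ncol = 4),
               matrix(stats::rnorm(n * 4, mean = shift), ncol = 4))
  })
  colnames(x) <- paste0("f", 1:4)
  y <- factor(rep(c("negative", "positive"), each = n),
              levels = c("negative", "positive"))
  list(x = x, y = y)
}

test_that("a sub-model separates well-separated blobs and is deterministic", {
  blobs <- separable_blobs()
  sm <- train_submodel(blobs$x, blobs$y, small_hyper())
  p <- predict_submodel(sm, blobs$x)
  expect_true(all(p >= 0 & p <= 1))
  predicted <- ifelse(p >= 0.5, "positive", "negative")
  expect_identical(predicted, as.character(blobs$y))

  sm2 <- train_submodel(blobs$x, blobs$y, small_hyper())
  expect_identical(predict_submodel(sm2, blobs$x), p)

  # on overlapping classes, the seed changes the forest and its output
  close_blobs <- separable_blobs(shift = 1)
  pa <- predict_submodel(train_submodel(close_blobs$x, close_blobs$y,
                                        small_hyper()), close_blobs$x)
  pb <- predict_submodel(
    train_submodel(close_blobs$x, close_blobs$y,
                   rf_hyperparameters(n_trees = 50L, seed = 99L)),
    close_blobs$x)
  expect_false(identical(pa, pb))
})

test_that("degenerate training inputs are rejected", {
  blobs <- separable_blobs(n = 10L)
  expect_error(train_submodel(blobs$x, factor(rep("positive", 20))),
               "single class")
  xnan <- blobs$x
  xnan[3, 2] <- NaN
  expect_error(train_submodel(xnan, blobs$y), "missing or non-finite")
  sm <- train_submodel(blobs$x, blobs$y, small_hyper())
  expect_error(predict_submodel(sm, blobs$x[, 1:3, drop = FALSE]),
               "width 3.*width 4")
})

test_that("dual-model sub-models differ only via TF-TF row orientation", {
  sd <- small_dataset(n_per_class = 15L, n_indices = 5L)
  model <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  expect_identical(model$sub_forward$orientation, "forward")
  expect_identical(model$sub_reverse$orientation, "reversed")
  expect_identical(model$label_counts,
                   list(OTHER = 15L, TCOF = 15L, TF = 15L))

  # with no TF-TF pairs and shared seeds the two sub-models coincide
  no_tftf <- sd$pairs[sd$pairs$label != "TF", ]
  m0 <- train_dual_model(no_tftf, sd$features, "model1", small_hyper(),
                         seeds = c(5L, 5L))
  probe <- m0$probe$x
  expect_identical(predict_submodel(m0$sub_forward, probe),
                   predict_submodel(m0$sub_reverse, probe))
})

test_that("model2 requires both TF-TF and TF-TCOF instances", {
  sd <- small_dataset(n_per_class = 10L, n_indices = 5L)
  only_other <- sd$pairs[sd$pairs$label == "OTHER", ]
  expect_error(train_dual_model(only_other, sd$features, "model2"),
               "no usable pairs")
  no_tftf <- sd$pairs[sd$pairs$label != "TF", ]
  expect_error(train_dual_model(no_tftf, sd$features, "model2"),
               "requires TF-TF")
})

test_that("paper-mode score is the exact mean of the two sub-scores", {
  sd <- small_dataset(n_per_class = 15L, n_indices = 5L)
  model <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  for (i in c(1L, 20L, 40L)) {
    p <- predict_pair(model, sd$pairs$tf_id[i], sd$pairs$partner_id[i],
                      sd$features, "paper")
    expect_identical(p$score, (p$sub_score_forward + p$sub_score_reverse) / 2)
  }
})

test_that("a score exactly at the threshold is called positive", {
  sd <- small_dataset(n_per_class = 15L, n_indices = 5L)
  model <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  p <- predict_pair(model, sd$pairs$tf_id[1], sd$pairs$partner_id[1],
                    sd$features)
  at_threshold <- predict_pair(model, sd$pairs$tf_id[1],
                               sd$pairs$partner_id[1], sd$features,
                               threshold = p$score)
  expect_identical(at_threshold$predicted_label, "TF/TCOF")
})

test_that("strict mode is exactly symmetric; paper mode need not be", {
  sd <- small_dataset(n_per_class = 20L, n_indices = 6L)
  model <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  for (i in c(2L, 11L, 35L)) {
    a <- sd$pairs$tf_id[i]; b <- sd$pairs$partner_id[i]
    s_ab <- predict_pair(model, a, b, sd$features, "strict")
    s_ba <- predict_pair(model, b, a, sd$features, "strict")
    expect_identical(s_ab$score, s_ba$score)
  }
})

test_that("the cascade resolves OTHER, TF and TCOF by thresholding", {
  sd <- small_dataset(n_per_class = 15L, n_indices = 5L)
  m1 <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  m2 <- train_dual_model(sd$pairs, sd$features, "model2", small_hyper())
  tf <- sd$pairs$tf_id[1]; pt <- sd$pairs$partner_id[1]
  s1 <- predict_pair(m1, tf, pt, sd$features)$score
  s2 <- predict_pair(m2, tf, pt, sd$features)$score

  # model1 below threshold -> OTHER, model2 never consulted
  below <- cascade_predict(m1, m2, tf, pt, sd$features,
                           threshold = min(s1 + 0.01, 1))
  expect_identical(below$predicted_class, "OTHER")
  expect_true(is.na(below$model2_score))

  # model1 passes; model2 decides TCOF vs TF
  thr <- min(s1, s2)
  expect_identical(
    cascade_predict(m1, m2, tf, pt, sd$features, threshold = thr)$predicted_class,
    "TCOF")
  if (s2 < s1) {
    mid <- (s2 + s1) / 2
    expect_identical(
      cascade_predict(m1, m2, tf, pt, sd$features,
                      threshold = mid)$predicted_class,
      "TF")
  }
})

test_that("models trained on different index sets refuse to cooperate", {
  sd <- small_dataset(n_per_class = 12L, n_indices = 5L)
  other_set <- select_indices(sd$ds$aaindex, sd$ds$aaindex$accession[1:3])
  other_features <- featurize_proteins(sd$ds$records, other_set)
  m1 <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  m2b <- train_dual_model(sd$pairs, other_features, "model2", small_hyper())
  expect_error(predict_pair(m1, sd$pairs$tf_id[1], sd$pairs$partner_id[1],
                            other_features),
               "signature mismatch")
  expect_error(cascade_predict(m1, m2b, sd$pairs$tf_id[1],
                               sd$pairs$partner_id[1], sd$features),
               "different index sets")
})

test_that("save/load round-trips bit-identical probe predictions", {
  sd <- small_dataset(n_per_class = 15L, n_indices = 5L)
  model <- train_dual_model(sd$pairs, sd$features, "model1", small_hyper())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  loaded <- load_model(path)
  probe <- model$probe$x
  expect_identical(nrow(probe), 20L)
  expect_identical(predict_submodel(loaded$sub_forward, probe),
                   predict_submodel(model$sub_forward, probe))
  expect_identical(predict_submodel(loaded$sub_reverse, probe),
                   predict_submodel(model$sub_reverse, probe))

  expect_error(load_model(path, expected_accessions = c("WRONG00001")),
               "different index accession list")

  # truncation is detected as an error, not a crash
  bytes <- readBin(path, "raw", file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".rds")
  writeBin(bytes[seq_len(floor(length(bytes) / 2))], trunc_path)
  expect_error(load_model(trunc_path), "corrupt or truncated")
})
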