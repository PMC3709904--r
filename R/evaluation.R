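# Cross-validation and split evaluation: accuracy, sensitivity, specificity.

#' Confusion counts from truth and prediction
#'
#' @param truth,predicted Factors or characters; `positive` names the
#'   positive class.
#' @param positive Positive class label (default `"positive"`).
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive = "positive") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  c(tp = sum(truth == positive & predicted == positive),
    fp = sum(truth != positive & predicted == positive),
    tn = sum(truth != positive & predicted != positive),
    fn = sum(truth == positive & predicted != positive))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
#' accuracy = (tp + tn) / (tp + fp + tn + fn). A rate with a zero
#' denominator is undefined and reported as `NA`, never as 0. Counts are
#' integers, so each rate is a single exact integer division rounded once
#' to double.
#'
#' @param counts Named vector or list with `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics_from_counts <- function(counts) {
  counts <- unlist(counts)[c("tp", "fp", "tn", "fn")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative tp/fp/tn/fn")
  total <- sum(counts)
  if (total == 0)
    stop("no evaluated pairs: all confusion counts are zero")
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  c(accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Canonical row order: by label, then identifiers. Makes fold assignment
# and training-row order a function of (seed, labels, ids), not file order.
canonical_order <- function(pairs) {
  order(pairs$label, pairs$tf_id, pairs$partner_id, method = "radix")
}

# Stratified fold labels for pairs already in canonical order.
assign_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k == n)   # leave-one-out: one pair per fold
    return(withr::with_seed(seed, sample(n)))
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

new_eval_report <- function(task, scheme, folds_df, seed, hyper, n_excluded,
                            threshold) {
  agg <- vapply(c("tp", "fp", "tn", "fn"), function(cn) sum(folds_df[[cn]]),
                numeric(1))
  structure(
    list(task = task, scheme = scheme, folds = folds_df,
         aggregate_counts = agg, metrics = metrics_from_counts(agg),
         seed = seed, hyper = hyper, n_excluded = n_excluded,
         threshold = threshold, n = sum(agg)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  sch <- if (x$scheme$type == "kfold") sprintf("%d-fold CV", x$scheme$k) else
    sprintf("%.0f%%/%.0f%% split", 100 * x$scheme$train_fraction,
            100 * (1 - x$scheme$train_fraction))
  cat(sprintf("eval_report [%s, %s, n=%d]\n", x$task, sch, x$n))
  m <- x$metrics
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  invisible(x)
}

# Shared fold evaluation: train both sub-models on the training rows of the
# forward/reversed matrices, score test rows in paper mode.
fit_and_score_fold <- function(dm_f, dm_r, train_idx, test_idx, hyper,
                               seeds, task, threshold) {
  h_f <- hyper; h_f$seed <- seeds[1]
  h_r <- hyper; h_r$seed <- seeds[2]
  sub_f <- train_submodel(dm_f$x[train_idx, , drop = FALSE],
                          dm_f$y[train_idx], h_f, "forward", task,
                          dm_f$index_signature)
  sub_r <- train_submodel(dm_r$x[train_idx, , drop = FALSE],
                          dm_r$y[train_idx], h_r, "reversed", task,
                          dm_r$index_signature)
  pf <- predict_submodel(sub_f, dm_f$x[test_idx, , drop = FALSE])
  pr <- predict_submodel(sub_r, dm_f$x[test_idx, , drop = FALSE])
  score <- (pf + pr) / 2
  predicted <- ifelse(score >= threshold, "positive", "negative")
  confusion_counts(dm_f$y[test_idx], predicted)
}

#' Stratified k-fold cross-validation of a dual model
#'
#' Folds are stratified on the pair labels (class proportions preserved per
#' fold within one instance); the dual model is retrained on each training
#' fold and every pair is tested exactly once. Fold assignment depends only
#' on the seed and the (label, identifier) keys, not on input row order.
#' `k = n` performs leave-one-out; otherwise every class must have at least
#' `k` members.
#'
#' @param pairs Labeled pair data.frame.
#' @param features Matrix from [featurize_proteins()].
#' @param task `"model1"` or `"model2"`.
#' @param k Number of folds (>= 2).
#' @param hyper An [rf_hyperparameters()] object.
#' @param seed Seed controlling fold assignment and the per-fold forest
#'   seeds.
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_report`: per-fold confusion counts and class balance,
#'   pooled aggregate counts, and accuracy/sensitivity/specificity
#'   recomputed exactly from the pooled counts.
#' @export
cross_validate <- function(pairs, features, task = c("model1", "model2"),
                           k = 10L, hyper = rf_hyperparameters(), seed = 1L,
                           threshold = 0.5) {
  task <- match.arg(task)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  dm_f <- build_design_matrix(pairs, features, task, "forward")
  n_excluded <- dm_f$n_excluded
  ord <- canonical_order(dm_f$pairs)
  used <- dm_f$pairs[ord, , drop = FALSE]
  dm_f <- build_design_matrix(used, features, task, "forward")
  dm_r <- build_design_matrix(used, features, task, "reversed")
  n <- nrow(used)
  if (k > n) stop(sprintf("k = %d exceeds the %d available pairs", k, n))
  tab <- table(used$label)
  if (k < n && any(tab < k))
    stop(sprintf("class '%s' has only %d pair(s); choose k <= %d",
                 names(tab)[which.min(tab)], min(tab), min(tab)))
  fold <- assign_folds(used$label, k, seed)
  seeds <- c(seed, seed + 1L)
  rows <- lapply(seq_len(k), function(f) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    cc <- fit_and_score_fold(dm_f, dm_r, train_idx, test_idx, hyper,
                             seeds, task, threshold)
    data.frame(fold = f, tp = cc["tp"], fp = cc["fp"], tn = cc["tn"],
               fn = cc["fn"],
               n_pos = sum(dm_f$y[test_idx] == "positive"),
               n_neg = sum(dm_f$y[test_idx] == "negative"),
               row.names = NULL)
  })
  new_eval_report(task, list(type = "kfold", k = k), do.call(rbind, rows),
                  seed, hyper, n_excluded, threshold)
}

#' Stratified train/test split evaluation
#'
#' Holds out a stratified test fraction (class proportions preserved; the
#' per-class test size is `round((1 - train_fraction) * n_class)`), trains
#' the dual model on the rest and evaluates once.
#'
#' @inheritParams cross_validate
#' @param train_fraction Fraction of pairs used for training, in (0, 1).
#' @return An `eval_report` with a single evaluation row; the scheme records
#'   both subset sizes.
#' @export
split_evaluate <- function(pairs, features, task = c("model1", "model2"),
                           train_fraction = 2 / 3,
                           hyper = rf_hyperparameters(), seed = 1L,
                           threshold = 0.5) {
  task <- match.arg(task)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  dm_f <- build_design_matrix(pairs, features, task, "forward")
  n_excluded <- dm_f$n_excluded
  ord <- canonical_order(dm_f$pairs)
  used <- dm_f$pairs[ord, , drop = FALSE]
  dm_f <- build_design_matrix(used, features, task, "forward")
  dm_r <- build_design_matrix(used, features, task, "reversed")
  n <- nrow(used)
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (cl in sort(unique(used$label))) {
      idx <- which(used$label == cl)
      n_test <- round((1 - train_fraction) * length(idx))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  for (subset in list(train = train_idx, test = test_idx)) {
    present <- unique(as.character(dm_f$y[subset]))
    if (length(present) < 2L)
      stop("a class is absent from the train or test subset; adjust the fraction")
  }
  cc <- fit_and_score_fold(dm_f, dm_r, train_idx, test_idx, hyper,
                           c(seed, seed + 1L), task, threshold)
  folds_df <- data.frame(fold = 1L, tp = cc["tp"], fp = cc["fp"],
                         tn = cc["tn"], fn = cc["fn"],
                         n_pos = sum(dm_f$y[test_idx] == "positive"),
                         n_neg = sum(dm_f$y[test_idx] == "negative"),
                         row.names = NULL)
  new_eval_report(task,
                  list(type = "split", train_fraction = train_fraction,
                       n_train = length(train_idx), n_test = length(test_idx)),
                  folds_df, seed, hyper, n_excluded, threshold)
}

#' Write evaluation reports as JSON and TSV
#'
#' The JSON carries the full per-fold detail; the TSV has one summary row
#' per report (task, scheme, counts, rates).
#'
#' @param reports A list of `eval_report`s.
#' @param json_file,tsv_file Output paths (either may be `NULL` to skip).
#' @export
write_eval_reports <- function(reports, json_file = NULL, tsv_file = NULL) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  if (!is.null(json_file)) {
    payload <- lapply(reports, function(r)
      list(task = r$task, scheme = r$scheme, folds = r$folds,
           aggregate_counts = as.list(r$aggregate_counts),
           metrics = as.list(r$metrics), seed = r$seed,
           threshold = r$threshold, n = r$n, n_excluded = r$n_excluded))
    jsonlite::write_json(payload, json_file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_file)) {
    rows <- lapply(reports, function(r) {
      sch <- if (r$scheme$type == "kfold") sprintf("cv%d", r$scheme$k) else
        sprintf("split%.3f", r$scheme$train_fraction)
      data.frame(task = r$task, scheme = sch,
                 n = r$n, tp = r$aggregate_counts[["tp"]],
                 fp = r$aggregate_counts[["fp"]],
                 tn = r$aggregate_counts[["tn"]],
                 fn = r$aggregate_counts[["fn"]],
                 accuracy = r$metrics[["accuracy"]],
                 sensitivity = r$metrics[["sensitivity"]],
                 specificity = r$metrics[["specificity"]])
    })
    utils::write.table(do.call(rbind, rows), tsv_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(reports)
}
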