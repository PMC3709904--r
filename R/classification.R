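# Dual-sub-model Random Forest ensembles and the cascaded three-class call.
#
# Each task (model1: TF/TcoF vs other; model2: TcoF vs TF) is served by two
# Random Forest sub-models trained on opposite orderings of the TF-TF pair
# rows. A pair's confidence score is the averaged positive-class
# probability, where each forest's probability is itself the average of the
# per-tree class probabilities.

#' Random Forest hyperparameters
#'
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `NULL` means
#'   `floor(sqrt(2k))` for a `2k`-column design matrix.
#' @param max_depth Maximum tree depth; `0` (default) means unlimited.
#' @param seed Seed for the forest's RNG (default 1).
#' @return A list of class `rf_hyperparameters`.
#' @export
rf_hyperparameters <- function(n_trees = 100L, mtry = NULL, max_depth = 0L,
                               seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 0L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "rf_hyperparameters")
}

#' Train one Random Forest sub-model
#'
#' A probability forest: its prediction for a row is the average of the
#' per-tree class probabilities, summing to 1 over the two classes. Training
#' is deterministic given the data, hyperparameters and seed.
#'
#' @param x Numeric design matrix (no missing values).
#' @param y Factor with levels `negative`, `positive`; both classes must be
#'   present.
#' @param hyper An [rf_hyperparameters()] object.
#' @param orientation `"forward"` or `"reversed"` (metadata).
#' @param task `"model1"` or `"model2"` (metadata).
#' @param index_signature Signature of the index set behind `x`.
#' @return A `tfp_submodel`.
#' @importFrom ranger ranger
#' @export
train_submodel <- function(x, y, hyper = rf_hyperparameters(),
                           orientation = "forward", task = "model1",
                           index_signature = NULL) {
  stopifnot(is.matrix(x), inherits(hyper, "rf_hyperparameters"))
  if (anyNA(x) || any(!is.finite(x)))
    stop("design matrix contains missing or non-finite values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop(sprintf("training set has a single class ('%s'); two are required",
                 levels(y)[1]))
  y <- factor(as.character(y), levels = c("negative", "positive"))
  mtry <- if (is.null(hyper$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    as.integer(hyper$mtry)
  forest <- ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = hyper$n_trees, mtry = mtry,
    max.depth = if (hyper$max_depth > 0L) hyper$max_depth else NULL,
    seed = hyper$seed, num.threads = 1L)
  structure(
    list(task = task, orientation = orientation, forest = forest,
         hyper = hyper, mtry = mtry, n_features = ncol(x),
         index_signature = index_signature,
         class_counts = as.list(table(y))),
    class = "tfp_submodel")
}

#' Positive-class probabilities from a sub-model
#'
#' @param submodel A `tfp_submodel`.
#' @param x Matrix of rows to score (width must match training width).
#' @return Numeric vector of positive-class probabilities in `[0, 1]`.
#' @export
predict_submodel <- function(submodel, x) {
  stopifnot(inherits(submodel, "tfp_submodel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != submodel$n_features)
    stop(sprintf("input width %d does not match model width %d",
                 ncol(x), submodel$n_features))
  colnames(x) <- submodel$forest$forest$independent.variable.names
  p <- stats::predict(submodel$forest, data = x,
                      num.threads = 1L)$predictions
  unname(p[, "positive"])
}

#' Train a dual (forward + reverse) model for one task
#'
#' The forward sub-model sees pair rows as (TF, partner); the reverse
#' sub-model sees TF-TF rows with the two halves swapped, so that averaging
#' the two sub-models approximates invariance to the arbitrary ordering of
#' a TF-TF pair. The two sub-models share hyperparameters but receive
#' independent seeds.
#'
#' @param pairs Labeled pair data.frame.
#' @param features Matrix from [featurize_proteins()].
#' @param task `"model1"` or `"model2"`.
#' @param hyper An [rf_hyperparameters()] object (its `seed` is ignored in
#'   favour of `seeds`).
#' @param seeds Integer pair: seeds for the forward and reverse sub-models.
#' @return A `dual_model` carrying both sub-models, training class counts
#'   and a 20-row probe with its expected sub-model scores (used to verify
#'   serialization round-trips).
#' @export
train_dual_model <- function(pairs, features, task = c("model1", "model2"),
                             hyper = rf_hyperparameters(),
                             seeds = c(1L, 2L)) {
  task <- match.arg(task)
  stopifnot(length(seeds) == 2L)
  dm_f <- build_design_matrix(pairs, features, task, "forward")
  dm_r <- build_design_matrix(pairs, features, task, "reversed")
  if (task == "model2") {
    tab <- table(dm_f$pairs$label)
    if (!"TF" %in% names(tab) || tab[["TF"]] == 0L)
      stop("model2 requires TF-TF training instances")
    if (!"TCOF" %in% names(tab) || tab[["TCOF"]] == 0L)
      stop("model2 requires TF-TCOF training instances")
  }
  h_f <- hyper; h_f$seed <- as.integer(seeds[1])
  h_r <- hyper; h_r$seed <- as.integer(seeds[2])
  sig <- dm_f$index_signature
  sub_forward <- train_submodel(dm_f$x, dm_f$y, h_f, "forward", task, sig)
  sub_reverse <- train_submodel(dm_r$x, dm_r$y, h_r, "reversed", task, sig)
  probe_x <- dm_f$x[seq_len(min(20L, nrow(dm_f$x))), , drop = FALSE]
  model <- structure(
    list(task = task, sub_forward = sub_forward, sub_reverse = sub_reverse,
         hyper = hyper, seeds = as.integer(seeds),
         index_signature = sig,
         accessions = attr(features, "accessions"),
         label_counts = as.list(table(dm_f$pairs$label)),
         target_counts = as.list(table(dm_f$y)),
         n_excluded = dm_f$n_excluded,
         created = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("tfpartner"))),
    class = "dual_model")
  model$probe <- list(x = probe_x,
                      forward = predict_submodel(sub_forward, probe_x),
                      reverse = predict_submodel(sub_reverse, probe_x))
  model
}

#' @export
print.dual_model <- function(x, ...) {
  cat(sprintf("dual_model [%s]: %d trees x 2 sub-models, signature %s\n",
              x$task, x$hyper$n_trees, x$index_signature))
  cat("  training labels:",
      paste(sprintf("%s=%d", names(x$label_counts),
                    unlist(x$label_counts)), collapse = " "), "\n")
  invisible(x)
}

check_signature <- function(model, features) {
  sig <- attr(features, "index_signature")
  if (!is.null(sig) && !is.null(model$index_signature) &&
      !identical(sig, model$index_signature))
    stop(sprintf("index signature mismatch: model %s vs features %s",
                 model$index_signature, sig))
}

# Dual-model scores for a matrix of forward-oriented pair rows.
# paper mode: mean of the two sub-model scores on the rows as given.
# strict mode needs per-pair reversed rows, handled in predict_pair.
score_matrix <- function(model, x_forward) {
  pf <- predict_submodel(model$sub_forward, x_forward)
  pr <- predict_submodel(model$sub_reverse, x_forward)
  (pf + pr) / 2
}

#' Score one interacting pair
#'
#' In `"paper"` mode the pair is fed to both sub-models in the order given
#' (TF first) and the two confidence scores are averaged. In `"strict"`
#' (strictly order-symmetric) mode each sub-model scores both orderings and
#' the four scores are averaged, which makes the result exactly invariant
#' to swapping the two proteins. The label is positive when the score
#' reaches the threshold; a score exactly at the threshold is positive.
#'
#' @param model A `dual_model`.
#' @param tf_id,partner_id Identifiers present in `features`.
#' @param features Matrix from [featurize_proteins()] built with the same
#'   index set as the model.
#' @param mode `"paper"` (default) or `"strict"`.
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return One-row data.frame: `tf_id`, `partner_id`, `task`, `score`,
#'   `sub_score_forward`, `sub_score_reverse`, `predicted_label`. The score
#'   is always the exact mean of the two sub-scores.
#' @export
predict_pair <- function(model, tf_id, partner_id, features,
                         mode = c("paper", "strict"), threshold = 0.5) {
  stopifnot(inherits(model, "dual_model"))
  mode <- match.arg(mode)
  check_signature(model, features)
  row_f <- pair_feature_row(tf_id, partner_id, features, "forward")
  if (mode == "paper") {
    ssf <- predict_submodel(model$sub_forward, row_f)
    ssr <- predict_submodel(model$sub_reverse, row_f)
  } else {
    row_r <- pair_feature_row(tf_id, partner_id, features, "reversed")
    # per-sub-model average over both orderings: symmetric in (a, b)
    ssf <- (predict_submodel(model$sub_forward, row_f) +
            predict_submodel(model$sub_forward, row_r)) / 2
    ssr <- (predict_submodel(model$sub_reverse, row_f) +
            predict_submodel(model$sub_reverse, row_r)) / 2
  }
  score <- (ssf + ssr) / 2
  positive_name <- if (model$task == "model1") "TF/TCOF" else "TCOF"
  negative_name <- if (model$task == "model1") "OTHER" else "TF"
  data.frame(tf_id = tf_id, partner_id = partner_id, task = model$task,
             score = score, sub_score_forward = ssf, sub_score_reverse = ssr,
             predicted_label = if (score >= threshold) positive_name else
               negative_name,
             stringsAsFactors = FALSE)
}

#' Score a table of pairs
#'
#' Vectorised [predict_pair()]; one output row per input pair.
#'
#' @inheritParams predict_pair
#' @param pairs data.frame with `tf_id` and `partner_id` columns.
#' @return data.frame with one row per pair.
#' @export
predict_pairs <- function(model, pairs, features,
                          mode = c("paper", "strict"), threshold = 0.5) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(nrow(pairs)), function(i)
    predict_pair(model, pairs$tf_id[i], pairs$partner_id[i], features,
                 mode, threshold))
  do.call(rbind, out)
}

#' Cascaded three-class prediction
#'
#' Model 1 first decides TF/TcoF versus other nuclear protein; pairs passing
#' Model 1 are forwarded to Model 2, which decides TcoF versus TF.
#'
#' @param model1,model2 `dual_model`s for the two tasks, trained on the same
#'   index set.
#' @inheritParams predict_pair
#' @return One-row data.frame: `tf_id`, `partner_id`, `model1_score`,
#'   `model2_score` (`NA` when Model 1 rejects), `predicted_class` in
#'   `OTHER`/`TF`/`TCOF`.
#' @export
cascade_predict <- function(model1, model2, tf_id, partner_id, features,
                            mode = c("paper", "strict"), threshold = 0.5) {
  stopifnot(model1$task == "model1", model2$task == "model2")
  if (!identical(model1$index_signature, model2$index_signature))
    stop("model1 and model2 were trained on different index sets")
  mode <- match.arg(mode)
  p1 <- predict_pair(model1, tf_id, partner_id, features, mode, threshold)
  if (p1$score < threshold)
    return(data.frame(tf_id = tf_id, partner_id = partner_id,
                      model1_score = p1$score, model2_score = NA_real_,
                      predicted_class = "OTHER", stringsAsFactors = FALSE))
  p2 <- predict_pair(model2, tf_id, partner_id, features, mode, threshold)
  data.frame(tf_id = tf_id, partner_id = partner_id,
             model1_score = p1$score, model2_score = p2$score,
             predicted_class = if (p2$score >= threshold) "TCOF" else "TF",
             stringsAsFactors = FALSE)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a dual model artifact
#'
#' The artifact bundles the two serialized forests, a manifest (accessions,
#' index signature, hyperparameters, seeds, class counts) and a probe
#' matrix with the sub-model scores recorded at training time. [load_model()]
#' re-scores the probe and refuses the artifact unless the predictions are
#' bit-identical.
#'
#' @param model A `dual_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dual_model"))
  artifact <- list(format_version = MODEL_FORMAT_VERSION,
                   manifest = list(task = model$task,
                                   accessions = model$accessions,
                                   index_signature = model$index_signature,
                                   hyper = unclass(model$hyper),
                                   seeds = model$seeds,
                                   label_counts = model$label_counts,
                                   created = model$created,
                                   package_version = model$package_version),
                   model = model)
  saveRDS(artifact, path)
  invisible(path)
}

#' Load a dual model artifact
#'
#' @param path Artifact written by [save_model()].
#' @param expected_accessions Optional accession list; loading aborts if it
#'   differs from the artifact's.
#' @return The `dual_model`.
#' @export
load_model <- function(path, expected_accessions = NULL) {
  artifact <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read model artifact '%s' (corrupt or truncated): %s",
                 path, conditionMessage(e)), call. = FALSE))
  if (!is.list(artifact) || is.null(artifact$format_version) ||
      artifact$format_version != MODEL_FORMAT_VERSION)
    stop(sprintf("'%s' is not a compatible model artifact", path))
  model <- artifact$model
  if (!is.null(expected_accessions) &&
      !identical(as.character(expected_accessions),
                 as.character(model$accessions)))
    stop("model artifact was trained on a different index accession list")
  fwd <- predict_submodel(model$sub_forward, model$probe$x)
  rev <- predict_submodel(model$sub_reverse, model$probe$x)
  if (!identical(fwd, model$probe$forward) ||
      !identical(rev, model$probe$reverse))
    stop(sprintf("probe check failed for '%s': stored and recomputed predictions differ",
                 path))
  model
}

#' Write predictions as TSV
#'
#' @param predictions data.frame from [predict_pairs()] or a rbind of
#'   [cascade_predict()] rows.
#' @param file Output path.
#' @export
write_predictions <- function(predictions, file) {
  utils::write.table(predictions, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(predictions)
}
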