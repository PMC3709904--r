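# Composition-averaged physico-chemical feature vectors and pair rows.
#
# A protein's value for one amino-acid index is the arithmetic mean of that
# index over the residues of its sequence; equivalently the dot product of
# the residue-frequency vector with the index's 20 residue values. A pair
# row is the concatenation of the two per-protein vectors.

residue_composition <- function(sequence, ambiguity = c("skip", "error")) {
  ambiguity <- match.arg(ambiguity)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  std <- res %in% AAINDEX_RESIDUES
  if (ambiguity == "error" && !all(std)) {
    pos <- which(!std)[1]
    stop(sprintf("nonstandard residue '%s' at position %d", res[pos], pos))
  }
  res <- res[std]
  if (!length(res))
    stop("sequence has no scorable residues")
  counts <- tabulate(match(res, AAINDEX_RESIDUES), nbins = 20L)
  counts / sum(counts)
}

#' Composition-averaged feature vector for one protein
#'
#' Entry *j* is the mean of index *j*'s residue values over the sequence.
#' Under the `"skip"` ambiguity policy, residues outside the 20 standard
#' codes are excluded from both numerator and denominator; under `"error"`
#' any nonstandard residue aborts.
#'
#' @param sequence Protein sequence string (or a one-row data.frame from
#'   [read_fasta()]).
#' @param set An `aa_index_set` with no missing values (see
#'   [resolve_missing_values()]).
#' @param ambiguity `"skip"` (default) or `"error"`.
#' @return Named numeric vector (one entry per index) with attribute
#'   `index_signature`.
#' @export
protein_feature_vector <- function(sequence, set,
                                   ambiguity = c("skip", "error")) {
  stopifnot(inherits(set, "aa_index_set"))
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  if (anyNA(set$values))
    stop("index set contains missing values; apply resolve_missing_values() first")
  p <- residue_composition(sequence, ambiguity)
  v <- as.numeric(set$values %*% p)
  names(v) <- set$accession
  attr(v, "index_signature") <- set$signature
  v
}

#' Featurize a table of protein records
#'
#' @param records data.frame from [read_fasta()].
#' @param set An `aa_index_set` with no missing values.
#' @param ambiguity Passed to [protein_feature_vector()].
#' @return Numeric matrix (proteins x indices) with `protein_id` rownames
#'   and attributes `index_signature`, `accessions` and `ambiguity`.
#' @export
featurize_proteins <- function(records, set, ambiguity = c("skip", "error")) {
  stopifnot(inherits(set, "aa_index_set"))
  ambiguity <- match.arg(ambiguity)
  if (anyNA(set$values))
    stop("index set contains missing values; apply resolve_missing_values() first")
  comp <- t(vapply(records$sequence, residue_composition, numeric(20L),
                   ambiguity = ambiguity, USE.NAMES = FALSE))
  m <- comp %*% t(set$values)
  rownames(m) <- records$protein_id
  colnames(m) <- set$accession
  attr(m, "index_signature") <- set$signature
  attr(m, "accessions") <- set$accession
  attr(m, "ambiguity") <- ambiguity
  m
}

feature_lookup <- function(features, ids) {
  missing <- setdiff(ids, rownames(features))
  if (length(missing))
    stop(sprintf("no feature vector for identifier(s): %s",
                 paste(missing, collapse = ", ")))
  features[ids, , drop = FALSE]
}

#' Concatenated feature row for one interacting pair
#'
#' `"forward"` places the known TF first, `"reversed"` the partner first;
#' reversing twice restores the forward row.
#'
#' @param tf_id,partner_id Identifiers present in `features`.
#' @param features Matrix from [featurize_proteins()].
#' @param orientation `"forward"` (default) or `"reversed"`.
#' @return Numeric vector of length `2 * ncol(features)` with attributes
#'   `orientation` and `index_signature`.
#' @export
pair_feature_row <- function(tf_id, partner_id, features,
                             orientation = c("forward", "reversed")) {
  orientation <- match.arg(orientation)
  f <- feature_lookup(features, c(tf_id, partner_id))
  row <- if (orientation == "forward") c(f[1, ], f[2, ]) else c(f[2, ], f[1, ])
  names(row) <- c(paste0("a_", colnames(features)),
                  paste0("b_", colnames(features)))
  attr(row, "orientation") <- orientation
  attr(row, "index_signature") <- attr(features, "index_signature")
  row
}

#' Build a design matrix and binary target for one classification task
#'
#' `"model1"` keeps every labeled pair and targets TF/TcoF partners
#' (positive) against other nuclear proteins (negative). `"model2"` keeps
#' only TF- and TCOF-labeled pairs (OTHER rows are excluded and counted)
#' and targets TcoF partners (positive) against TF partners (negative).
#'
#' Under the `"reversed"` orientation only rows whose partner is itself a TF
#' (label `TF`) have their two halves swapped: these are the pairs whose
#' ordering is arbitrary, and training one sub-model per ordering is what
#' makes the averaged ensemble order-symmetric.
#'
#' @param pairs Labeled data.frame from [read_pair_table()].
#' @param features Matrix from [featurize_proteins()].
#' @param task `"model1"` or `"model2"`.
#' @param orientation `"forward"` or `"reversed"`.
#' @return List of class `design_matrix`: `x` (numeric matrix), `y` (factor
#'   with levels `negative`, `positive`), `pairs`, `task`, `orientation`,
#'   `n_excluded` and `index_signature`.
#' @export
build_design_matrix <- function(pairs, features,
                                task = c("model1", "model2"),
                                orientation = c("forward", "reversed")) {
  task <- match.arg(task)
  orientation <- match.arg(orientation)
  if (anyNA(pairs$label))
    stop("all pairs must be labeled to build a training design matrix")
  bad <- setdiff(unique(pairs$label), PAIR_LABELS)
  if (length(bad))
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))

  n_excluded <- 0L
  if (task == "model2") {
    keep <- pairs$label %in% c("TF", "TCOF")
    n_excluded <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (!nrow(pairs))
    stop(sprintf("no usable pairs for task '%s'", task))

  ftf <- feature_lookup(features, pairs$tf_id)
  fpt <- feature_lookup(features, pairs$partner_id)
  x <- cbind(ftf, fpt)
  colnames(x) <- c(paste0("a_", colnames(features)),
                   paste0("b_", colnames(features)))
  if (orientation == "reversed") {
    k <- ncol(features)
    swap <- pairs$label == "TF"
    if (any(swap))
      x[swap, ] <- x[swap, c((k + 1L):(2L * k), 1L:k), drop = FALSE]
  }
  positive <- if (task == "model1") pairs$label %in% c("TF", "TCOF")
              else pairs$label == "TCOF"
  y <- factor(ifelse(positive, "positive", "negative"),
              levels = c("negative", "positive"))
  structure(
    list(x = x, y = y, pairs = pairs, task = task, orientation = orientation,
         n_excluded = n_excluded,
         index_signature = attr(features, "index_signature")),
    class = "design_matrix")
}

#' Write a featurized pair table with its manifest
#'
#' Writes a TSV (`tf_id`, `partner_id`, `label`, then the `2k` feature
#' columns of the forward orientation) and a sidecar JSON manifest
#' recording the index signature, accession list and the policies used.
#'
#' @param pairs data.frame of pairs.
#' @param features Matrix from [featurize_proteins()].
#' @param file Output TSV path; the manifest goes to `<file>.manifest.json`.
#' @param missing_policy,ambiguity_policy Recorded in the manifest.
#' @export
write_feature_table <- function(pairs, features, file,
                                missing_policy = "drop",
                                ambiguity_policy = attr(features, "ambiguity")) {
  ftf <- feature_lookup(features, pairs$tf_id)
  fpt <- feature_lookup(features, pairs$partner_id)
  df <- data.frame(tf_id = pairs$tf_id, partner_id = pairs$partner_id,
                   label = if ("label" %in% names(pairs)) pairs$label else NA,
                   stringsAsFactors = FALSE)
  mat <- cbind(ftf, fpt)
  colnames(mat) <- c(paste0("a_", colnames(features)),
                     paste0("b_", colnames(features)))
  utils::write.table(cbind(df, as.data.frame(mat)), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(index_signature = attr(features, "index_signature"),
                   accessions = attr(features, "accessions"),
                   ambiguity_policy = ambiguity_policy,
                   missing_policy = missing_policy,
                   n_pairs = nrow(df))
  jsonlite::write_json(manifest, paste0(file, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(df)
}
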