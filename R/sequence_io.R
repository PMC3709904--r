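# FASTA and interaction-pair table input/output.

# Residues accepted in input sequences: the 20 standard codes plus the
# common ambiguity/rare letters. How the extras are scored is decided at
# featurization time.
AMBIGUITY_RESIDUES <- c("B", "Z", "X", "U", "O", "J")
ALLOWED_RESIDUES <- c(AAINDEX_RESIDUES, AMBIGUITY_RESIDUES)

PAIR_LABELS <- c("TF", "TCOF", "OTHER")

strip_fasta_id <- function(header) {
  id <- sub("\\s.*$", "", header)
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  if (length(parts) == 3L) parts[2] else id
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and line breaks joined. The record identifier is
#' the first whitespace-delimited token of the header; UniProt-style
#' `db|ACC|name` headers are reduced to the accession. The alphabet is
#' restricted to the 20 standard residues plus `B, Z, X, U, O, J`.
#'
#' @param file Path to a FASTA file.
#' @return A data.frame with columns `protein_id` and `sequence`.
#' @export
read_fasta <- function(file) {
  set <- Biostrings::readBStringSet(file)
  ids <- vapply(names(set), strip_fasta_id, "", USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty))
    stop(sprintf("FASTA record '%s' has an empty sequence", ids[empty[1]]))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA identifier(s): %s",
                 paste(unique(dup), collapse = ", ")))
  bad_re <- sprintf("[^%s]", paste(ALLOWED_RESIDUES, collapse = ""))
  pos <- regexpr(bad_re, seqs)
  hit <- which(pos > 0L)
  if (length(hit)) {
    k <- hit[1]
    stop(sprintf("record '%s': invalid character '%s' at position %d",
                 ids[k], substr(seqs[k], pos[k], pos[k]), pos[k]))
  }
  data.frame(protein_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' @param records data.frame with `protein_id` and `sequence` columns.
#' @param file Output path.
#' @param width Line width for wrapping (default 60).
#' @export
write_fasta <- function(records, file, width = 60L) {
  xs <- Biostrings::AAStringSet(stats::setNames(records$sequence,
                                               records$protein_id))
  Biostrings::writeXStringSet(xs, file, width = width)
  invisible(records)
}

#' Read an interaction-pair table
#'
#' Tab-separated, two columns (known TF, partner) or three (plus a class
#' label in `TF`, `TCOF`, `OTHER`). Lines starting with `#` are comments.
#' Exact duplicate rows are collapsed with a warning; the same (tf, partner)
#' pair carrying conflicting labels is an error.
#'
#' @param file Path, connection, or character vector of lines.
#' @param labeled `TRUE` to require 3 columns, `FALSE` to require 2, `NA`
#'   (default) to infer from the first data row.
#' @return data.frame with `tf_id`, `partner_id`, `label` (`NA` when
#'   unlabeled), in file order.
#' @export
read_pair_table <- function(file, labeled = NA) {
  lines <- if (is.character(file) &&
               (length(file) > 1L || grepl("[\t\n]", file)))
    unlist(strsplit(file, "\n", fixed = TRUE))
  else readLines(file)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  tf <- character(0); partner <- character(0); label <- character(0)
  ncol_expect <- if (isTRUE(labeled)) 3L else if (isFALSE(labeled)) 2L else NA_integer_
  for (ln in keep) {
    toks <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    if (is.na(ncol_expect)) {
      if (!length(toks) %in% c(2L, 3L))
        stop(sprintf("pair table line %d: expected 2 or 3 columns, found %d",
                     ln, length(toks)))
      ncol_expect <- length(toks)
    }
    if (length(toks) != ncol_expect)
      stop(sprintf("pair table line %d: expected %d columns, found %d",
                   ln, ncol_expect, length(toks)))
    if (!nzchar(toks[1]) || !nzchar(toks[2]))
      stop(sprintf("pair table line %d: empty identifier", ln))
    lab <- if (ncol_expect == 3L) toupper(toks[3]) else NA_character_
    if (!is.na(lab) && !lab %in% PAIR_LABELS)
      stop(sprintf("pair table line %d: unknown label '%s' (expected %s)",
                   ln, toks[3], paste(PAIR_LABELS, collapse = "/")))
    tf <- c(tf, toks[1]); partner <- c(partner, toks[2]); label <- c(label, lab)
  }
  df <- data.frame(tf_id = tf, partner_id = partner, label = label,
                   stringsAsFactors = FALSE)
  # conflicting labels for the same id pair are an error, not a vote
  key <- paste(df$tf_id, df$partner_id, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    labs <- unique(df$label[key == k])
    if (length(labs) > 1L)
      stop(sprintf("conflicting labels for pair (%s): %s",
                   gsub("\r", ", ", k), paste(labs, collapse = " vs ")))
  }
  full_key <- paste(key, df$label, sep = "\r")
  if (anyDuplicated(full_key)) {
    n_dup <- sum(duplicated(full_key))
    warning(sprintf("collapsed %d duplicate pair row(s)", n_dup))
    df <- df[!duplicated(full_key), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write an interaction-pair table
#'
#' @param pairs data.frame with `tf_id`, `partner_id` and optionally `label`.
#' @param file Output path or connection.
#' @export
write_pair_table <- function(pairs, file) {
  labeled <- "label" %in% names(pairs) && !all(is.na(pairs$label))
  cols <- if (labeled) c("tf_id", "partner_id", "label") else
    c("tf_id", "partner_id")
  utils::write.table(pairs[, cols, drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(pairs)
}

#' Cross-reference pairs against sequence records
#'
#' Checks that every identifier in the pair table has a sequence. In strict
#' mode any unresolved identifier aborts; in lenient mode pairs with an
#' unresolved side are dropped and reported.
#'
#' @param pairs data.frame from [read_pair_table()].
#' @param records data.frame from [read_fasta()].
#' @param strict Abort on unresolved identifiers (default `TRUE`).
#' @return List with `pairs` (resolved rows), `unresolved` (identifiers
#'   without a record) and `n_dropped`.
#' @export
resolve_pairs <- function(pairs, records, strict = TRUE) {
  known <- records$protein_id
  miss_tf <- !pairs$tf_id %in% known
  miss_pt <- !pairs$partner_id %in% known
  unresolved <- unique(c(pairs$tf_id[miss_tf], pairs$partner_id[miss_pt]))
  if (length(unresolved) && strict)
    stop(sprintf("unresolved identifier(s): %s",
                 paste(unresolved, collapse = ", ")))
  keep <- !(miss_tf | miss_pt)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out, unresolved = unresolved, n_dropped = sum(!keep))
}
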