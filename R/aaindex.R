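# AAindex1 flat-file input/output and index-set handling.

#' Canonical residue order of the AAindex1 value rows
#'
#' The two `I`-record rows of an AAindex1 entry list values in the fixed
#' order A R N D C Q E G H I (first row) and L K M F P S T W Y V (second
#' row). All value matrices in this package use this column order.
#'
#' @format Character vector of the 20 standard one-letter residue codes.
#' @export
AAINDEX_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# 32-bit FNV-1a over a string, returned as 8 hex digits. Multiplication is
# split into 16-bit halves so intermediates stay below 2^53 (exact doubles).
fnv1a32 <- function(x) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(x)) {
    h <- bitwXor_dbl(h, b)
    hi <- floor(h / 65536)
    lo <- h - hi * 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  hex <- "0123456789abcdef"
  out <- character(8)
  for (i in 8:1) {
    d <- h %% 16
    out[i] <- substr(hex, d + 1, d + 1)
    h <- (h - d) / 16
  }
  paste(out, collapse = "")
}

# bitwXor for doubles in [0, 2^32); base bitwXor works on 32-bit signed ints.
bitwXor_dbl <- function(a, b) {
  ai <- a %% 4294967296
  res <- 0
  bit <- 1
  for (i in 1:32) {
    abit <- ai %% 2
    bbit <- b %% 2
    if (abit != bbit) res <- res + bit
    ai <- (ai - abit) / 2
    b <- (b - bbit) / 2
    bit <- bit * 2
  }
  res
}

index_signature <- function(accessions) {
  fnv1a32(paste(accessions, collapse = "\n"))
}

new_index_set <- function(accession, description, values) {
  stopifnot(is.matrix(values), ncol(values) == 20L,
            nrow(values) == length(accession),
            length(description) == length(accession))
  colnames(values) <- AAINDEX_RESIDUES
  rownames(values) <- accession
  structure(
    list(accession = accession,
         description = description,
         values = values,
         signature = index_signature(accession)),
    class = "aa_index_set")
}

#' @export
print.aa_index_set <- function(x, ...) {
  cat(sprintf("aa_index_set: %d indices, signature %s\n",
              length(x$accession), x$signature))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d missing value(s)\n", n_na))
  utils::head(x$accession, 5) |>
    paste(collapse = ", ") |>
    (\(a) cat("  ", a, if (length(x$accession) > 5) ", ..." else "", "\n",
              sep = ""))()
  invisible(x)
}

#' @export
length.aa_index_set <- function(x) length(x$accession)

#' Read an AAindex1 flat file
#'
#' Parses the AAindex1 format: each entry starts with an `H` (accession)
#' record, carries a `D` (description) record, and an `I` record followed by
#' two rows of ten values in the canonical residue order
#' ([AAINDEX_RESIDUES]); entries end with `//`. The literal token `NA`
#' denotes a missing value and is kept as `NA`, never coerced to a number.
#' Other record types (`R`, `A`, `T`, `J`, `C`) are tolerated and ignored.
#'
#' @param file Path to an AAindex1 file, a connection, or a character vector
#'   of lines.
#' @return An `aa_index_set`: accessions, descriptions, a numeric value
#'   matrix (indices x 20 residues) and a signature hash of the ordered
#'   accession list. An empty file yields an empty set.
#' @export
read_aaindex <- function(file) {
  lines <- if (is.character(file) && length(file) != 1L)
    file
  else if (is.character(file) && grepl("\n", file, fixed = TRUE))
    strsplit(file, "\n", fixed = TRUE)[[1]]
  else readLines(file)

  accs <- character(0)
  descs <- character(0)
  vals <- list()

  acc <- NULL; desc <- ""; v <- NULL
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    key <- substr(line, 1L, 1L)
    if (key == "H") {
      if (!is.null(acc))
        stop(sprintf("AAindex parse error at line %d: entry '%s' not terminated by //",
                     i, acc))
      acc <- trimws(substring(line, 2L))
      if (!nzchar(acc))
        stop(sprintf("AAindex parse error at line %d: empty accession", i))
      desc <- ""; v <- NULL
    } else if (key == "D" && !is.null(acc)) {
      desc <- trimws(substring(line, 2L))
      # indented continuation lines belong to the description
      while (i + 1L <= n && grepl("^\\s+\\S", lines[[i + 1L]])) {
        i <- i + 1L
        desc <- paste(desc, trimws(lines[[i]]))
      }
    } else if (key == "I" && !is.null(acc)) {
      if (i + 2L > n)
        stop(sprintf("AAindex parse error: truncated I record in entry '%s'", acc))
      v <- numeric(0)
      for (r in 1:2) {
        row_line <- lines[[i + r]]
        toks <- strsplit(trimws(row_line), "\\s+")[[1]]
        if (length(toks) != 10L)
          stop(sprintf(
            "AAindex parse error in entry '%s', line %d: expected 10 values, found %d",
            acc, i + r, length(toks)))
        row <- suppressWarnings(
          ifelse(toks == "NA", NA_real_, as.numeric(toks)))
        bad <- which(toks != "NA" & is.na(row))
        if (length(bad))
          stop(sprintf(
            "AAindex parse error in entry '%s', line %d: non-numeric token '%s'",
            acc, i + r, toks[bad[1]]))
        v <- c(v, row)
      }
      i <- i + 2L
    } else if (grepl("^//", line)) {
      if (is.null(acc))
        stop(sprintf("AAindex parse error at line %d: '//' outside an entry", i))
      if (is.null(v))
        stop(sprintf("AAindex parse error: entry '%s' has no I record", acc))
      if (all(is.na(v)))
        stop(sprintf("AAindex entry '%s' has no defined values", acc))
      if (acc %in% accs)
        stop(sprintf("duplicate AAindex accession '%s'", acc))
      accs <- c(accs, acc)
      descs <- c(descs, desc)
      vals[[length(vals) + 1L]] <- v
      acc <- NULL; desc <- ""; v <- NULL
    }
    # anything else (R/A/T/J/C records, blanks, continuations) is skipped
    i <- i + 1L
  }
  if (!is.null(acc))
    stop(sprintf("AAindex parse error: entry '%s' not terminated by //", acc))

  values <- if (length(vals)) do.call(rbind, vals) else
    matrix(numeric(0), nrow = 0, ncol = 20)
  new_index_set(accs, descs, values)
}

#' Write an index set in AAindex1 layout
#'
#' Emits `H`, `D` and `I` records (two rows of ten values, `NA` for missing)
#' terminated by `//`, at full numeric precision so that re-parsing restores
#' the values exactly.
#'
#' @param set An `aa_index_set`.
#' @param file Path or connection to write to.
#' @export
write_aaindex <- function(set, file) {
  stopifnot(inherits(set, "aa_index_set"))
  fmt1 <- function(x) if (is.na(x)) "NA" else format(x, digits = 17)
  out <- character(0)
  for (j in seq_along(set$accession)) {
    v <- set$values[j, ]
    row1 <- paste(vapply(v[1:10], fmt1, ""), collapse = "  ")
    row2 <- paste(vapply(v[11:20], fmt1, ""), collapse = "  ")
    out <- c(out,
             paste("H", set$accession[j]),
             paste("D", set$description[j]),
             "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
             paste0("    ", row1),
             paste0("    ", row2),
             "//")
  }
  writeLines(out, file)
  invisible(set)
}

#' Select indices by accession
#'
#' Subsets a parsed index set to a requested accession list, preserving the
#' request order. This is how a reduced feature configuration (for example a
#' curated subset of the full AAindex release) is applied.
#'
#' @param set An `aa_index_set`.
#' @param accessions Character vector of accessions to keep, in the desired
#'   order. Duplicates are an error, as is any accession absent from `set`.
#' @return An `aa_index_set` in the requested order with a new signature.
#' @export
select_indices <- function(set, accessions) {
  stopifnot(inherits(set, "aa_index_set"), is.character(accessions))
  if (anyDuplicated(accessions))
    stop(sprintf("duplicate accession(s) in selection: %s",
                 paste(unique(accessions[duplicated(accessions)]), collapse = ", ")))
  missing <- setdiff(accessions, set$accession)
  if (length(missing))
    stop(sprintf("accession(s) not found in index set: %s",
                 paste(missing, collapse = ", ")))
  idx <- match(accessions, set$accession)
  new_index_set(set$accession[idx], set$description[idx],
                set$values[idx, , drop = FALSE])
}

#' Drop or impute missing residue values
#'
#' Composition averaging is undefined over residues whose index value is
#' missing, so missing values must be resolved before featurization.
#' `"drop"` removes every index with at least one missing value;
#' `"impute_mean"` replaces each missing value with the mean of that index's
#' defined values.
#'
#' @param set An `aa_index_set`.
#' @param policy `"drop"` (default) or `"impute_mean"`.
#' @return An `aa_index_set` with no missing values.
#' @export
resolve_missing_values <- function(set, policy = c("drop", "impute_mean")) {
  stopifnot(inherits(set, "aa_index_set"))
  policy <- match.arg(policy)
  if (policy == "drop") {
    keep <- !apply(is.na(set$values), 1L, any)
    if (!any(keep))
      stop("missing-value policy 'drop' removed every index")
    new_index_set(set$accession[keep], set$description[keep],
                  set$values[keep, , drop = FALSE])
  } else {
    values <- set$values
    for (j in seq_len(nrow(values))) {
      miss <- is.na(values[j, ])
      if (any(miss))
        values[j, miss] <- mean(values[j, !miss])
    }
    new_index_set(set$accession, set$description, values)
  }
}

#' Export an index set as TSV
#'
#' One row per index: accession followed by the 20 residue columns in
#' canonical order.
#'
#' @param set An `aa_index_set`.
#' @param file Path or connection.
#' @export
export_indices_tsv <- function(set, file) {
  stopifnot(inherits(set, "aa_index_set"))
  df <- data.frame(accession = set$accession, set$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read an accession list (one accession per line)
#'
#' Lines starting with `#` and blank lines are ignored. Used to supply a
#' reduced feature configuration as a plain text file.
#'
#' @param file Path or connection.
#' @return Character vector of accessions in file order.
#' @export
read_accession_list <- function(file) {
  lines <- trimws(readLines(file))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
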