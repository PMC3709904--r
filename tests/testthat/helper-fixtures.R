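# Shared fixtures, built in code.

# Three-entry AAindex1 fixture:
#   TEST000001 - positional values 1..20
#   TEST000002 - value for L missing (leading NA in the second row)
#   TEST000003 - all 2.0 except one missing (for mean imputation)
toy_aaindex_lines <- function() c(
  "H TEST000001",
  "D positional toy index (values are residue positions)",
  "R ref",
  "A Nobody",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "    1.      2.      3.      4.      5.      6.      7.      8.      9.     10.",
  "   11.     12.     13.     14.     15.     16.     17.     18.     19.     20.",
  "//",
  "H TEST000002",
  "D toy index with a missing value for L",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "    0.1     0.2     0.3     0.4     0.5     0.6     0.7     0.8     0.9     1.0",
  "    NA      1.2     1.3     1.4     1.5     1.6     1.7     1.8     1.9     2.0",
  "//",
  "H TEST000003",
  "D constant index with one missing value",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "    2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0",
  "    2.0     NA      2.0     2.0     2.0     2.0     2.0     2.0     2.0     2.0",
  "//")

toy_aaindex_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy_aaindex.txt")
  writeLines(toy_aaindex_lines(), path)
  path
}

# One toy index as an aa_index_set (A = 1, ..., V = 20).
positional_index_set <- function() {
  select_indices(read_aaindex(toy_aaindex_lines()), "TEST000001")
}

# Independent brute-force oracle: re-sums index values residue by residue,
# never touching the composition-matrix path used by the implementation.
oracle_feature_vector <- function(sequence, set) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res <- res[res %in% AAINDEX_RESIDUES]
  vapply(seq_along(set$accession), function(j) {
    total <- 0
    for (r in res) total <- total + set$values[j, r]
    total / length(res)
  }, numeric(1))
}

# Small well-separated dataset + features for classifier tests.
small_dataset <- function(n_per_class = 30L, n_indices = 8L, delta = 0.5,
                          seed = 7L) {
  cfg <- synthetic_config(n_tf_tcof = n_per_class, n_tf_tf = n_per_class,
                          n_tf_other = n_per_class,
                          length_range = c(60L, 200L), delta = delta,
                          n_indices = n_indices, seed = seed)
  ds <- generate_dataset(cfg)
  list(ds = ds, pairs = ds$pairs,
       features = featurize_proteins(ds$records, ds$aaindex))
}

small_hyper <- function(n_trees = 50L) rf_hyperparameters(n_trees = n_trees)

# Random sequence of standard residues.
random_sequence <- function(len) {
  paste(sample(AAINDEX_RESIDUES, len, replace = TRUE), collapse = "")
}

# Random fully-defined index set.
random_index_set <- function(n_indices) {
  vals <- matrix(stats::runif(20L * n_indices, -5, 5), nrow = n_indices)
  tfpartner:::new_index_set(sprintf("RND%07d", seq_len(n_indices)),
                            rep("random index", n_indices), vals)
}

expect_identical_index_sets <- function(a, b) {
  expect_identical(a$accession, b$accession)
  expect_identical(a$description, b$description)
  expect_equal(unname(a$values), unname(b$values), tolerance = 0)
  expect_identical(is.na(a$values), is.na(b$values))
}
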