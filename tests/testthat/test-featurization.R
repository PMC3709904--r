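# Composition-averaged feature vectors and design-matrix construction.

toy_two_features <- function() {
  # hand-built feature matrix: T = (1, 2), P = (3, 4)
  m <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("T", "P"), c("i1", "i2")))
  attr(m, "index_signature") <- "toysig"
  attr(m, "accessions") <- c("i1", "i2")
  m
}

test_that("feature entries are arithmetic means of residue values", {
  set <- positional_index_set()
  # homopolymer returns the raw index value
  homo_set <- tfpartner:::new_index_set("TOY0000001", "toy",
                                        matrix(c(1.7, 2:20), nrow = 1))
  expect_identical(as.numeric(protein_feature_vector("AAAA", homo_set)), 1.7)
  # A = 1, R = 2 under the positional index
  expect_identical(as.numeric(protein_feature_vector("AR", set)), 1.5)
  # SKIP excludes nonstandard residues from numerator and denominator
  expect_identical(as.numeric(protein_feature_vector("ARX", set)), 1.5)
  expect_identical(as.numeric(protein_feature_vector("ARX", set, "skip")),
                   as.numeric(protein_feature_vector("AR", set)))
})

test_that("ambiguity and degenerate sequences follow the stated policies", {
  set <- positional_index_set()
  expect_error(protein_feature_vector("ARX", set, "error"),
               "'X' at position 3")
  expect_error(protein_feature_vector("XXXX", set, "skip"),
               "no scorable residues")
  unresolved <- read_aaindex(toy_aaindex_lines())
  expect_error(protein_feature_vector("AR", unresolved),
               "missing values")
})

test_that("implementation matches a residue-by-residue brute-force oracle", {
  withr::with_seed(202, {
    set <- random_index_set(5L)
    for (i in 1:20) {
      seqn <- random_sequence(sample(30:300, 1))
      expect_equal(as.numeric(protein_feature_vector(seqn, set)),
                   oracle_feature_vector(seqn, set), tolerance = 1e-12)
    }
  })
})

test_that("features are permutation-invariant and scale-equivariant", {
  withr::with_seed(303, {
    set <- random_index_set(4L)
    seqn <- random_sequence(120)
    shuffled <- paste(sample(strsplit(seqn, "")[[1]]), collapse = "")
    expect_identical(protein_feature_vector(seqn, set),
                     protein_feature_vector(shuffled, set))
    # multiplying index j's residue values by c multiplies feature j by c
    scaled <- set
    scaled$values[2, ] <- 3 * scaled$values[2, ]
    f0 <- protein_feature_vector(seqn, set)
    f1 <- protein_feature_vector(seqn, scaled)
    expect_equal(unname(f1[2]), 3 * unname(f0[2]), tolerance = 1e-12)
    expect_identical(f1[-2], f0[-2])
  })
})

test_that("feature values stay within the index's residue range", {
  withr::with_seed(404, {
    set <- random_index_set(6L)
    f <- featurize_proteins(
      data.frame(protein_id = c("a", "b"),
                 sequence = c(random_sequence(80), random_sequence(150))),
      set)
    for (j in seq_len(6L)) {
      expect_gte(min(f[, j]), min(set$values[j, ]))
      expect_lte(max(f[, j]), max(set$values[j, ]))
    }
  })
})

test_that("pair rows concatenate in the stated orientation", {
  f <- toy_two_features()
  fwd <- pair_feature_row("T", "P", f, "forward")
  expect_identical(as.numeric(fwd), c(1, 2, 3, 4))
  rev <- pair_feature_row("T", "P", f, "reversed")
  expect_identical(as.numeric(rev), c(3, 4, 1, 2))
  # reversing twice restores the forward row
  k <- 2L
  expect_identical(unname(rev[c((k + 1):(2 * k), 1:k)]), as.numeric(fwd))
  expect_error(pair_feature_row("T", "NOPE", f), "NOPE")
})

test_that("design matrices encode the task targets and orientation rule", {
  withr::with_seed(9, {
    rec <- data.frame(protein_id = c("T1", "T2", "T3", "PA", "PB", "PC"),
                      sequence = vapply(rep(60, 6), random_sequence, ""))
    set <- random_index_set(3L)
  })
  features <- featurize_proteins(rec, set)
  pairs <- data.frame(tf_id = c("T1", "T2", "T3"),
                      partner_id = c("PA", "PB", "PC"),
                      label = c("TCOF", "TF", "OTHER"),
                      stringsAsFactors = FALSE)

  dm1 <- build_design_matrix(pairs, features, "model1", "forward")
  # TF/TcoF partners are positive, other nuclear proteins negative
  expect_identical(as.character(dm1$y), c("positive", "positive", "negative"))

  dm2 <- build_design_matrix(pairs, features, "model2", "forward")
  expect_identical(nrow(dm2$x), 2L)
  expect_identical(as.character(dm2$y), c("positive", "negative"))
  expect_identical(dm2$n_excluded, 1L)

  # reversed orientation swaps halves only for TF-TF rows
  dmr <- build_design_matrix(pairs, features, "model1", "reversed")
  k <- ncol(features)
  swap <- c((k + 1):(2 * k), 1:k)
  expect_identical(unname(dmr$x[2, ]), unname(dm1$x[2, swap]))
  expect_identical(unname(dmr$x[c(1, 3), ]), unname(dm1$x[c(1, 3), ]))

  # forward and reversed matrices agree after half-swapping TF-TF rows
  recovered <- dmr$x
  recovered[2, ] <- recovered[2, swap]
  expect_identical(unname(recovered), unname(dm1$x))

  unlabeled <- pairs
  unlabeled$label[2] <- NA
  expect_error(build_design_matrix(unlabeled, features, "model1"),
               "must be labeled")
})

test_that("feature tables are written with their manifest", {
  sd <- small_dataset(n_per_class = 5L, n_indices = 4L)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "features.tsv")
  write_feature_table(sd$pairs, sd$features, out)
  tab <- utils::read.delim(out)
  expect_identical(nrow(tab), nrow(sd$pairs))
  expect_identical(ncol(tab), 3L + 2L * ncol(sd$features))
  manifest <- jsonlite::read_json(paste0(out, ".manifest.json"),
                                  simplifyVector = TRUE)
  expect_identical(manifest$index_signature,
                   attr(sd$features, "index_signature"))
  expect_identical(manifest$ambiguity_policy, "skip")
})
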