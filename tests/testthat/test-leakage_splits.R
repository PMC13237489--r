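test_that("global identity matches hand-checked alignments", {
  expect_equal(global_identity("ACDE", "ACDE"), 1.0)
  expect_equal(global_identity("ACDE", "ACDF"), 0.75)  # no gaps optimal
  expect_error(global_identity("", "ACD"), "empty")
})

test_that("global identity is symmetric and matches the brute-force DP oracle", {
  # linear gap scoring so the enumeration oracle applies exactly:
  # a gap of length g costs -2g under both conventions
  scoring <- list(match = 2, mismatch = -1, gap_open = -2, gap_extend = -2)
  set.seed(61)
  alphabet <- c("A", "C", "D", "W")  # reduced alphabet
  for (rep in 1:12) {
    a <- paste(sample(alphabet, sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(3:6, 1), replace = TRUE), collapse = "")
    oracle <- enumerate_alignments(a, b, 2, -1, -2)
    impl <- enzact:::align_global(a, b, scoring)
    expect_equal(impl$score, oracle$score,
                 info = paste(a, b))
    expect_true(any(abs(impl$nmatch / impl$length - oracle$identities) < 1e-9),
                info = paste(a, b))
    expect_equal(global_identity(a, b, scoring), global_identity(b, a, scoring),
                 info = paste(a, b))
  }
})

test_that("nearest-train identity finds exact duplicates and matches exhaustive search", {
  recs <- toy_records(12L, len = 30L, seed = 42L)
  train <- recs[1:9, ]
  val <- recs[10:12, ]
  val$sequence[1] <- train$sequence[4]   # plant an exact duplicate
  out <- nearest_train_identity(val, train, prefilter_k = 9L)
  expect_equal(out$identity[1], 1.0)
  expect_equal(out$neighbor_id[1], train$record_id[4])
  # prefilter_k = |training set| equals exhaustive all-pairs maximum
  exhaustive <- vapply(val$sequence, function(s)
    max(vapply(train$sequence, function(t) global_identity(s, t), 0)), 0)
  expect_equal(out$identity, unname(exhaustive))
  expect_error(nearest_train_identity(val, train, prefilter_k = 0L),
               "prefilter_k")
})

test_that("the 3-mer TF-IDF prefilter ranks true near-duplicates first", {
  recs <- toy_records(8L, len = 40L, seed = 7L)
  vec <- tfidf_3mer(recs$sequence)
  V <- vec(recs$sequence)
  sims <- V %*% t(V)
  # every sequence is most similar to itself
  expect_equal(unname(apply(sims, 1L, which.max)), 1:8)
  expect_equal(unname(diag(sims)), rep(1, 8), tolerance = 1e-12)
})

test_that("identity-capped folds reduce to a plain partition when no pair reaches the cap", {
  recs <- toy_records(20L, len = 30L, seed = 9L)  # random: all identities low
  fold <- identity_capped_folds(recs, cap = 0.9, k = 5L, seed = 1L)
  expect_setequal(unique(fold), 1:5)
  expect_equal(as.vector(table(fold)), rep(4L, 5L))
  expect_equal(max(attr(fold, "clusters") == attr(fold, "clusters")[1]), 1L)
})

test_that("identity-capped folds pass the nearest-train identity audit", {
  # families of near-duplicates that must never straddle folds
  set.seed(77)
  base <- toy_records(6L, len = 40L, seed = 77L)
  make_variants <- function(seq, n) {
    vapply(seq_len(n), function(i) {
      ch <- strsplit(seq, "")[[1]]
      pos <- sample(40L, 2L)
      ch[pos] <- vapply(ch[pos], function(a)
        sample(setdiff(enzact:::AA_ALPHABET, a), 1L), "")
      paste(ch, collapse = "")
    }, "")
  }
  seqs <- unlist(lapply(base$sequence, make_variants, n = 4L))
  recs <- enzact:::make_seq_records(sprintf("v%02d", seq_along(seqs)), seqs)
  for (cap in c(0.70, 0.40)) {
    fold <- identity_capped_folds(recs, cap = cap, k = 3L, seed = 2L)
    for (f in unique(fold)) {
      audit <- nearest_train_identity(recs[fold == f, ], recs[fold != f, ],
                                      prefilter_k = nrow(recs))
      expect_true(all(audit$identity < cap), info = paste("cap", cap))
    }
  }
  # determinism for a fixed seed
  expect_identical(identity_capped_folds(recs, 0.7, k = 3L, seed = 2L),
                   identity_capped_folds(recs, 0.7, k = 3L, seed = 2L))
})

test_that("auxiliary NONE records are excluded before clustering", {
  recs <- toy_records(12L, len = 25L, seed = 13L)
  labels <- rep(c("HIGH", "LOW", "NONE"), each = 4L)
  expect_message(fold <- identity_capped_folds(recs, 0.9, k = 4L, seed = 1L,
                                               labels = labels),
                 "4 auxiliary NONE")
  expect_true(all(is.na(fold[labels == "NONE"])))
  expect_true(all(!is.na(fold[labels != "NONE"])))
})

test_that("an oversized identity cluster is rejected with advice", {
  seqs <- rep(paste(rep("AC", 15L), collapse = ""), 10L)
  recs <- enzact:::make_seq_records(paste0("r", 1:10), seqs)
  expect_error(identity_capped_folds(recs, cap = 0.5, k = 5L), "loosen")
})

test_that("grouped holdouts never split a species and balance fold sizes", {
  fam <- generate_family(family_spec(n_sequences = 50L, seed = 31L))
  recs <- fam$records
  fold <- grouped_holdout_folds(recs, "species", k = 5L, seed = 42L,
                                labels = fam$labels)
  # exhaustive membership check: no species string appears in two folds
  for (sp in unique(recs$species)) {
    expect_length(unique(fold[recs$species == sp]), 1L)
  }
  expect_setequal(unique(fold), 1:5)
  gfold <- grouped_holdout_folds(recs, "genus", k = 3L, seed = 42L)
  for (g in unique(recs$genus)) {
    expect_length(unique(gfold[recs$genus == g]), 1L)
  }
  expect_equal(formals(grouped_holdout_folds)$seed, 42L)
})

test_that("k groups over k folds is a bijection; too few groups is an error", {
  recs <- enzact:::make_seq_records(
    paste0("r", 1:6), vapply(1:6, function(i)
      paste(sample(enzact:::AA_ALPHABET, 10L, TRUE), collapse = ""), ""),
    species = rep(c("Aa x", "Bb y", "Cc z"), each = 2L))
  fold <- grouped_holdout_folds(recs, "species", k = 3L, seed = 1L)
  expect_setequal(unique(fold), 1:3)
  expect_equal(as.vector(table(fold)), rep(2L, 3L))
  expect_error(grouped_holdout_folds(recs, "species", k = 4L), "3 group")
})
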