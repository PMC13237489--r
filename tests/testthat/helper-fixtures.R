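# Shared fixtures. Everything is generated in code; heavyweight objects are
# built lazily once per test run and cached in this environment.
.fixture_env <- new.env(parent = emptyenv())

toy_records <- function(n = 6L, len = 20L, seed = 99L) {
  enzact:::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(enzact:::AA_ALPHABET, len, replace = TRUE), collapse = ""),
      "")
    enzact:::make_seq_records(sprintf("toy%02d", seq_len(n)), seqs,
                              species = sprintf("Genus%02d species01",
                                                ((seq_len(n) - 1L) %% 3L) + 1L))
  })
}

tiny_embedder <- function(dim = 16L, seed = 5L) {
  synthetic_embedder(dim = dim, window = 2L, seed = seed)
}

# A small trained model on an easy planted task, for attribution tests.
tiny_trained_model <- function() {
  if (!is.null(.fixture_env$tiny_model)) return(.fixture_env$tiny_model)
  spec <- family_spec(root_length = 60L, n_sequences = 70L, seed = 404L)
  ds <- generate_three_class_dataset(spec)
  emb <- embed_sequences(ds$records, tiny_embedder())
  folds <- stratified_kfold(ds$labels, k = 5L, seed = 1L)
  tr <- folds != 1L
  cfg <- enzact_config(num_blocks = 1L, n_heads = 4L, d_model = 16L,
                       dropout = 0)
  ck <- fit_transformer(emb[tr], ds$labels[tr], emb[!tr], ds$labels[!tr],
                        cfg, train_control(max_epochs = 6L, patience = 5L,
                                           seed = 2L))
  out <- list(checkpoint = ck, config = cfg, embeddings = emb,
              labels = ds$labels, records = ds$records)
  .fixture_env$tiny_model <- out
  out
}

# Brute-force global-alignment oracle: enumerate every alignment of two short
# sequences under a linear gap score, return the optimal score and the set of
# identities attained by optimal alignments.
enumerate_alignments <- function(a, b, match, mismatch, gap) {
  best <- new.env(parent = emptyenv())
  best$score <- -Inf; best$ids <- numeric(0)
  rec <- function(i, j, score, nmatch, len) {
    if (i > nchar(a) && j > nchar(b)) {
      if (score > best$score + 1e-9) {
        best$score <- score; best$ids <- nmatch / len
      } else if (abs(score - best$score) <= 1e-9) {
        best$ids <- unique(c(best$ids, nmatch / len))
      }
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      eq <- substr(a, i, i) == substr(b, j, j)
      rec(i + 1L, j + 1L, score + if (eq) match else mismatch,
          nmatch + eq, len + 1L)
    }
    if (i <= nchar(a)) rec(i + 1L, j, score + gap, nmatch, len + 1L)
    if (j <= nchar(b)) rec(i, j + 1L, score + gap, nmatch, len + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  list(score = best$score, identities = best$ids)
}

# Heavy shared fixture for the acceptance suite: the full planted-signal
# cross-validation (transformer + linear baseline) and the label-permutation
# stress test, computed once per test run.
acceptance_benchmark <- function() {
  if (!is.null(.fixture_env$acceptance)) return(.fixture_env$acceptance)
  ds <- generate_three_class_dataset(family_spec(seed = 11L))
  emb <- embed_sequences(ds$records, synthetic_embedder(dim = 64L, seed = 11L))
  cfg <- enzact_config(num_blocks = 1L, n_heads = 4L, d_model = 64L,
                       dropout = 0.1)
  fit <- enzact(emb, ds$labels, cfg,
                train_control(learning_rate = 2e-3, seed = 12L), k = 5L)
  cfg_lin <- enzact_config(num_blocks = 0L, d_model = 64L, dropout = 0.2,
                           prepool_input = TRUE)
  fit_lin <- enzact(emb, ds$labels, cfg_lin,
                    train_control(learning_rate = 1e-3, weight_decay = 5e-7,
                                  seed = 12L), k = 5L)
  keep <- ds$labels != "NONE"
  stress <- permutation_stress_test(pool_embeddings(emb[keep]),
                                    as.character(ds$labels[keep]),
                                    learner_multinom(), B = 100L, seed = 13L)
  out <- list(dataset = ds, embeddings = emb, fit = fit, fit_linear = fit_lin,
              stress = stress)
  .fixture_env$acceptance <- out
  out
}
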