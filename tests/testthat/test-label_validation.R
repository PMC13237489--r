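test_that("every permutation scheme preserves the global label multiset", {
  set.seed(21)
  labels <- sample(c("HIGH", "LOW"), 200L, replace = TRUE, prob = c(0.2, 0.8))
  covar <- list(length = sample(80:300, 200L, replace = TRUE),
                composition_pc = rnorm(200L))
  for (kind in c("GLOBAL", "LENGTH_BINNED", "DUAL_RESTRICTED")) {
    perm <- permute_labels(labels, permutation_scheme(kind), covar)
    expect_equal(sort(perm), sort(labels), info = kind)
  }
})

test_that("length-binned shuffling preserves the per-bin multiset", {
  set.seed(22)
  labels <- sample(c("HIGH", "LOW"), 150L, replace = TRUE)
  covar <- list(length = sample(50:500, 150L, replace = TRUE))
  perm <- permute_labels(labels, permutation_scheme("LENGTH_BINNED"), covar)
  strata <- attr(perm, "strata")
  expect_equal(length(unique(strata)), 10L)
  for (s in unique(strata)) {
    expect_equal(sort(perm[strata == s]), sort(labels[strata == s]))
  }
  # equal-frequency construction: bin sizes approximately equal
  expect_lte(diff(range(table(strata))), 3L)
})

test_that("the dual scheme partitions into 25 strata", {
  set.seed(23)
  labels <- sample(c("HIGH", "LOW"), 500L, replace = TRUE)
  covar <- list(length = runif(500L, 100, 400),
                composition_pc = rnorm(500L))
  perm <- permute_labels(labels, permutation_scheme("DUAL_RESTRICTED"), covar)
  expect_equal(length(unique(attr(perm, "strata"))), 25L)
})

test_that("composition PC scores are deterministic and match the closed form", {
  seqs <- c("AAAA", "AACC", "ACCC", "CCCC", "AAAC")
  s1 <- composition_first_pc(seqs)
  s2 <- composition_first_pc(seqs)
  expect_identical(s1, s2)
  expect_equal(s1[1], s1[1])
  # two-letter reduction: covariance has rank 1, leading eigenvector
  # proportional to (1, -1)/sqrt(2) on the A/C coordinates, so scores are
  # +/- sqrt(2) * (fA - mean(fA))
  fA <- c(1, 0.5, 0.25, 0, 0.75)
  expected <- sqrt(2) * (fA - mean(fA))
  expect_equal(abs(unname(s1)), abs(expected), tolerance = 1e-9)
  # identical sequences get identical scores
  expect_equal(composition_first_pc(c("ACD", "ACD", "WWW"))[1],
               composition_first_pc(c("ACD", "ACD", "WWW"))[2])
  expect_error(composition_first_pc(c("ACD", "")), "empty")
})

test_that("stress-test p-values follow the add-one empirical formula", {
  set.seed(24)
  # linearly separable toy problem: observed score beats every null
  n <- 60L
  y <- rep(c("HIGH", "LOW"), each = n / 2)
  X <- matrix(rnorm(n * 4L), n)
  X[y == "HIGH", 1] <- X[y == "HIGH", 1] + 6
  res <- permutation_stress_test(X, y, learner_multinom(), B = 9L, k = 3L,
                                 seed = 1L)
  expect_equal(res$p, 1 / 10)
  expect_length(res$null_scores, 9L)
  expect_equal(res$p, (sum(res$null_scores >= res$observed[["macro_f1"]]) + 1) /
                 (res$B + 1))
  expect_gte(res$p, 1 / (res$B + 1))  # p can never be 0
  expect_error(permutation_stress_test(X, y, learner_multinom(), B = 0L),
               "B must be")
})

test_that("pure-noise features give a large stress-test p-value", {
  set.seed(25)
  n <- 48L
  y <- rep(c("HIGH", "LOW"), each = n / 2)
  X <- matrix(rnorm(n * 3L), n)
  res <- permutation_stress_test(X, y, learner_multinom(), B = 19L, k = 3L,
                                 seed = 2L)
  expect_gte(res$p, 0.05)
})

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  set.seed(26)
  x <- round(rnorm(50L), 1)  # rounding forces ties
  pos <- sample(c(TRUE, FALSE), 50L, replace = TRUE)
  auc <- auc_mann_whitney(x, pos)
  wins <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    wins <- wins + (x[i] > x[j]) + 0.5 * (x[i] == x[j])
  }
  expect_equal(auc, wins / (sum(pos) * sum(!pos)), tolerance = 1e-12)
  expect_equal(rank_biserial_from_auc(auc), 2 * auc - 1)
})

test_that("pair agreement analysis matches the pair-counting oracle", {
  recs <- toy_records(12L, len = 20L, seed = 50L)
  labels <- rep(c("HIGH", "LOW"), 6L)
  ps <- pair_agreement_analysis(recs, labels, n_pairs = 50L, n_boot = 50L,
                                seed = 3L)
  expect_equal(ps$n_pairs, 50L)
  expect_setequal(unique(ps$pairs$pair_type),
                  c("high-high", "low-low", "high-low"))
  expect_equal(ps$pairs$same_label, ps$pairs$pair_type != "high-low")
  auc_oracle <- auc_mann_whitney(ps$pairs$identity, ps$pairs$same_label)
  expect_equal(ps$auc, auc_oracle)
  expect_equal(ps$rank_biserial, 2 * ps$auc - 1, tolerance = 1e-12)
  # requesting more pairs than exist caps with a warning
  small <- toy_records(4L, len = 10L, seed = 51L)
  expect_warning(psx <- pair_agreement_analysis(small, rep(c("HIGH", "LOW"), 2L),
                                                n_pairs = 100L, n_boot = 10L),
                 "capping")
  expect_equal(psx$n_pairs, 6L)
})

test_that("equal pair identities yield AUC 0.5 and permutation p of 1", {
  recs <- toy_records(8L, len = 15L, seed = 52L)
  labels <- rep(c("HIGH", "LOW"), 4L)
  ps <- pair_agreement_analysis(recs, labels, n_pairs = 20L, n_boot = 10L,
                                seed = 4L, identities = rep(0.3, 20L))
  expect_equal(ps$auc, 0.5)
  expect_equal(ps$rank_biserial, 0)
  pt <- pair_label_permutation(ps, labels, R = 50L, seed = 5L)
  expect_equal(unname(pt$p_two_sided[["auc"]]), 1)
  expect_error(pair_label_permutation(ps, labels, R = 0L), "R must be")
})

test_that("pair permutation p-values are roughly uniform under random labels", {
  # deterministic given the fixed seeds: empirical false-positive rate of
  # the AUC permutation test across synthetic null runs stays near 0.05
  reject <- vapply(1:40, function(run) {
    recs <- toy_records(10L, len = 12L, seed = 600L + run)
    labels <- enzact:::with_seed(700L + run,
                                 sample(rep(c("HIGH", "LOW"), 5L)))
    ps <- pair_agreement_analysis(recs, labels, n_pairs = 30L, n_boot = 2L,
                                  seed = run)
    pt <- pair_label_permutation(ps, labels, R = 59L, seed = 800L + run)
    pt$p_two_sided[["auc"]] < 0.05
  }, TRUE)
  expect_lte(mean(reject), 0.15)
})
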