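test_that("stratified folds partition indices with balanced class counts", {
  y <- rep(c("HIGH", "LOW"), c(20L, 80L))
  f <- stratified_kfold(y, k = 5L, seed = 1L)
  for (k in 1:5) {
    expect_equal(sum(y[f == k] == "HIGH"), 4L)
    expect_equal(sum(y[f == k] == "LOW"), 16L)
  }
  # pairwise disjoint and jointly exhaustive by construction of a vector
  expect_setequal(unique(f), 1:5)
  expect_length(f, 100L)
  # uneven class sizes still differ by at most one per fold
  y2 <- rep(c("HIGH", "LOW", "NONE"), c(23L, 41L, 17L))
  f2 <- stratified_kfold(y2, k = 5L, seed = 2L)
  for (cl in unique(y2)) {
    counts <- table(factor(f2[y2 == cl], levels = 1:5))
    expect_lte(max(counts) - min(counts), 1L)
  }
  expect_error(stratified_kfold(rep(c("HIGH", "LOW"), c(3L, 50L)), k = 5L),
               "HIGH")
  expect_equal(formals(stratified_kfold)$k, 5L)
})

test_that("the learning-rate schedule warms up linearly then decays exponentially", {
  base <- 2e-3
  expect_equal(lr_schedule(1, base), base / 5)
  expect_equal(lr_schedule(5, base), base)
  expect_equal(lr_schedule(6, base), base * 0.95)
  expect_equal(lr_schedule(10, base), base * 0.95^5)
})

test_that("classification metrics match an independent reference implementation", {
  # 12-item 3-class toy set; expected values frozen from an independent
  # implementation of the standard formulas
  truth <- c("HIGH", "HIGH", "LOW", "LOW", "LOW", "LOW", "NONE", "NONE",
             "NONE", "HIGH", "LOW", "NONE")
  pred <- c("HIGH", "LOW", "LOW", "LOW", "NONE", "HIGH", "NONE", "NONE",
            "LOW", "HIGH", "LOW", "NONE")
  m <- compute_metrics(pred, truth)
  expect_equal(m$accuracy, 0.6666667, tolerance = 1e-6)
  expect_equal(m$balanced_accuracy, 0.6722222, tolerance = 1e-6)
  expect_equal(m$macro_f1, 0.6722222, tolerance = 1e-6)
  expect_equal(m$mcc, 0.4893617, tolerance = 1e-6)
  expect_equal(m$per_class$f1, c(0.6666667, 0.6, 0.75), tolerance = 1e-6)
})

test_that("metrics handle perfect, no-information and rejected predictions", {
  y <- rep(c("HIGH", "LOW"), 6L)
  m <- compute_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$mcc, 1)
  m0 <- compute_metrics(rep("LOW", 12L), y)  # constant predictor, balanced
  expect_equal(m0$mcc, 0)
  pred <- c(y[1:10], "REJECTED", "REJECTED")
  expect_message(mr <- compute_metrics(pred, y), "2 rejected")
  expect_equal(mr$n, 10L)
  expect_error(compute_metrics(y, c(y[-1], "REJECTED")), "REJECTED")
})

test_that("metrics are invariant under consistent class renaming", {
  set.seed(40)
  truth <- sample(c("HIGH", "LOW", "NONE"), 60L, replace = TRUE)
  pred <- sample(c("HIGH", "LOW", "NONE"), 60L, replace = TRUE)
  ren <- c(HIGH = "NONE", LOW = "HIGH", NONE = "LOW")
  m1 <- compute_metrics(pred, truth)
  m2 <- compute_metrics(ren[pred], ren[truth])
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$macro_f1, m2$macro_f1)
  expect_equal(m1$mcc, m2$mcc)
})

test_that("rank correlations match brute-force pair counting with ties", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  rc <- rank_correlations(x, y)
  # O(n^2) concordant/discordant oracle (tau-b with tie corrections)
  nc <- 0; nd <- 0; tx <- 0; ty <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) nc <- nc + 1
    else nd <- nd + 1
  }
  tau_oracle <- (nc - nd) / sqrt((nc + nd + tx) * (nc + nd + ty))
  expect_equal(rc$kendall_tau, tau_oracle, tolerance = 1e-9)
  expect_equal(unname(unlist(rank_correlations(1:5, 1:5))), c(1, 1))
  expect_equal(unname(unlist(rank_correlations(1:5, 5:1))), c(-1, -1))
  expect_warning(rc0 <- rank_correlations(rep(1, 5), 1:5), "constant")
  expect_true(is.nan(rc0$spearman_rho))
})

test_that("hyperparameter search respects bounds and finds a planted optimum", {
  space <- hyperparameter_space()
  one <- search_hyperparameters(space, 1L, function(cfg) cfg$dropout,
                                seed = 3L)
  expect_equal(nrow(one$trials), 1L)
  expect_equal(one$best_value, one$trials$value[1])

  res <- search_hyperparameters(space, 100L, function(cfg) 0, seed = 4L)
  tr <- res$trials
  expect_true(all(tr$num_blocks >= 4L & tr$num_blocks <= 10L))
  expect_true(all(tr$learning_rate >= 1e-5 & tr$learning_rate <= 5e-3))
  expect_true(all(tr$dropout >= 0.1 & tr$dropout <= 0.7))
  expect_true(all(tr$weight_decay >= 1e-6 & tr$weight_decay <= 1e-2))
  expect_true(all(tr$n_heads %in% c(4L, 8L, 16L)))
  expect_true(all(tr$tau_high >= 0.3 & tr$tau_high <= 0.9))

  # quadratic toy objective in log learning rate, optimum at 1e-4
  obj <- function(cfg) -(log10(cfg$learning_rate) + 4)^2
  big <- search_hyperparameters(space, 300L, obj, seed = 5L)
  expect_lt(abs(log10(big$best_config$learning_rate) + 4), 0.15)
  # failing trials are recorded and skipped
  flaky <- search_hyperparameters(space, 10L, function(cfg) {
    if (cfg$dropout > 0.4) stop("boom") else cfg$dropout
  }, seed = 6L)
  expect_true(any(flaky$trials$failed))
  expect_true(flaky$best_value <= 0.4)
})

test_that("fold training honors early stopping and returns the best checkpoint", {
  tm <- tiny_trained_model()
  ck <- tm$checkpoint
  expect_equal(ck$best_val_macro_f1, max(ck$history$val_macro_f1))
  expect_lte(nrow(ck$history),
             ck$best_epoch + formals(train_control)$patience)
  expect_error(fit_transformer(list(), character(0), list(), character(0)),
               "empty training split")
})

test_that("class weights default to normalized inverse fold frequency", {
  w <- enzact:::default_class_weights(c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))
  expect_equal(mean(w), 1)
  expect_equal(w[1] / w[2], 2)  # class 2 twice as frequent as class 1
})
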