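random_input <- function(L = 6L, d = 8L, seed = 1L) {
  enzact:::with_seed(seed, matrix(rnorm(L * d), L, d))
}

test_that("the forward pass returns a valid 3-class posterior", {
  cfg <- enzact_config(num_blocks = 2L, n_heads = 2L, d_model = 8L,
                       dropout = 0)
  m <- build_variant(cfg, seed = 2L)
  out <- enzact:::model_forward(m, random_input())
  expect_length(out$probs, 3L)
  expect_true(all(out$probs >= 0))
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
})

test_that("attention rows are probability distributions; L = 1 gives [[1]]", {
  cfg <- enzact_config(num_blocks = 2L, n_heads = 2L, d_model = 8L,
                       dropout = 0)
  m <- build_variant(cfg, seed = 3L)
  out <- enzact:::model_forward(m, random_input(L = 7L), return_attention = TRUE)
  for (arr in out$attention) {
    for (h in seq_len(dim(arr)[1])) {
      expect_equal(rowSums(arr[h, , ]), rep(1, 7L), tolerance = 1e-8)
      expect_true(all(arr[h, , ] >= 0))
    }
  }
  cfg1 <- enzact_config(num_blocks = 1L, n_heads = 1L, d_model = 8L,
                        dropout = 0)
  m1 <- build_variant(cfg1, seed = 3L)
  out1 <- enzact:::model_forward(m1, random_input(L = 1L),
                                 return_attention = TRUE)
  expect_equal(out1$attention[[1]][1, , , drop = TRUE], 1)
})

test_that("with no dropout the pooled posterior is invariant to residue permutation", {
  cfg <- enzact_config(num_blocks = 2L, n_heads = 2L, d_model = 8L,
                       dropout = 0)
  m <- build_variant(cfg, seed = 4L)
  X <- random_input(L = 9L)
  p1 <- enzact:::model_forward(m, X)$probs
  p2 <- enzact:::model_forward(m, X[sample(9L), ])$probs
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("forward is deterministic with dropout 0 and rejects bad inputs", {
  cfg <- enzact_config(num_blocks = 1L, n_heads = 2L, d_model = 8L,
                       dropout = 0)
  m <- build_variant(cfg, seed = 5L)
  X <- random_input()
  expect_identical(enzact:::model_forward(m, X)$probs,
                   enzact:::model_forward(m, X)$probs)
  expect_error(enzact:::model_forward(m, random_input(d = 6L)),
               "does not match d_model")
  bad <- enzact:::residue_embedding("x", X, rep(FALSE, 6L))
  expect_error(enzact:::model_forward(m, bad), "all-false")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(focal_loss(p, 2L, gamma = 0), -log(0.5))
  expect_equal(focal_loss(c(0, 1, 0), 2L), 0)
  expect_equal(focal_loss(c(0.25, 0.5, 0.25), 2L, gamma = 2),
               0.25 * log(2), tolerance = 1e-12)  # 0.25 ln 2 ~ 0.17329
  expect_gte(focal_loss(c(1e-12, 0.5, 0.5), 1L), 0)  # clamped, finite
  # monotone decreasing in the true-class probability
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(q)
    focal_loss(c(q, (1 - q) / 2, (1 - q) / 2), 1L), 0)
  expect_true(all(diff(ls) < 0))
})

test_that("the decision rule rejects, gates HIGH, and breaks ties toward LOW", {
  rej <- decision_rule(tau_high = 0.5, reject_below = 0.55)
  expect_equal(as.character(decide(c(0.30, 0.35, 0.35), rej)), "REJECTED")
  expect_equal(as.character(decide(c(0.70, 0.2, 0.1),
                                   decision_rule(tau_high = 0.65))), "HIGH")
  expect_equal(as.character(decide(c(0, 1, 0), decision_rule())), "LOW")
  expect_equal(as.character(decide(c(0, 0, 1), decision_rule())), "NONE")
  expect_equal(as.character(decide(c(0.2, 0.4, 0.4), decision_rule())), "LOW")
  expect_error(decision_rule(tau_high = 0.95))
})

test_that("depth 0 with a linear head reduces to a linear model on the pooled embedding", {
  cfg <- enzact_config(num_blocks = 0L, n_heads = 2L, d_model = 8L,
                       dropout = 0)
  m <- build_variant(cfg, seed = 6L)
  X <- random_input(L = 5L)
  out <- enzact:::model_forward(m, X)
  pooled <- colMeans(X)
  logits <- drop(pooled %*% m$params$head$Wh) + m$params$head$bh
  expect_equal(out$logits, logits, tolerance = 1e-12)
})

test_that("all ablation variants are constructible and behave structurally", {
  for (depth in c(0L, 1L, 3L, 5L)) {
    m <- build_variant(enzact_config(num_blocks = depth, n_heads = 4L,
                                     d_model = 16L, dropout = 0.1), seed = 1L)
    expect_length(m$params$blocks, depth)
  }
  # attention-free variant retains residual connections: with near-zero
  # sublayer weights the block output stays close to its input signal
  mf <- build_variant(enzact_config(num_blocks = 5L, n_heads = 4L,
                                    d_model = 16L, dropout = 0,
                                    attention_enabled = FALSE), seed = 1L)
  expect_true(all(c("Wa1", "Wa2") %in% names(mf$params$blocks[[1]])))
  expect_false("Wq" %in% names(mf$params$blocks[[1]]))
  # prepool variant: head only, incompatible with encoder blocks
  expect_error(enzact_config(num_blocks = 5L, prepool_input = TRUE),
               "incompatible")
  mp <- build_variant(enzact_config(num_blocks = 0L, d_model = 16L,
                                    prepool_input = TRUE), seed = 1L)
  out <- enzact:::model_forward(mp, random_input(L = 4L, d = 16L))
  expect_equal(sum(out$probs), 1, tolerance = 1e-8)
  expect_error(enzact_config(n_heads = 16L, d_model = 20L), "divisible")
})

test_that("backpropagated gradients match finite differences and reach every block", {
  cfg <- enzact_config(num_blocks = 2L, n_heads = 2L, d_model = 8L,
                       dropout = 0, head_type = "mlp", mlp_hidden = 6L)
  m <- build_variant(cfg, seed = 7L)
  X <- random_input(L = 4L, seed = 11L)
  w <- c(1.3, 0.7, 1.0)
  fwd <- enzact:::model_forward(m, X, return_cache = TRUE)
  bk <- enzact:::model_backward(m, fwd,
                                enzact:::focal_loss_grad(fwd$probs, 2L, 2, w))
  loss_at <- function(model) focal_loss(enzact:::model_forward(model, X)$probs,
                                        2L, 2, w)
  eps <- 1e-6
  # input gradient
  set.seed(8)
  for (k in sample(length(X), 6L)) {
    Xp <- X; Xp[k] <- Xp[k] + eps
    Xm <- X; Xm[k] <- Xm[k] - eps
    mp <- m
    num <- (focal_loss(enzact:::model_forward(m, Xp)$probs, 2L, 2, w) -
              focal_loss(enzact:::model_forward(m, Xm)$probs, 2L, 2, w)) /
      (2 * eps)
    expect_equal(bk$dX[k], num, tolerance = 1e-5)
  }
  # one sampled entry of every parameter tensor in every block and the head
  for (b in seq_along(m$params$blocks)) {
    for (nm in names(m$params$blocks[[b]])) {
      g <- bk$grads$blocks[[b]][[nm]]
      expect_false(all(g == 0))  # gradient flows: no dead sublayer
      k <- which.max(abs(g))
      mp <- m; mp$params$blocks[[b]][[nm]][k] <-
        mp$params$blocks[[b]][[nm]][k] + eps
      mm <- m; mm$params$blocks[[b]][[nm]][k] <-
        mm$params$blocks[[b]][[nm]][k] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-5)
    }
  }
  for (nm in names(m$params$head)) {
    g <- bk$grads$head[[nm]]
    k <- which.max(abs(g))
    mp <- m; mp$params$head[[nm]][k] <- mp$params$head[[nm]][k] + eps
    mm <- m; mm$params$head[[nm]][k] <- mm$params$head[[nm]][k] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})
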