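#' Transformer classifier configuration
#'
#' Architecture of the residue-level activity classifier: a stack of
#' pre-normalized transformer encoder blocks (layer norm, multihead
#' self-attention, dropout, residual; then layer norm, position-wise
#' feed-forward expanded by `ffn_multiplier`, dropout, residual), mean
#' pooling over residues, and a classification head with 3 outputs
#' (`HIGH`, `LOW`, `NONE`).  No positional encoding is added: the
#' contextual embedder already carries local order, and the pooled
#' posterior is therefore invariant to residue permutation.
#'
#' Ablation variants are expressed through the same configuration:
#' `num_blocks = 0` with a linear head reduces to a linear model on the
#' pooled embedding; `head_type = "mlp"` gives a 2-hidden-layer
#' 512-unit head; `attention_enabled = FALSE` replaces each attention
#' sublayer with a position-wise feed-forward sublayer while retaining
#' residual connections; `prepool_input = TRUE` mean-pools the residue
#' embeddings before the head (blocks are not applied).
#'
#' @param num_blocks Number of encoder blocks (>= 0; 5 in the reference
#'   architecture).
#' @param n_heads Attention heads, one of 4, 8, 16; must divide `d_model`.
#' @param d_model Embedding/model width (1152 for the default embedder).
#' @param ffn_multiplier Feed-forward expansion factor (4).
#' @param dropout Dropout probability in `[0, 1)`.
#' @param head_type `"linear"` or `"mlp"`.
#' @param attention_enabled Use self-attention sublayers (`TRUE`) or
#'   feed-forward-only sublayers (`FALSE`).
#' @param prepool_input Mean-pool the input before the head (input
#'   granularity ablation); incompatible with `num_blocks > 0`.
#' @param mlp_hidden Hidden width of the MLP head.
#' @return A validated `enzact_config` object.
#' @export
enzact_config <- function(num_blocks = 5L, n_heads = 16L, d_model = 1152L,
                          ffn_multiplier = 4L, dropout = 0.1,
                          head_type = c("linear", "mlp"),
                          attention_enabled = TRUE, prepool_input = FALSE,
                          mlp_hidden = 512L) {
  head_type <- match.arg(head_type)
  num_blocks <- as.integer(num_blocks)
  stopifnot(num_blocks >= 0L, n_heads %in% c(1L, 2L, 4L, 8L, 16L),
            d_model >= 1L, dropout >= 0, dropout < 1)
  if (d_model %% n_heads != 0L) {
    stop("d_model must be divisible by n_heads")
  }
  if (prepool_input && num_blocks > 0L) {
    stop("prepool_input is incompatible with encoder blocks: set num_blocks = 0")
  }
  structure(list(num_blocks = num_blocks, n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 ffn_multiplier = as.integer(ffn_multiplier),
                 dropout = dropout, head_type = head_type,
                 attention_enabled = attention_enabled,
                 prepool_input = prepool_input,
                 mlp_hidden = as.integer(mlp_hidden),
                 n_classes = 3L),
            class = "enzact_config")
}

#' Build an (untrained) model variant from a configuration
#'
#' Initializes parameters for the requested architecture variant with
#' Glorot-scaled random weights.
#'
#' @param config An [enzact_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `enzact_model`: list with `config` and `params`.
#' @export
build_variant <- function(config, seed = 1L) {
  stopifnot(inherits(config, "enzact_config"))
  params <- with_seed(seed, init_params(config))
  structure(list(config = config, params = params), class = "enzact_model")
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

init_params <- function(config) {
  d <- config$d_model
  dff <- d * config$ffn_multiplier
  blocks <- if (config$prepool_input) list() else
    lapply(seq_len(config$num_blocks), function(b) {
      blk <- list(ln1_g = rep(1, d), ln1_b = rep(0, d),
                  ln2_g = rep(1, d), ln2_b = rep(0, d),
                  W1 = glorot(d, dff), b1 = rep(0, dff),
                  W2 = glorot(dff, d), b2 = rep(0, d))
      if (config$attention_enabled) {
        blk <- c(blk, list(Wq = glorot(d, d), bq = rep(0, d),
                           Wk = glorot(d, d), bk = rep(0, d),
                           Wv = glorot(d, d), bv = rep(0, d),
                           Wo = glorot(d, d), bo = rep(0, d)))
      } else {
        # Attention-free ablation: a second position-wise FFN sublayer.
        blk <- c(blk, list(Wa1 = glorot(d, dff), ba1 = rep(0, dff),
                           Wa2 = glorot(dff, d), ba2 = rep(0, d)))
      }
      blk
    })
  head <- if (config$head_type == "linear") {
    list(Wh = glorot(d, config$n_classes), bh = rep(0, config$n_classes))
  } else {
    m <- config$mlp_hidden
    list(Wm1 = glorot(d, m), bm1 = rep(0, m),
         Wm2 = glorot(m, m), bm2 = rep(0, m),
         Wh = glorot(m, config$n_classes), bh = rep(0, config$n_classes))
  }
  list(blocks = blocks, head = head)
}

## ---- numeric primitives ----------------------------------------------------

add_rowvec <- function(X, v) t(t(X) + v)
mul_rowvec <- function(X, v) t(t(X) * v)

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + 1e-5)
  xhat <- xc * inv
  list(out = add_rowvec(mul_rowvec(xhat, g), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- mul_rowvec(dY, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

attn_forward <- function(h, blk, H) {
  d <- ncol(h); dh <- d %/% H; scal <- 1 / sqrt(dh)
  Q <- add_rowvec(h %*% blk$Wq, blk$bq)
  K <- add_rowvec(h %*% blk$Wk, blk$bk)
  V <- add_rowvec(h %*% blk$Wv, blk$bv)
  C <- matrix(0, nrow(h), d)
  A_list <- vector("list", H)
  for (i in seq_len(H)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) * scal)
    A_list[[i]] <- A
    C[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  list(out = add_rowvec(C %*% blk$Wo, blk$bo),
       h = h, Q = Q, K = K, V = V, C = C, A = A_list, scal = scal)
}

attn_backward <- function(dout, cache, blk, H) {
  d <- ncol(dout); dh <- d %/% H
  g <- list(Wo = crossprod(cache$C, dout), bo = colSums(dout))
  dC <- dout %*% t(blk$Wo)
  dQ <- matrix(0, nrow(dout), d); dK <- dQ; dV <- dQ
  for (i in seq_len(H)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    A <- cache$A[[i]]
    dCi <- dC[, cols, drop = FALSE]
    Vi <- cache$V[, cols, drop = FALSE]
    dA <- dCi %*% t(Vi)
    dV[, cols] <- crossprod(A, dCi)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] * cache$scal
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) * cache$scal
  }
  g$Wq <- crossprod(cache$h, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$h, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$h, dV); g$bv <- colSums(dV)
  dh_ <- dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) + dV %*% t(blk$Wv)
  list(dh = dh_, grads = g)
}

ffn_forward <- function(h, W1, b1, W2, b2) {
  upre <- add_rowvec(h %*% W1, b1)
  u <- pmax(upre, 0)
  list(out = add_rowvec(u %*% W2, b2), h = h, u = u, act = upre > 0)
}

ffn_backward <- function(dy, cache, W1, W2) {
  g <- list(W2 = crossprod(cache$u, dy), b2 = colSums(dy))
  du <- (dy %*% t(W2)) * cache$act
  g$W1 <- crossprod(cache$h, du); g$b1 <- colSums(du)
  list(dh = du %*% t(W1), grads = g)
}

dropout_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL, p = p))
  mask <- matrix(runif(length(X)) >= p, nrow(X), ncol(X))
  list(out = X * mask / (1 - p), mask = mask, p = p)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) return(dY)
  dY * cache$mask / (1 - cache$p)
}

## ---- forward / backward ----------------------------------------------------

#' Forward pass of the classifier
#'
#' Maps one residue embedding to the 3-class posterior.  Masked rows are
#' dropped at entry (the model has no positional encoding, so dropping a
#' padded row is exactly equivalent to masking it out of attention and
#' pooling).
#'
#' @param model An `enzact_model` (see [build_variant()]).
#' @param embedding A `residue_embedding` or an `L x D` matrix.
#' @param train Apply dropout (training mode).
#' @param return_attention Capture per-block, per-head attention matrices.
#' @param return_cache Keep intermediate activations for [model_backward()].
#' @return List with `logits`, `probs` (length 3, sums to 1), optionally
#'   `attention` (list over blocks of `H x L x L` arrays) and `cache`.
#' @export
model_forward <- function(model, embedding, train = FALSE,
                          return_attention = FALSE, return_cache = FALSE) {
  config <- model$config; params <- model$params
  X <- if (inherits(embedding, "residue_embedding")) {
    if (!any(embedding$mask)) stop("embedding mask is all-false")
    embedding$mat[embedding$mask, , drop = FALSE]
  } else embedding
  if (ncol(X) != config$d_model) {
    stop(sprintf("embedding dimension %d does not match d_model %d",
                 ncol(X), config$d_model))
  }
  caches <- list()
  attn_out <- if (return_attention) list() else NULL
  if (config$prepool_input) {
    pooled <- colMeans(X)
    L <- nrow(X)
  } else {
    for (b in seq_along(params$blocks)) {
      blk <- params$blocks[[b]]
      ln1 <- ln_forward(X, blk$ln1_g, blk$ln1_b)
      sub1 <- if (config$attention_enabled) {
        attn_forward(ln1$out, blk, config$n_heads)
      } else {
        ffn_forward(ln1$out, blk$Wa1, blk$ba1, blk$Wa2, blk$ba2)
      }
      if (return_attention && config$attention_enabled) {
        L <- nrow(X)
        arr <- array(0, c(config$n_heads, L, L))
        for (i in seq_len(config$n_heads)) arr[i, , ] <- sub1$A[[i]]
        attn_out[[b]] <- arr
      }
      do1 <- dropout_forward(sub1$out, config$dropout, train)
      X1 <- X + do1$out
      ln2 <- ln_forward(X1, blk$ln2_g, blk$ln2_b)
      ff <- ffn_forward(ln2$out, blk$W1, blk$b1, blk$W2, blk$b2)
      do2 <- dropout_forward(ff$out, config$dropout, train)
      X2 <- X1 + do2$out
      caches[[b]] <- list(ln1 = ln1, sub1 = sub1, do1 = do1,
                          ln2 = ln2, ff = ff, do2 = do2)
      X <- X2
    }
    pooled <- colMeans(X)
    L <- nrow(X)
  }
  hp <- params$head
  if (config$head_type == "linear") {
    logits <- drop(pooled %*% hp$Wh) + hp$bh
    head_cache <- list(pooled = pooled)
  } else {
    z1pre <- drop(pooled %*% hp$Wm1) + hp$bm1
    z1 <- pmax(z1pre, 0)
    d1 <- dropout_forward(matrix(z1, 1L), config$dropout, train)
    z1d <- drop(d1$out)
    z2pre <- drop(z1d %*% hp$Wm2) + hp$bm2
    z2 <- pmax(z2pre, 0)
    d2 <- dropout_forward(matrix(z2, 1L), config$dropout, train)
    z2d <- drop(d2$out)
    logits <- drop(z2d %*% hp$Wh) + hp$bh
    head_cache <- list(pooled = pooled, z1 = z1, z1pre = z1pre, d1 = d1,
                       z1d = z1d, z2 = z2, z2pre = z2pre, d2 = d2, z2d = z2d)
  }
  m <- max(logits)
  probs <- exp(logits - m); probs <- probs / sum(probs)
  out <- list(logits = logits, probs = probs)
  if (return_attention) out$attention <- attn_out
  if (return_cache) out$cache <- list(blocks = caches, head = head_cache, L = L)
  out
}

# Backward pass from a gradient on the logits; returns parameter gradients
# (same tree shape as params) and the gradient on the input matrix.
model_backward <- function(model, fwd, dlogits) {
  config <- model$config; params <- model$params
  cache <- fwd$cache
  hp <- params$head
  grads <- list(blocks = vector("list", length(params$blocks)), head = list())
  hc <- cache$head
  if (config$head_type == "linear") {
    grads$head$Wh <- outer(hc$pooled, dlogits)
    grads$head$bh <- dlogits
    dpooled <- drop(hp$Wh %*% dlogits)
  } else {
    grads$head$Wh <- outer(hc$z2d, dlogits)
    grads$head$bh <- dlogits
    dz2d <- drop(hp$Wh %*% dlogits)
    dz2 <- drop(dropout_backward(matrix(dz2d, 1L), hc$d2)) * (hc$z2pre > 0)
    grads$head$Wm2 <- outer(hc$z1d, dz2)
    grads$head$bm2 <- dz2
    dz1d <- drop(hp$Wm2 %*% dz2)
    dz1 <- drop(dropout_backward(matrix(dz1d, 1L), hc$d1)) * (hc$z1pre > 0)
    grads$head$Wm1 <- outer(hc$pooled, dz1)
    grads$head$bm1 <- dz1
    dpooled <- drop(hp$Wm1 %*% dz1)
  }
  L <- cache$L
  dX <- matrix(rep(dpooled / L, each = L), nrow = L)
  if (!config$prepool_input) {
    for (b in rev(seq_along(params$blocks))) {
      blk <- params$blocks[[b]]
      cb <- cache$blocks[[b]]
      # sublayer 2 (FFN)
      dff_out <- dropout_backward(dX, cb$do2)
      fb <- ffn_backward(dff_out, cb$ff, blk$W1, blk$W2)
      lb2 <- ln_backward(fb$dh, cb$ln2, blk$ln2_g)
      dX1 <- dX + lb2$dX
      # sublayer 1 (attention or FFN)
      dsub_out <- dropout_backward(dX1, cb$do1)
      if (config$attention_enabled) {
        ab <- attn_backward(dsub_out, cb$sub1, blk, config$n_heads)
        lb1 <- ln_backward(ab$dh, cb$ln1, blk$ln1_g)
        g1 <- ab$grads
      } else {
        ab <- ffn_backward(dsub_out, cb$sub1, blk$Wa1, blk$Wa2)
        lb1 <- ln_backward(ab$dh, cb$ln1, blk$ln1_g)
        g1 <- list(Wa1 = ab$grads$W1, ba1 = ab$grads$b1,
                   Wa2 = ab$grads$W2, ba2 = ab$grads$b2)
      }
      dX <- dX1 + lb1$dX
      gb <- c(list(ln1_g = lb1$dg, ln1_b = lb1$db,
                   ln2_g = lb2$dg, ln2_b = lb2$db,
                   W1 = fb$grads$W1, b1 = fb$grads$b1,
                   W2 = fb$grads$W2, b2 = fb$grads$b2),
              g1)
      # align to the parameter tree order: tree_map pairs by position
      grads$blocks[[b]] <- gb[names(params$blocks[[b]])]
    }
  }
  grads$head <- grads$head[names(params$head)]
  list(grads = grads, dX = dX)
}

## ---- loss and decision -----------------------------------------------------

#' Focal loss
#'
#' `loss = -w_c (1 - p_c)^gamma log(p_c)` for true class `c`, averaged over
#' the batch.  With `gamma = 0` and unit weights this reduces to
#' cross-entropy.  Probabilities are clamped at `eps` before the log.
#'
#' @param probs Numeric vector of 3 class probabilities, or an `n x 3`
#'   matrix for a batch.
#' @param true_class Integer class index (1-based) or vector thereof.
#' @param gamma Focusing exponent (>= 0; 2 in the reference setup).
#' @param weights Per-class nonnegative weights (length 3).
#' @param eps Probability clamp.
#' @return Nonnegative scalar loss.
#' @export
focal_loss <- function(probs, true_class, gamma = 2, weights = c(1, 1, 1),
                       eps = 1e-8) {
  stopifnot(gamma >= 0, all(is.finite(weights)))
  if (is.matrix(probs)) {
    pc <- probs[cbind(seq_len(nrow(probs)), true_class)]
  } else {
    pc <- probs[true_class]
  }
  pc <- pmax(pc, eps)
  mean(-weights[true_class] * (1 - pc)^gamma * log(pc))
}

# Gradient of the focal loss of one sample with respect to the logits.
focal_loss_grad <- function(probs, true_class, gamma, weights, eps = 1e-8) {
  pc <- max(probs[true_class], eps)
  w <- weights[true_class]
  dldp <- w * gamma * (1 - pc)^(max(gamma - 1, 0)) * log(pc) -
    w * (1 - pc)^gamma / pc
  onehot <- numeric(length(probs)); onehot[true_class] <- 1
  dldp * pc * (onehot - probs)
}

#' Thresholded / rejecting decision rule
#'
#' @param tau_high Decision threshold for the `HIGH` class, in
#'   `[0.3, 0.9]` (treated as a tunable hyperparameter because `HIGH` is
#'   the minority class of practical interest).
#' @param reject_below When non-`NULL`, predictions whose maximum class
#'   probability falls below this value are withheld (`REJECTED`, the -1
#'   label); 0.55 in the ablation setup.
#' @return A `decision_rule` object.
#' @export
decision_rule <- function(tau_high = 0.5, reject_below = NULL) {
  stopifnot(tau_high >= 0.3, tau_high <= 0.9)
  if (!is.null(reject_below)) stopifnot(reject_below > 0, reject_below < 1)
  structure(list(tau_high = tau_high, reject_below = reject_below),
            class = "decision_rule")
}

#' Apply a decision rule to class probabilities
#'
#' If rejection is enabled and the maximum probability is below the
#' rejection floor the prediction is `REJECTED`; otherwise `HIGH` when
#' `p_HIGH >= tau_high`, else the argmax over `LOW`/`NONE` with exact
#' ties broken toward `LOW`.
#'
#' @param probs Length-3 vector or `n x 3` matrix (columns HIGH, LOW,
#'   NONE).
#' @param rule A [decision_rule()].
#' @return Factor with levels `HIGH`, `LOW`, `NONE`, `REJECTED`.
#' @export
decide <- function(probs, rule = decision_rule()) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  stopifnot(ncol(probs) == 3L)
  out <- character(nrow(probs))
  for (i in seq_len(nrow(probs))) {
    p <- probs[i, ]
    if (!is.null(rule$reject_below) && max(p) < rule$reject_below) {
      out[i] <- "REJECTED"
    } else if (p[1] >= rule$tau_high) {
      out[i] <- "HIGH"
    } else {
      out[i] <- if (p[2] >= p[3]) "LOW" else "NONE"
    }
  }
  factor(out, levels = c(ACTIVITY_LEVELS, "REJECTED"))
}

## ---- parameter-tree utilities ---------------------------------------------

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- tree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)
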