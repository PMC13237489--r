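#' Training configuration
#'
#' Optimization settings for the classifier: Adam or AdamW with focal
#' loss, a learning-rate schedule with `warmup_steps` linear warm-up
#' steps followed by exponential decay of `decay_per_step` per scheduler
#' step (the trainer steps the scheduler once per epoch), and early
#' stopping on validation Macro-F1 with the given patience.
#'
#' @param learning_rate Base learning rate.
#' @param weight_decay Weight decay (decoupled for `adamw`, L2 for
#'   `adam`).
#' @param optimizer_kind `"adam"` or `"adamw"`.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs (< `max_epochs`).
#' @param warmup_steps Linear warm-up scheduler steps.
#' @param decay_per_step Multiplicative decay per scheduler step after
#'   warm-up.
#' @param gamma Focal-loss exponent.
#' @param class_weights Per-class loss weights; `NULL` means inverse
#'   class frequency of the training fold, normalized to mean 1.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `train_control` object.
#' @export
train_control <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                          optimizer_kind = c("adamw", "adam"),
                          batch_size = 16L, max_epochs = 50L, patience = 5L,
                          warmup_steps = 5L, decay_per_step = 0.95,
                          gamma = 2, class_weights = NULL, seed = 1L,
                          verbose = FALSE) {
  optimizer_kind <- match.arg(optimizer_kind)
  stopifnot(learning_rate > 0, weight_decay >= 0, patience < max_epochs,
            gamma >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 optimizer_kind = optimizer_kind,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 warmup_steps = as.integer(warmup_steps),
                 decay_per_step = decay_per_step, gamma = gamma,
                 class_weights = class_weights, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Learning-rate schedule
#'
#' Linear warm-up for `warmup` steps (reaching the base rate exactly at
#' step `warmup`), then multiplication by `decay` for every further step:
#' at step `warmup + 1` the rate is `base * decay`.
#'
#' @param step Scheduler step (1-based).
#' @param base Base learning rate.
#' @param warmup Number of warm-up steps.
#' @param decay Decay factor per post-warm-up step.
#' @return The learning rate at `step`.
#' @export
lr_schedule <- function(step, base, warmup = 5L, decay = 0.95) {
  ifelse(step <= warmup, base * step / warmup,
         base * decay^(step - warmup))
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay, kind,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  if (kind == "adam" && weight_decay > 0) {
    grads <- tree_map(function(g, p) g + weight_decay * p, grads, params)
  }
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  upd <- tree_map(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  params <- tree_map(function(p, u) p - lr * u, params, upd)
  if (kind == "adamw" && weight_decay > 0) {
    params <- tree_map(function(p) p * (1 - lr * weight_decay), params)
  }
  list(params = params, state = state)
}

label_to_int <- function(y) {
  ints <- match(as.character(y), ACTIVITY_LEVELS)
  if (anyNA(ints)) stop("labels must be HIGH, LOW or NONE for training")
  ints
}

default_class_weights <- function(y_int, n_classes = 3L) {
  counts <- tabulate(y_int, nbins = n_classes)
  w <- ifelse(counts > 0, 1 / counts, 0)
  present <- counts > 0
  w[present] <- w[present] / mean(w[present])  # normalize to mean 1
  w[!present] <- 1
  w
}

#' Train the classifier on one train/validation fold
#'
#' Minibatch training with focal loss and the configured optimizer and
#' schedule; after each epoch the validation Macro-F1 (argmax decisions)
#' is evaluated, and the parameters with the best validation score are
#' returned.  Training stops early after `patience` epochs without
#' improvement.
#'
#' @param x_train,x_val Lists of `residue_embedding` objects (or `L x D`
#'   matrices).
#' @param y_train,y_val Labels in `HIGH`/`LOW`/`NONE`.
#' @param config An [enzact_config()].
#' @param control A [train_control()].
#' @return An `enzact_checkpoint`: `config`, `params` (best epoch),
#'   `history` data frame, `best_epoch`, `best_val_macro_f1`,
#'   `class_weights`.
#' @export
fit_transformer <- function(x_train, y_train, x_val, y_val,
                            config = enzact_config(),
                            control = train_control()) {
  if (length(x_train) == 0L) stop("empty training split")
  stopifnot(length(x_train) == length(y_train),
            length(x_val) == length(y_val))
  yt <- label_to_int(y_train)
  yv <- label_to_int(y_val)
  w <- control$class_weights %||% default_class_weights(yt)

  set.seed(control$seed)
  model <- list(config = config, params = init_params(config))
  class(model) <- "enzact_model"
  state <- adam_init(model$params)

  best <- list(val = -Inf, params = model$params, epoch = 0L)
  since_improve <- 0L
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_macro_f1 = numeric(0))
  n <- length(x_train)
  for (epoch in seq_len(control$max_epochs)) {
    lr <- lr_schedule(epoch, control$learning_rate,
                      control$warmup_steps, control$decay_per_step)
    ord <- sample.int(n)
    epoch_loss <- 0
    starts <- seq(1L, n, by = control$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1L, n)]
      gacc <- NULL
      bloss <- 0
      for (i in idx) {
        fwd <- model_forward(model, x_train[[i]], train = TRUE,
                             return_cache = TRUE)
        bloss <- bloss + focal_loss(fwd$probs, yt[i], control$gamma, w)
        dlog <- focal_loss_grad(fwd$probs, yt[i], control$gamma, w)
        bk <- model_backward(model, fwd, dlog)
        gacc <- if (is.null(gacc)) bk$grads else
          tree_map(`+`, gacc, bk$grads)
      }
      gacc <- tree_map(function(g) g / length(idx), gacc)
      res <- adam_step(model$params, gacc, state, lr,
                       control$weight_decay, control$optimizer_kind)
      model$params <- res$params
      state <- res$state
      epoch_loss <- epoch_loss + bloss
    }
    val_probs <- t(vapply(x_val, function(x)
      model_forward(model, x)$probs, numeric(3)))
    val_pred <- decide(val_probs, decision_rule(tau_high = 0.5))
    val_f1 <- compute_metrics(val_pred, factor(ACTIVITY_LEVELS[yv],
                                               levels = ACTIVITY_LEVELS))$macro_f1
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = epoch_loss / n,
                                         val_macro_f1 = val_f1))
    if (control$verbose) {
      message(sprintf("epoch %2d lr %.2e loss %.4f val macro-F1 %.4f",
                      epoch, lr, epoch_loss / n, val_f1))
    }
    if (val_f1 > best$val) {
      best <- list(val = val_f1, params = model$params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= control$patience) break
    }
  }
  structure(list(config = config, params = best$params, history = history,
                 best_epoch = best$epoch, best_val_macro_f1 = best$val,
                 class_weights = w),
            class = c("enzact_checkpoint"))
}

#' Fit the cross-validated activity classifier
#'
#' The main fitting function.  Trains one transformer per stratified
#' cross-validation fold (each fold's model validated and early-stopped
#' on its held-out fold) and assembles the fold checkpoints into an
#' ensemble whose prediction is the mean of the post-softmax
#' probabilities across members.  Out-of-fold predictions and per-fold
#' metrics are retained.
#'
#' @param x Named list of `residue_embedding` objects.
#' @param y Labels (`HIGH`/`LOW`/`NONE`), same length/order as `x`.
#' @param config An [enzact_config()].
#' @param control A [train_control()].
#' @param k Number of folds (default 5).
#' @param rule Decision rule used for out-of-fold class decisions.
#' @return An object of class `enzact` with `checkpoints`, `folds`,
#'   `oof_probs`, `oof_pred`, `metrics` (per fold), `cv_macro_f1`
#'   (mean +/- sd across folds), `config`, `control`.
#' @seealso [predict.enzact()], [fit_transformer()]
#' @export
enzact <- function(x, y, config = enzact_config(), control = train_control(),
                   k = 5L, rule = decision_rule()) {
  stopifnot(length(x) == length(y))
  y <- factor(as.character(y), levels = ACTIVITY_LEVELS)
  folds <- stratified_kfold(y, k = k, seed = control$seed)
  checkpoints <- vector("list", k)
  oof <- matrix(NA_real_, length(x), 3,
                dimnames = list(names(x), ACTIVITY_LEVELS))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    ctl <- control
    ctl$seed <- control$seed + f  # distinct init/shuffle per fold
    ck <- fit_transformer(x[tr], y[tr], x[va], y[va], config, ctl)
    checkpoints[[f]] <- ck
    model <- structure(list(config = config, params = ck$params),
                       class = "enzact_model")
    probs <- t(vapply(x[va], function(e) model_forward(model, e)$probs,
                      numeric(3)))
    oof[va, ] <- probs
    fold_metrics[[f]] <- compute_metrics(decide(probs, rule), y[va])
  }
  mf1 <- vapply(fold_metrics, function(m) m$macro_f1, 0)
  out <- list(config = config, control = control, k = k, rule = rule,
              folds = folds, checkpoints = checkpoints,
              oof_probs = oof, oof_pred = decide(oof, rule),
              y = y, metrics = fold_metrics,
              cv_macro_f1 = mean(mf1), cv_macro_f1_sd = sd(mf1))
  class(out) <- "enzact"
  out
}

#' Predict from a fitted classifier ensemble
#'
#' Averages post-softmax probabilities across the fold checkpoints.
#'
#' @param object An `enzact` fit.
#' @param newdata List of `residue_embedding` objects (or matrices).
#' @param type `"prob"` for the `n x 3` posterior matrix, `"class"` for
#'   decided labels.
#' @param rule Decision rule for `type = "class"`.
#' @param ... Unused.
#' @export
predict.enzact <- function(object, newdata,
                           type = c("prob", "class"),
                           rule = object$rule, ...) {
  type <- match.arg(type)
  probs <- ensemble_probs(object$checkpoints, newdata, object$config)
  if (type == "prob") probs else decide(probs, rule)
}

# Mean post-softmax probability across fold checkpoints.
ensemble_probs <- function(checkpoints, x, config) {
  acc <- matrix(0, length(x), 3)
  for (ck in checkpoints) {
    model <- structure(list(config = config, params = ck$params),
                       class = "enzact_model")
    acc <- acc + t(vapply(x, function(e) model_forward(model, e)$probs,
                          numeric(3)))
  }
  probs <- acc / length(checkpoints)
  dimnames(probs) <- list(names(x), ACTIVITY_LEVELS)
  probs
}

#' @export
print.enzact <- function(x, ...) {
  cat("Cross-validated residue-level transformer activity classifier\n")
  cat(sprintf("  %d-fold CV, %d sequences, %d encoder block(s), %d head(s), d_model %d\n",
              x$k, length(x$folds), x$config$num_blocks, x$config$n_heads,
              x$config$d_model))
  cat(sprintf("  CV Macro-F1: %.3f +/- %.3f\n", x$cv_macro_f1, x$cv_macro_f1_sd))
  invisible(x)
}

#' @method summary enzact
#' @export
summary.enzact <- function(object, ...) {
  mf <- t(vapply(object$metrics, function(m)
    c(accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
      macro_f1 = m$macro_f1, mcc = m$mcc), numeric(4)))
  overall <- compute_metrics(object$oof_pred, object$y)
  out <- list(per_fold = as.data.frame(mf), overall = overall,
              cv_macro_f1 = object$cv_macro_f1,
              cv_macro_f1_sd = object$cv_macro_f1_sd)
  class(out) <- "summary.enzact"
  out
}

#' @export
print.summary.enzact <- function(x, ...) {
  cat("Per-fold validation metrics:\n")
  print(round(x$per_fold, 4))
  cat(sprintf("\nCV Macro-F1: %.4f +/- %.4f\n", x$cv_macro_f1, x$cv_macro_f1_sd))
  cat("\nOut-of-fold pooled metrics:\n")
  print(x$overall)
  invisible(x)
}

#' Plot training histories of the fold models
#'
#' @param x An `enzact` fit.
#' @param ... Passed to [graphics::matplot()].
#' @method plot enzact
#' @export
plot.enzact <- function(x, ...) {
  hs <- lapply(x$checkpoints, function(ck) ck$history$val_macro_f1)
  n <- max(vapply(hs, length, 0L))
  mat <- vapply(hs, function(h) c(h, rep(NA, n - length(h))), numeric(n))
  graphics::matplot(seq_len(n), mat, type = "b", pch = 20, lty = 1,
                    xlab = "epoch", ylab = "validation Macro-F1", ...)
  invisible(x)
}
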