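#' Classification metrics
#'
#' Accuracy, balanced accuracy, Macro-F1 (unweighted mean of per-class
#' F1), multiclass Matthews correlation coefficient (generalized
#' correlation form), and per-class precision/recall/F1.  `REJECTED`
#' predictions are excluded from the computation with their count
#' reported; `REJECTED` in the truth is an error.
#'
#' @param predictions,truth Equal-length label vectors/factors.
#' @return A `metric_report` list.
#' @export
compute_metrics <- function(predictions, truth) {
  pred <- as.character(predictions); tr <- as.character(truth)
  stopifnot(length(pred) == length(tr))
  if (any(tr == "REJECTED")) stop("truth labels may not contain REJECTED")
  keep <- pred != "REJECTED"
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    message(sprintf("%d rejected prediction(s) excluded from metrics", n_rejected))
  }
  pred <- pred[keep]; tr <- tr[keep]
  classes <- sort(unique(c(pred, tr)))
  ord <- match(classes, ACTIVITY_LEVELS)
  classes <- classes[order(ifelse(is.na(ord), 99L, ord), classes)]
  cm <- table(factor(tr, levels = classes), factor(pred, levels = classes))
  n <- sum(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  # Generalized multiclass MCC
  num <- sum(tp) * n - sum(pred_tot * true_tot)
  den <- sqrt(n^2 - sum(pred_tot^2)) * sqrt(n^2 - sum(true_tot^2))
  mcc <- if (den == 0) 0 else num / den
  out <- list(accuracy = sum(tp) / n,
              balanced_accuracy = mean(recall[true_tot > 0]),
              macro_f1 = mean(f1),
              mcc = mcc,
              per_class = data.frame(class = classes, precision = precision,
                                     recall = recall, f1 = f1,
                                     row.names = NULL),
              confusion = cm, n = n, n_rejected = n_rejected)
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  balanced accuracy %.4f  Macro-F1 %.4f  MCC %.4f  (n = %d",
              x$accuracy, x$balanced_accuracy, x$macro_f1, x$mcc, x$n))
  if (x$n_rejected > 0) cat(sprintf(", %d rejected", x$n_rejected))
  cat(")\n")
  print(transform(x$per_class, precision = round(precision, 4),
                  recall = round(recall, 4), f1 = round(f1, 4)))
  invisible(x)
}

#' Rank correlations between predicted scores and gold values
#'
#' Spearman's rho and Kendall's tau with midrank tie handling; constant
#' input vectors make both undefined and `NaN` is returned with a
#' warning.
#'
#' @param scores,gold Equal-length numeric vectors, length >= 3.
#' @return List with `spearman_rho` and `kendall_tau`.
#' @export
rank_correlations <- function(scores, gold) {
  stopifnot(length(scores) == length(gold), length(scores) >= 3L)
  if (sd(scores) == 0 || sd(gold) == 0) {
    warning("constant input vector: rank correlations undefined")
    return(list(spearman_rho = NaN, kendall_tau = NaN))
  }
  list(spearman_rho = cor(scores, gold, method = "spearman"),
       kendall_tau = cor(scores, gold, method = "kendall"))
}

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds so that per-class counts differ by
#' at most 1 across folds.  Classes smaller than `k` are an error.
#'
#' @param labels Label vector/factor.
#' @param k Number of folds.
#' @param seed Optional seed (local to this call).
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = NULL) {
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop(sprintf("class '%s' has %d members, fewer than k = %d",
                 small[1], counts[[small[1]]], k))
  }
  assign_folds <- function() {
    fold <- integer(length(labels))
    offset <- 0L
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      ids <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      fold[idx] <- ids
      offset <- (offset + length(idx)) %% k
    }
    fold
  }
  if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
}

#' Hyperparameter search space
#'
#' The tunable space of the classifier: encoder depth 4-10, learning
#' rate log-uniform on `[1e-5, 5e-3]`, dropout uniform on `[0.1, 0.7]`,
#' weight decay log-uniform on `[1e-6, 1e-2]`, heads in `{4, 8, 16}`,
#' optimizer in `{adam, adamw}`, and the `HIGH` decision threshold
#' uniform on `[0.3, 0.9]`.
#'
#' @return A `hyperparameter_space` list of sampling bounds.
#' @export
hyperparameter_space <- function() {
  structure(list(num_blocks = c(4L, 10L),
                 learning_rate = c(1e-5, 5e-3),
                 dropout = c(0.1, 0.7),
                 weight_decay = c(1e-6, 1e-2),
                 n_heads = c(4L, 8L, 16L),
                 optimizer = c("adam", "adamw"),
                 tau_high = c(0.3, 0.9)),
            class = "hyperparameter_space")
}

sample_trial <- function(space) {
  logu <- function(lim) exp(runif(1, log(lim[1]), log(lim[2])))
  list(num_blocks = sample(space$num_blocks[1]:space$num_blocks[2], 1L),
       learning_rate = logu(space$learning_rate),
       dropout = runif(1, space$dropout[1], space$dropout[2]),
       weight_decay = logu(space$weight_decay),
       n_heads = sample(space$n_heads, 1L),
       optimizer = sample(space$optimizer, 1L),
       tau_high = runif(1, space$tau_high[1], space$tau_high[2]))
}

#' Seeded random hyperparameter search
#'
#' Samples `budget` configurations from the space and returns the trial
#' maximizing the objective (mean cross-validation Macro-F1 in the
#' training pipeline).  Trials whose objective raises an error are
#' marked failed and the search continues.
#'
#' @param space A [hyperparameter_space()].
#' @param budget Number of trials (>= 1).
#' @param objective Function taking a sampled configuration list and
#'   returning a numeric score to maximize.
#' @param seed RNG seed.
#' @return List with `best_config`, `best_value` and `trials` (a data
#'   frame log of every trial).
#' @export
search_hyperparameters <- function(space, budget, objective, seed = 1L) {
  stopifnot(budget >= 1L)
  best <- NULL; best_val <- -Inf
  rows <- vector("list", budget)
  with_seed(seed, {
    for (t in seq_len(budget)) {
      cfg <- sample_trial(space)
      val <- tryCatch(objective(cfg), error = function(e) NA_real_)
      rows[[t]] <- data.frame(trial = t, num_blocks = cfg$num_blocks,
                              learning_rate = cfg$learning_rate,
                              dropout = cfg$dropout,
                              weight_decay = cfg$weight_decay,
                              n_heads = cfg$n_heads, optimizer = cfg$optimizer,
                              tau_high = cfg$tau_high, value = val,
                              failed = is.na(val))
      if (!is.na(val) && val > best_val) {
        best_val <- val; best <- cfg
      }
    }
  })
  list(best_config = best, best_value = best_val,
       trials = do.call(rbind, rows))
}
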