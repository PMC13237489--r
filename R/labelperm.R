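#' Stratified label permutation schemes
#'
#' Builds the stratification used by the label-permutation stress test:
#' `GLOBAL` (one stratum), `LENGTH_BINNED` (10 equal-frequency sequence
#' length bins), or `DUAL_RESTRICTED` (5 length bins crossed with 5 bins
#' of the first principal component of amino-acid composition, 25
#' strata).  Bin edges are equal-frequency quantiles; a value exactly on
#' an interior edge goes to the lower bin.
#'
#' @param kind Scheme kind.
#' @param length_bins,composition_bins Bin counts (defaults follow the
#'   scheme definitions).
#' @return A `permutation_scheme` object.
#' @export
permutation_scheme <- function(kind = c("GLOBAL", "LENGTH_BINNED",
                                        "DUAL_RESTRICTED"),
                               length_bins = NULL, composition_bins = NULL) {
  kind <- match.arg(kind)
  lb <- length_bins %||% switch(kind, GLOBAL = 1L, LENGTH_BINNED = 10L,
                                DUAL_RESTRICTED = 5L)
  cb <- composition_bins %||% switch(kind, GLOBAL = 1L, LENGTH_BINNED = 1L,
                                     DUAL_RESTRICTED = 5L)
  structure(list(kind = kind, length_bins = lb, composition_bins = cb),
            class = "permutation_scheme")
}

equal_frequency_bins <- function(x, nbins) {
  if (nbins <= 1L) return(rep(1L, length(x)))
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = nbins + 1L),
                           names = FALSE, type = 7))
  if (length(edges) < 2L) return(rep(1L, length(x)))
  cut(x, edges, include.lowest = TRUE, right = TRUE, labels = FALSE)
}

scheme_strata <- function(scheme, covariates, n) {
  switch(scheme$kind,
    GLOBAL = rep(1L, n),
    LENGTH_BINNED = equal_frequency_bins(covariates$length, scheme$length_bins),
    DUAL_RESTRICTED = {
      lb <- equal_frequency_bins(covariates$length, scheme$length_bins)
      cb <- equal_frequency_bins(covariates$composition_pc,
                                 scheme$composition_bins)
      as.integer(interaction(lb, cb, drop = FALSE))
    })
}

#' Permute labels within strata
#'
#' Shuffles labels uniformly within each stratum of the scheme, so the
#' global label multiset (and each per-stratum multiset) is preserved.
#' Singleton strata are fixed points.
#'
#' @param labels Label vector.
#' @param scheme A [permutation_scheme()].
#' @param covariates List with `length` and (for the dual scheme)
#'   `composition_pc`, parallel to `labels`.
#' @return Permuted labels, with the stratum vector as attribute
#'   `strata`.
#' @export
permute_labels <- function(labels, scheme = permutation_scheme("GLOBAL"),
                           covariates = NULL) {
  n <- length(labels)
  if (scheme$kind != "GLOBAL") {
    stopifnot(!is.null(covariates$length))
    if (scheme$kind == "DUAL_RESTRICTED")
      stopifnot(!is.null(covariates$composition_pc))
  }
  strata <- scheme_strata(scheme, covariates, n)
  out <- labels
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) > 1L) out[idx] <- labels[idx[sample.int(length(idx))]]
  }
  attr(out, "strata") <- strata
  out
}

#' First principal component of amino-acid composition
#'
#' Represents each sequence by its 20-dimensional relative amino-acid
#' frequency vector, mean-centers, and projects onto the leading
#' eigenvector of the sample covariance.  The sign is fixed so that the
#' loading with the largest magnitude is positive.
#'
#' @param sequences Canonical amino-acid strings.
#' @return Numeric score per sequence.
#' @export
composition_first_pc <- function(sequences) {
  if (any(!nzchar(sequences))) stop("empty sequence")
  freq <- t(vapply(sequences, function(s) {
    tab <- tabulate(match(strsplit(s, "")[[1]], AA_ALPHABET), nbins = 20L)
    tab / sum(tab)
  }, numeric(20L)))
  pc <- prcomp(freq, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (v[which.max(abs(v))] < 0) return(-pc$x[, 1])
  unname(pc$x[, 1])
}

## ---- reference learners (classifier contract) ------------------------------

#' Reference learners for the stress test
#'
#' A classifier contract is a list with `fit(X, y)` returning a fitted
#' object and `predict(fit, X)` returning labels; any learner satisfying
#' it can drive the stress test.  `learner_random_forest()` (500 trees,
#' `mtry = sqrt(p)`) and `learner_xgboost()` (300 rounds, depth 4,
#' learning rate 0.05) are the reference configurations;
#' `learner_multinom()` is a fast multinomial-logistic learner for
#' small fixtures.
#'
#' @param ntree,nrounds,max_depth,eta Learner hyperparameters.
#' @return A `classifier_contract` list.
#' @name learners
NULL

#' @rdname learners
#' @export
learner_random_forest <- function(ntree = 500L) {
  structure(list(
    fit = function(X, y) {
      y <- factor(y)
      randomForest::randomForest(X, y, ntree = ntree,
                                 mtry = max(1L, floor(sqrt(ncol(X)))))
    },
    predict = function(fit, X) as.character(predict(fit, X))),
    class = "classifier_contract")
}

#' @rdname learners
#' @export
learner_xgboost <- function(nrounds = 300L, max_depth = 4L, eta = 0.05) {
  structure(list(
    fit = function(X, y) {
      lev <- sort(unique(as.character(y)))
      yi <- match(as.character(y), lev) - 1L
      params <- list(max_depth = max_depth, eta = eta, nthread = 1L,
                     objective = if (length(lev) > 2L) "multi:softmax"
                       else "binary:logistic")
      if (length(lev) > 2L) params$num_class <- length(lev)
      bst <- xgboost::xgb.train(params,
                                xgboost::xgb.DMatrix(X, label = yi),
                                nrounds = nrounds, verbose = 0)
      list(bst = bst, lev = lev)
    },
    predict = function(fit, X) {
      p <- predict(fit$bst, xgboost::xgb.DMatrix(X))
      if (length(fit$lev) > 2L) fit$lev[p + 1L]
      else fit$lev[as.integer(p > 0.5) + 1L]
    }),
    class = "classifier_contract")
}

#' @rdname learners
#' @export
learner_multinom <- function() {
  structure(list(
    fit = function(X, y) {
      df <- data.frame(y = factor(y), X)
      nnet::multinom(y ~ ., data = df, trace = FALSE, MaxNWts = 100000)
    },
    predict = function(fit, X) as.character(predict(fit, data.frame(X)))),
    class = "classifier_contract")
}

cv_score <- function(X, y, learner, k, seed) {
  folds <- stratified_kfold(y, k = k, seed = seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- learner$fit(X[tr, , drop = FALSE], y[tr])
    pred <- learner$predict(fit, X[!tr, , drop = FALSE])
    m <- compute_metrics(pred, y[!tr])
    c(m$macro_f1, m$mcc)
  }, numeric(2))
  c(macro_f1 = mean(scores[1, ]), mcc = mean(scores[2, ]))
}

#' Label-permutation stress test
#'
#' Measures whether weak labels carry sequence-associated signal: the
#' observed score is the mean stratified `k`-fold cross-validation
#' Macro-F1 of the injected learner on fixed-length feature vectors
#' (mean-pooled embeddings), and the null distribution is obtained by
#' re-running the identical cross-validation on `B` independently
#' permuted label vectors under the chosen scheme.  The one-sided
#' empirical p-value is `(b + 1) / (B + 1)` where `b` counts null
#' scores at or above the observed score, so `p` can never be 0.
#'
#' @param features `n x D` feature matrix.
#' @param labels Label vector.
#' @param learner A classifier contract (see [learners]).
#' @param scheme A [permutation_scheme()].
#' @param B Number of permutations (>= 1; 500 in the reference setup).
#' @param k Cross-validation folds.
#' @param covariates Covariates for stratified schemes (see
#'   [permute_labels()]).
#' @param seed RNG seed.
#' @return A `null_distribution` list: `observed` (macro_f1, mcc),
#'   `null_scores` (length `B`), `b`, `p`.
#' @export
permutation_stress_test <- function(features, labels, learner,
                                    scheme = permutation_scheme("GLOBAL"),
                                    B = 500L, k = 5L, covariates = NULL,
                                    seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  labels <- as.character(labels)
  observed <- cv_score(features, labels, learner, k, seed)
  null_scores <- with_seed(seed + 1L, vapply(seq_len(B), function(b) {
    yperm <- permute_labels(labels, scheme, covariates)
    cv_score(features, yperm, learner, k, seed)[["macro_f1"]]
  }, 0))
  b <- sum(null_scores >= observed[["macro_f1"]])
  structure(list(observed = observed, null_scores = null_scores,
                 b = b, B = B, p = (b + 1) / (B + 1), scheme = scheme$kind),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Label-permutation stress test (%s scheme, B = %d)\n",
              x$scheme, x$B))
  cat(sprintf("  observed Macro-F1 %.4f (MCC %.4f)\n",
              x$observed[["macro_f1"]], x$observed[["mcc"]]))
  cat(sprintf("  null Macro-F1 mean %.4f sd %.4f\n",
              mean(x$null_scores), sd(x$null_scores)))
  cat(sprintf("  empirical one-sided p = %.4g (b = %d)\n", x$p, x$b))
  invisible(x)
}
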