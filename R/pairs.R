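#' Mann-Whitney AUC with midranks
#'
#' Probability that a random positive-group value exceeds a random
#' negative-group value, ties counted 1/2 (equals Mann-Whitney
#' `U / (n1 * n2)`).
#'
#' @param x Numeric values.
#' @param positive Logical vector marking the positive group.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(x, positive) {
  stopifnot(length(x) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty")
  r <- rank(x, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

sample_unordered_pairs <- function(n, n_pairs) {
  total <- n * (n - 1) / 2
  if (n_pairs > total) {
    warning(sprintf("requested %d pairs but only %.0f exist; capping",
                    n_pairs, total))
    n_pairs <- total
  }
  if (total <= 2e6) {
    # enumerate and sample without replacement
    all_pairs <- t(combn(n, 2L))
    all_pairs[sample.int(total, n_pairs), , drop = FALSE]
  } else {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- matrix(0L, n_pairs, 2L)
    got <- 0L
    while (got < n_pairs) {
      i <- sample.int(n, 1L); j <- sample.int(n, 1L)
      if (i == j) next
      a <- min(i, j); b <- max(i, j)
      key <- paste0(a, "_", b)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1L
      out[got, ] <- c(a, b)
    }
    out
  }
}

pair_statistics <- function(identity, same) {
  auc <- auc_mann_whitney(identity, same)
  list(auc = auc,
       median_diff = median(identity[same]) - median(identity[!same]),
       rank_biserial = rank_biserial_from_auc(auc))
}

#' Rank-biserial correlation from an AUC
#'
#' The rank-based two-group effect size satisfies the exact identity
#' `rank_biserial = 2 * AUC - 1`.
#'
#' @param auc AUC in `[0, 1]`.
#' @return Rank-biserial correlation in `[-1, 1]`.
#' @export
rank_biserial_from_auc <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  2 * auc - 1
}

#' Pairwise sequence-similarity label-agreement analysis
#'
#' Samples unique unordered sequence pairs uniformly without replacement
#' (self-pairs excluded), computes the global-alignment identity of each
#' pair, annotates pairs as same-label vs different-label (and as
#' high-high / low-low / high-low), and summarizes the association
#' between identity and label agreement by the AUC for predicting
#' same-label status from identity (same-label pairs positive), the
#' median identity difference, and the rank-biserial correlation, with
#' percentile bootstrap confidence intervals over pairs.
#'
#' @param records `seq_records` data frame.
#' @param labels Labels restricted to `HIGH`/`LOW`, parallel to
#'   `records`.
#' @param n_pairs Number of pairs to sample (capped at `C(n, 2)` with a
#'   warning).
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed RNG seed.
#' @param identities Optional precomputed identity vector (parallel to
#'   the sampled pair table) to skip alignment.
#' @param scoring See [global_identity()].
#' @return A `pair_stats` list with the pair table, observed statistics
#'   and bootstrap CIs.
#' @export
pair_agreement_analysis <- function(records, labels, n_pairs = 20000L,
                                    n_boot = 1000L, seed = 1L,
                                    identities = NULL,
                                    scoring = list(match = 2, mismatch = -1,
                                                   gap_open = -5,
                                                   gap_extend = -0.5)) {
  labels <- as.character(labels)
  stopifnot(nrow(records) >= 2L, all(labels %in% c("HIGH", "LOW")))
  pairs <- with_seed(seed, sample_unordered_pairs(nrow(records), n_pairs))
  ids <- identities %||% vapply(seq_len(nrow(pairs)), function(r)
    global_identity(records$sequence[pairs[r, 1]],
                    records$sequence[pairs[r, 2]], scoring), 0)
  la <- labels[pairs[, 1]]; lb <- labels[pairs[, 2]]
  same <- la == lb
  type <- ifelse(same & la == "HIGH", "high-high",
                 ifelse(same, "low-low", "high-low"))
  obs <- pair_statistics(ids, same)
  boot <- with_seed(seed + 1L, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(ids), replace = TRUE)
    if (all(same[idx]) || !any(same[idx])) return(c(NA_real_, NA_real_, NA_real_))
    s <- pair_statistics(ids[idx], same[idx])
    c(s$auc, s$median_diff, s$rank_biserial)
  }, numeric(3)))
  ci <- apply(boot, 1L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  colnames(ci) <- c("auc", "median_diff", "rank_biserial")
  structure(list(
    pairs = data.frame(i = pairs[, 1], j = pairs[, 2], identity = ids,
                       same_label = same, pair_type = type),
    n_pairs = length(ids),
    auc = obs$auc, median_diff = obs$median_diff,
    rank_biserial = obs$rank_biserial,
    bootstrap_ci = ci),
    class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("Pairwise label-agreement analysis (%d pairs)\n", x$n_pairs))
  cat(sprintf("  AUC (same-label positive): %.4f  [%.4f, %.4f]\n",
              x$auc, x$bootstrap_ci[1, "auc"], x$bootstrap_ci[2, "auc"]))
  cat(sprintf("  median identity difference: %.4f\n", x$median_diff))
  cat(sprintf("  rank-biserial correlation:  %.4f\n", x$rank_biserial))
  print(table(x$pairs$pair_type))
  invisible(x)
}

#' Label-permutation test on a fixed pair table
#'
#' Permutes labels across sequence ids while keeping the precomputed
#' pair identities fixed, recomputes same/different assignments and the
#' three summary statistics per replicate, and reports add-one-corrected
#' two-sided p-values: the fraction of replicates whose statistic is at
#' least as far from its theoretical null center (AUC 0.5, differences
#' 0) as the observed one.
#'
#' @param pair_stats A [pair_agreement_analysis()] result.
#' @param labels The sequence labels (same vector used to build the pair
#'   table).
#' @param R Number of permutation replicates (>= 1).
#' @param seed RNG seed.
#' @return List with observed statistics, null means, and two-sided
#'   p-values per statistic.
#' @export
pair_label_permutation <- function(pair_stats, labels, R = 1000L, seed = 1L) {
  if (R < 1L) stop("R must be >= 1")
  labels <- as.character(labels)
  pairs <- pair_stats$pairs
  ids <- pairs$identity   # cached; never recomputed across replicates
  obs <- c(auc = pair_stats$auc, median_diff = pair_stats$median_diff,
           rank_biserial = pair_stats$rank_biserial)
  center <- c(auc = 0.5, median_diff = 0, rank_biserial = 0)
  null_mat <- with_seed(seed, vapply(seq_len(R), function(r) {
    perm <- labels[sample.int(length(labels))]
    same <- perm[pairs$i] == perm[pairs$j]
    if (all(same) || !any(same)) return(c(NA_real_, NA_real_, NA_real_))
    s <- pair_statistics(ids, same)
    c(s$auc, s$median_diff, s$rank_biserial)
  }, numeric(3)))
  rownames(null_mat) <- names(obs)
  p <- vapply(names(obs), function(nm) {
    vals <- null_mat[nm, ]
    vals <- vals[!is.na(vals)]
    (1 + sum(abs(vals - center[nm]) >= abs(obs[nm] - center[nm]) - 1e-12)) /
      (length(vals) + 1)
  }, 0)
  list(observed = obs, null_mean = rowMeans(null_mat, na.rm = TRUE),
       p_two_sided = p, R = R)
}
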