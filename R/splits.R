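#' Global alignment sequence identity
#'
#' Needleman-Wunsch global alignment under configurable match/mismatch/
#' gap scores (via Biostrings), with identity defined as the number of
#' matched aligned residues divided by the alignment length, gap columns
#' included in the denominator.  Gap costs follow the open/extend
#' convention in which a gap of length `g` costs
#' `gap_open + (g - 1) * gap_extend`.
#'
#' @param a,b Non-empty canonical amino-acid strings.
#' @param scoring List with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (the gap terms are negative scores).
#' @return Identity in `[0, 1]`.
#' @export
global_identity <- function(a, b,
                            scoring = list(match = 2, mismatch = -1,
                                           gap_open = -5, gap_extend = -0.5)) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- align_global(a, b, scoring)
  al$nmatch / al$length
}

align_global <- function(a, b, scoring) {
  letters <- unique(c(AA_ALPHABET, strsplit(paste0(a, b), "")[[1]]))
  sub <- matrix(scoring$mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- scoring$match
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = sub,
    gapOpening = -(scoring$gap_open - scoring$gap_extend),
    gapExtension = -scoring$gap_extend)
  pat <- as.character(Biostrings::alignedPattern(al))
  list(nmatch = Biostrings::nmatch(al), length = nchar(pat),
       score = Biostrings::score(al))
}

#' 3-mer TF-IDF vectorizer
#'
#' Overlapping 3-mer term frequencies with smooth inverse document
#' frequency (`idf = log((1 + N) / (1 + df)) + 1`), L2-normalized; the
#' corpus defining the vocabulary and document frequencies is the
#' training set.
#'
#' @param corpus Character vector of training sequences.
#' @return A function mapping a character vector of sequences to a
#'   matrix of TF-IDF vectors (rows = sequences).
#' @export
tfidf_3mer <- function(corpus) {
  kmerize <- function(s) {
    n <- nchar(s)
    if (n < 3L) return(character(0))
    substring(s, 1:(n - 2L), 3:n)
  }
  corpus_kmers <- lapply(corpus, kmerize)
  vocab <- sort(unique(unlist(corpus_kmers)))
  df <- numeric(length(vocab)); names(df) <- vocab
  for (ks in corpus_kmers) {
    u <- unique(ks)
    df[u] <- df[u] + 1
  }
  idf <- log((1 + length(corpus)) / (1 + df)) + 1
  function(seqs) {
    out <- matrix(0, length(seqs), length(vocab),
                  dimnames = list(NULL, vocab))
    for (i in seq_along(seqs)) {
      tab <- table(kmerize(seqs[i]))
      tab <- tab[names(tab) %in% vocab]
      if (length(tab)) out[i, names(tab)] <- as.numeric(tab) * idf[names(tab)]
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
}

#' Nearest-train identity audit
#'
#' For each validation sequence, candidate training neighbors are ranked
#' by 3-mer TF-IDF cosine similarity; the top `prefilter_k` candidates
#' are aligned globally and the maximum identity (and its neighbor) is
#' reported.  This is the leakage audit statistic for identity-capped
#' partitions.
#'
#' @param validation,training `seq_records` data frames (non-empty).
#' @param prefilter_k Number of prefilter candidates to align (>= 1).
#' @param scoring See [global_identity()].
#' @return Data frame `record_id`, `neighbor_id`, `identity`.
#' @export
nearest_train_identity <- function(validation, training, prefilter_k = 25L,
                                   scoring = list(match = 2, mismatch = -1,
                                                  gap_open = -5,
                                                  gap_extend = -0.5)) {
  stopifnot(nrow(validation) > 0L, nrow(training) > 0L)
  if (prefilter_k < 1L) stop("prefilter_k must be >= 1")
  vec <- tfidf_3mer(training$sequence)
  Vt <- vec(training$sequence)
  Vv <- vec(validation$sequence)
  sims <- Vv %*% t(Vt)   # cosine since both are L2-normalized
  k <- min(prefilter_k, nrow(training))
  res <- lapply(seq_len(nrow(validation)), function(i) {
    cand <- order(sims[i, ], decreasing = TRUE)[seq_len(k)]
    ids <- vapply(cand, function(j)
      global_identity(validation$sequence[i], training$sequence[j], scoring), 0)
    best <- which.max(ids)
    data.frame(record_id = validation$record_id[i],
               neighbor_id = training$record_id[cand[best]],
               identity = ids[best], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# All-pairs identity matrix (symmetric, unit diagonal).
pairwise_identity_matrix <- function(records, scoring) {
  n <- nrow(records)
  M <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        id <- global_identity(records$sequence[i], records$sequence[j], scoring)
        M[i, j] <- id; M[j, i] <- id
      }
    }
  }
  M
}

#' Identity-capped cross-validation folds
#'
#' Builds single-linkage clusters over the graph whose edges connect
#' pairs with identity at or above `cap`, then assigns whole clusters to
#' folds by greedy size balancing (largest first, seeded tie order).  By
#' construction no cross-fold pair reaches the cap.  Records labeled
#' `NONE` (auxiliary penalty sequences) are excluded before clustering
#' and receive fold `NA`.
#'
#' @param records `seq_records` data frame.
#' @param cap Maximum allowed cross-fold identity, in `(0, 1]` (presets
#'   0.70 and 0.40).
#' @param k Number of folds.
#' @param seed RNG seed for tie ordering.
#' @param labels Optional activity labels; `NONE` rows are excluded.
#' @param scoring See [global_identity()].
#' @return Integer fold vector (NA for excluded rows), with the cluster
#'   membership as attribute `clusters`.
#' @export
identity_capped_folds <- function(records, cap, k = 5L, seed = 1L,
                                  labels = NULL,
                                  scoring = list(match = 2, mismatch = -1,
                                                 gap_open = -5,
                                                 gap_extend = -0.5)) {
  stopifnot(cap > 0, cap <= 1)
  fold <- rep(NA_integer_, nrow(records))
  use <- if (is.null(labels)) rep(TRUE, nrow(records)) else
    as.character(labels) != "NONE"
  if (!all(use)) message(sprintf("excluded %d auxiliary NONE record(s) before clustering",
                                 sum(!use)))
  sub <- records[use, , drop = FALSE]
  n <- nrow(sub)
  M <- pairwise_identity_matrix(sub, scoring)
  adj <- M >= cap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  if (max(sizes) > (1 - 1 / k) * n) {
    stop(sprintf("one identity cluster holds %d of %d records; loosen the cap",
                 max(sizes), n))
  }
  cl_ids <- as.integer(names(sort(sizes, decreasing = TRUE)))
  cl_ids <- with_seed(seed, {
    # stable order for equal sizes, randomized within ties
    sz <- as.integer(sizes[as.character(cl_ids)])
    cl_ids[order(-sz, sample.int(length(cl_ids)))]
  })
  fold_sizes <- numeric(k)
  sub_fold <- integer(n)
  for (cid in cl_ids) {
    f <- which.min(fold_sizes)
    members <- which(comp == cid)
    sub_fold[members] <- f
    fold_sizes[f] <- fold_sizes[f] + length(members)
  }
  fold[use] <- sub_fold
  attr(fold, "clusters") <- comp
  fold
}

#' Species- or genus-holdout grouped folds
#'
#' Assigns every record of a taxonomic group (species or genus) to a
#' single fold, using a seeded constrained greedy assignment that
#' approximately balances fold sizes and class composition.
#'
#' @param records `seq_records` with `species`/`genus` columns.
#' @param group_key `"species"` or `"genus"`.
#' @param k Number of folds.
#' @param seed RNG seed (42 preset).
#' @param labels Optional class labels used to balance composition.
#' @return Integer fold vector.
#' @export
grouped_holdout_folds <- function(records, group_key = c("species", "genus"),
                                  k = 5L, seed = 42L, labels = NULL) {
  group_key <- match.arg(group_key)
  groups <- records[[group_key]]
  if (any(!nzchar(groups))) stop("every record must carry the group key")
  ug <- unique(groups)
  if (length(ug) < k) stop(sprintf("only %d group(s) for %d folds", length(ug), k))
  sizes <- table(groups)[ug]
  classes <- if (is.null(labels)) NULL else sort(unique(as.character(labels)))
  gcc <- if (is.null(classes)) NULL else
    t(vapply(ug, function(g) {
      tabulate(factor(as.character(labels)[groups == g], levels = classes),
               nbins = length(classes))
    }, integer(length(classes))))
  overall_prop <- if (is.null(classes)) NULL else colSums(gcc) / sum(gcc)

  ord <- with_seed(seed, {
    sz <- as.integer(sizes)
    order(-sz, sample.int(length(ug)))
  })
  fold_sizes <- numeric(k)
  fold_cc <- if (is.null(classes)) NULL else matrix(0, k, length(classes))
  gfold <- integer(length(ug))
  for (i in ord) {
    cost <- vapply(seq_len(k), function(f) {
      c1 <- fold_sizes[f] + sizes[i]
      c2 <- if (is.null(classes)) 0 else {
        p <- (fold_cc[f, ] + gcc[i, ]) / c1
        sum((p - overall_prop)^2)
      }
      c1 / sum(sizes) + c2
    }, 0)
    f <- which.min(cost)
    gfold[i] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[i]
    if (!is.null(classes)) fold_cc[f, ] <- fold_cc[f, ] + gcc[i, ]
  }
  gfold[match(groups, ug)]
}
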