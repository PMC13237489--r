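#' Synthetic per-residue embedder
#'
#' Deterministic stand-in for a frozen protein language-model embedder.
#' Residue `i` of a sequence is embedded as the (scaled) sum of seeded
#' random projections of the residue identities in a context window of
#' `window` positions on either side, so context-dependent label signals
#' (motif co-occurrence) are representable.  Positions outside the
#' sequence contribute a padding token.  Embeddings are a pure function of
#' `(sequence, dim, window, seed)` and are never trained or mutated.
#'
#' @param dim Embedding dimension `D` (1152 by default, matching the
#'   frozen external embedder contract; use a small `D` for tests).
#' @param window Context half-width in residues.
#' @param seed Integer seed for the projection tables.
#' @return An object of class `enzact_embedder`.
#' @export
synthetic_embedder <- function(dim = 1152L, window = 2L, seed = 1L) {
  stopifnot(dim >= 1L, window >= 0L)
  offsets <- -window:window
  tabs <- lapply(offsets, function(o) {
    # One 21 x D projection table per offset (20 residues + padding token),
    # seeded independently of R's global RNG state.
    rs <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
      set.seed(as.integer(seed) * 1000L + (o + window) * 7L + 13L)
      matrix(rnorm(21L * dim), nrow = 21L, ncol = dim)
    })
    rs
  })
  names(tabs) <- as.character(offsets)
  obj <- list(kind = "synthetic", dim = as.integer(dim),
              window = as.integer(window), seed = as.integer(seed),
              tables = tabs)
  class(obj) <- "enzact_embedder"
  obj
}

#' Embed one amino-acid sequence
#'
#' @param sequence Canonical amino-acid string.
#' @param embedder An [synthetic_embedder()] (or any object with the same
#'   contract).
#' @return A `residue_embedding`: list with `id`, `mat` (`L x D`) and
#'   `mask` (length-`L` logical, all `TRUE` here).
#' @export
synthetic_embed <- function(sequence, embedder, id = "seq") {
  sequence <- toupper(sequence)
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)) {
    stop("non-canonical residue in sequence to embed")
  }
  idx <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)
  L <- length(idx)
  w <- embedder$window
  mat <- matrix(0, nrow = L, ncol = embedder$dim)
  for (o in -w:w) {
    tab <- embedder$tables[[as.character(o)]]
    pos <- seq_len(L) + o
    valid <- pos >= 1L & pos <= L
    shifted <- rep(21L, L)                  # out-of-range -> padding row 21
    shifted[valid] <- idx[pos[valid]]
    mat <- mat + tab[shifted, , drop = FALSE]
  }
  mat <- mat / sqrt(2 * w + 1)
  residue_embedding(id, mat)
}

residue_embedding <- function(id, mat, mask = NULL) {
  mask <- mask %||% rep(TRUE, nrow(mat))
  stopifnot(length(mask) == nrow(mat))
  structure(list(id = id, mat = mat, mask = mask),
            class = "residue_embedding")
}

#' Embed a set of sequence records
#'
#' @param records `seq_records` data frame.
#' @param embedder See [synthetic_embed()].
#' @return Named list of `residue_embedding` objects, keyed by record id.
#' @export
embed_sequences <- function(records, embedder) {
  out <- lapply(seq_len(nrow(records)), function(i)
    synthetic_embed(records$sequence[i], embedder, id = records$record_id[i]))
  names(out) <- records$record_id
  out
}

#' Mean-pool a residue embedding
#'
#' Arithmetic mean over the unmasked rows; masked (padding) rows never
#' influence the result.
#'
#' @param embedding A `residue_embedding` or a plain `L x D` matrix.
#' @param mask Optional logical mask when `embedding` is a matrix.
#' @return Length-`D` numeric vector.
#' @export
mean_pool <- function(embedding, mask = NULL) {
  if (inherits(embedding, "residue_embedding")) {
    mat <- embedding$mat; mask <- embedding$mask
  } else {
    mat <- embedding; mask <- mask %||% rep(TRUE, nrow(mat))
  }
  if (!any(mask)) stop("all rows masked: cannot pool an empty embedding")
  colMeans(mat[mask, , drop = FALSE])
}

#' Pool a list of residue embeddings into a feature matrix
#'
#' @param embeddings List of `residue_embedding` objects.
#' @return `n x D` matrix of mean-pooled vectors, rownames = ids.
#' @export
pool_embeddings <- function(embeddings) {
  out <- t(vapply(embeddings, mean_pool, numeric(ncol(embeddings[[1]]$mat))))
  rownames(out) <- vapply(embeddings, function(e) e$id, "")
  out
}
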