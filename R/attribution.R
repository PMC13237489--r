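#' Integrated gradients for a model ensemble
#'
#' Path-integral attribution from a zero-embedding baseline to the
#' input along the straight line, using the trapezoidal approximation
#' with `steps` interpolation points on the logit of the target class
#' (the ensemble-predicted class by default).  Attribution tensors are
#' averaged across ensemble members before the per-residue score is
#' taken as the L2 norm of the attribution vector across embedding
#' dimensions.  For a linear model the attribution is exact for any
#' number of steps.
#'
#' @param checkpoints List of `enzact_checkpoint`s (or `enzact_model`s).
#' @param embedding A `residue_embedding` or `L x D` matrix.
#' @param config The shared [enzact_config()].
#' @param steps Interpolation steps (>= 1; 50 preset).
#' @param target Optional fixed target class index (1 = HIGH, 2 = LOW,
#'   3 = NONE); default is the ensemble-predicted class.
#' @return An `attribution_map`: list with `ig_score` (per residue),
#'   `attributions` (`L x D`, ensemble mean), `target`,
#'   `completeness_error` (|sum(attr) - (F(x) - F(0))| averaged over
#'   members).
#' @export
integrated_gradients <- function(checkpoints, embedding, config,
                                 steps = 50L, target = NULL) {
  if (steps < 1L) stop("steps must be >= 1")
  X <- if (inherits(embedding, "residue_embedding"))
    embedding$mat[embedding$mask, , drop = FALSE] else embedding
  models <- lapply(checkpoints, function(ck)
    structure(list(config = config, params = ck$params),
              class = "enzact_model"))
  if (is.null(target)) {
    probs <- Reduce(`+`, lapply(models, function(m)
      model_forward(m, X)$probs)) / length(models)
    target <- which.max(probs)
  }
  alphas <- seq(0, 1, length.out = steps + 1L)  # trapezoid nodes
  wts <- c(0.5, rep(1, steps - 1L), 0.5) / steps
  acc <- matrix(0, nrow(X), ncol(X))
  comp_err <- 0
  for (m in models) {
    gsum <- matrix(0, nrow(X), ncol(X))
    for (s in seq_along(alphas)) {
      fw <- model_forward(m, X * alphas[s], return_cache = TRUE)
      dlog <- numeric(3); dlog[target] <- 1
      gsum <- gsum + wts[s] * model_backward(m, fw, dlog)$dX
    }
    attr_m <- X * gsum
    f1 <- model_forward(m, X)$logits[target]
    f0 <- model_forward(m, X * 0)$logits[target]
    comp_err <- comp_err + abs(sum(attr_m) - (f1 - f0))
    acc <- acc + attr_m
  }
  attributions <- acc / length(models)
  structure(list(ig_score = sqrt(rowSums(attributions^2)),
                 attributions = attributions, target = target,
                 completeness_error = comp_err / length(models)),
            class = "attribution_map")
}

#' Incoming-attention residue scores
#'
#' Averages attention matrices across ensemble members, encoder blocks
#' and heads into one residue-by-residue matrix, zeroes the diagonal,
#' and scores each residue by the sum of off-diagonal attention weights
#' it receives from all other residues (column sums).
#'
#' @param attention_tensors List over ensemble members; each member a
#'   list over blocks of `H x L x L` arrays (as returned by
#'   [model_forward()] with `return_attention = TRUE`).
#' @return Numeric vector of length `L`.
#' @export
incoming_attention <- function(attention_tensors) {
  stopifnot(length(attention_tensors) >= 1L)
  acc <- NULL; count <- 0L
  for (member in attention_tensors) {
    for (blockA in member) {
      dims <- dim(blockA)
      if (dims[2] != dims[3]) stop("attention matrices must be square")
      for (h in seq_len(dims[1])) {
        A <- blockA[h, , ]
        acc <- if (is.null(acc)) A else acc + A
        count <- count + 1L
      }
    }
  }
  M <- acc / count
  diag(M) <- 0
  colSums(M)
}

#' Capture ensemble attention for one sequence
#'
#' @param checkpoints List of checkpoints.
#' @param embedding Input embedding.
#' @param config Shared configuration.
#' @return List over members of per-block `H x L x L` arrays.
#' @export
ensemble_attention <- function(checkpoints, embedding, config) {
  lapply(checkpoints, function(ck) {
    m <- structure(list(config = config, params = ck$params),
                   class = "enzact_model")
    model_forward(m, embedding, return_attention = TRUE)$attention
  })
}
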