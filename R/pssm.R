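#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, a column-header
#' row of amino-acid letters, then one row per position holding the
#' index, the wild-type residue and the first block of 20 log-odds
#' scores.  Trailing statistics lines are ignored.
#'
#' @param input File path or character vector of lines.
#' @return A `pssm` object: list with `parent_id`, `scores` (`L x 20`
#'   integer matrix, PSI-BLAST column order), `wt_residues`.
#' @export
parse_psiblast_pssm <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input)
    else input
  header_i <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) >= 20L && all(toks %in% c(AA_ALPHABET, "B", "Z", "X"))) {
      header_i <- i; break
    }
  }
  if (is.null(header_i)) stop("no PSSM column header found")
  cols <- strsplit(trimws(lines[header_i]), "[[:space:]]+")[[1]][1:20]
  rows <- list(); wt <- character(0); expected <- 1L
  for (i in (header_i + 1L):length(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) < 22L || is.na(suppressWarnings(as.integer(toks[1])))) {
      break
    }
    idx <- as.integer(toks[1])
    if (idx != expected) {
      stop(sprintf("PSSM row index %d found where %d expected (row %d)",
                   idx, expected, length(rows) + 1L))
    }
    expected <- expected + 1L
    wt <- c(wt, toks[2])
    rows[[length(rows) + 1L]] <- as.integer(toks[3:22])
  }
  if (!length(rows)) stop("no PSSM score rows found")
  scores <- do.call(rbind, rows)
  colnames(scores) <- cols
  scores <- scores[, PSSM_COLUMNS, drop = FALSE]  # normalize column order
  structure(list(parent_id = "pssm", scores = scores,
                 wt_residues = paste(wt, collapse = "")),
            class = "pssm")
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Fixture writer; [parse_psiblast_pssm()] round-trips its output.
#'
#' @param pssm A `pssm` object.
#' @param path Output path or `NULL` to return lines.
#' @export
write_psiblast_pssm <- function(pssm, path = NULL) {
  wt <- strsplit(pssm$wt_residues, "")[[1]]
  lines <- c("",
             "Last position-specific scoring matrix computed, weighted observed percentages rounded down",
             paste0("            ", paste(sprintf("%3s", PSSM_COLUMNS),
                                         collapse = " ")))
  for (i in seq_len(nrow(pssm$scores))) {
    lines <- c(lines, paste0(sprintf("%5d %s  ", i, wt[i]),
                             paste(sprintf("%3d", pssm$scores[i, PSSM_COLUMNS]),
                                   collapse = " ")))
  }
  lines <- c(lines, "", "                      K         Lambda", "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Mutant-minus-wild-type PSSM score change
#'
#' `delta_pssm = score[position, mutant] - score[position, wild type]`;
#' a conservativeness proxy (more negative = less conservative).
#'
#' @param pssm A `pssm` object.
#' @param variant One row of a variant table (list with `position`,
#'   `wt_aa`, `mut_aa`), or the three values given separately.
#' @return The score difference (0 for a synonymous "variant").
#' @export
delta_pssm <- function(pssm, variant) {
  pos <- variant$position; wt <- variant$wt_aa; mut <- variant$mut_aa
  stopifnot(pos >= 1L, pos <= nrow(pssm$scores))
  wt_in_pssm <- substr(pssm$wt_residues, pos, pos)
  if (wt_in_pssm != wt) {
    stop(sprintf("wild-type mismatch at position %d: PSSM has %s, variant says %s",
                 pos, wt_in_pssm, wt))
  }
  unname(pssm$scores[pos, mut] - pssm$scores[pos, wt])
}

#' Filter and rank a mutant library
#'
#' Applies the conservativeness filter `delta_pssm >= cutoff` and ranks
#' the surviving variants by ensemble high-activity probability
#' (descending), ties broken by `delta_pssm` descending, then variant
#' name.  Filtered-out variants are retained with `passed_filter =
#' FALSE` and no rank.  The library-wide mean `delta_pssm` is attached
#' so the "cutoff near the library average" heuristic is reproducible.
#'
#' @param library Variant table ([full_single_mutant_library()]).
#' @param pssm A `pssm` for the parent.
#' @param p_high Named (by variant name) or positional vector of
#'   ensemble mean `P(HIGH)` per variant.
#' @param cutoff Filter threshold (-7 preset).
#' @return A `candidate_ranking` data frame (`name`, `delta_pssm`,
#'   `ensemble_p_high`, `passed_filter`, `rank`).
#' @export
prioritize_variants <- function(library, pssm, p_high, cutoff = -7) {
  n <- nrow(library)
  if (!is.null(names(p_high))) {
    miss <- setdiff(library$name, names(p_high))
    if (length(miss)) stop(sprintf("missing ensemble score for variant %s",
                                   miss[1]))
    p_high <- p_high[library$name]
  } else if (length(p_high) != n) {
    stop("p_high must cover every variant")
  }
  dp <- vapply(seq_len(n), function(i) delta_pssm(pssm, library[i, ]), 0)
  passed <- dp >= cutoff
  out <- data.frame(name = library$name, position = library$position,
                    wt_aa = library$wt_aa, mut_aa = library$mut_aa,
                    delta_pssm = dp, ensemble_p_high = as.numeric(p_high),
                    passed_filter = passed, rank = NA_integer_,
                    stringsAsFactors = FALSE)
  if (any(passed)) {
    sub <- out[passed, ]
    ord <- order(-sub$ensemble_p_high, -sub$delta_pssm, sub$name)
    out$rank[passed][ord] <- seq_len(sum(passed))
    # reorder: passing variants first, by rank; excluded rows after
    out <- out[order(!out$passed_filter, out$rank), ]
  }
  rownames(out) <- NULL
  attr(out, "mean_delta_pssm") <- mean(dp)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' Sweep the conservativeness cutoff
#'
#' Rank stability of the top candidates under a range of filter
#' cutoffs.
#'
#' @param library,pssm,p_high As in [prioritize_variants()].
#' @param cutoffs Numeric vector of cutoffs to evaluate.
#' @param top Number of top-ranked names to report per cutoff.
#' @return Data frame with one row per cutoff: `cutoff`, `n_passing`,
#'   `top_names` (comma-separated).
#' @export
cutoff_sweep <- function(library, pssm, p_high, cutoffs = seq(-10, -4), top = 5L) {
  rows <- lapply(cutoffs, function(ct) {
    r <- prioritize_variants(library, pssm, p_high, cutoff = ct)
    passing <- r[r$passed_filter, ]
    data.frame(cutoff = ct, n_passing = nrow(passing),
               top_names = paste(head(passing$name, top), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
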