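#' Active-site knockout variants for the "no activity" penalty group
#'
#' Substitutes every annotated active/binding-site residue of a parent
#' sequence with each of the remaining 19 canonical amino acids, yielding
#' `19 * length(positions)` single-point variants that are assigned the
#' `NONE` label downstream.  Variants are ordered by position, then mutant
#' residue A-Y, and named in the `<wt><pos><mut>` convention (`V129G`).
#'
#' @param parent A single-row `seq_records` data frame, or a list/row with
#'   `record_id` and `sequence`.
#' @param positions Strictly increasing 1-based residue indices annotated
#'   as active or binding site (overlapping annotations should be passed as
#'   their union).
#' @return A data frame with columns `parent_id`, `position`, `wt_aa`,
#'   `mut_aa`, `name`, `sequence`.
#' @export
site_knockout_variants <- function(parent, positions) {
  parent <- as_parent(parent)
  positions <- as.integer(positions)
  if (length(positions)) {
    stopifnot(!is.unsorted(positions, strictly = TRUE), all(positions >= 1L))
    bad <- positions[positions > nchar(parent$sequence)]
    if (length(bad)) {
      stop(sprintf("site position %d exceeds parent length %d",
                   bad[1], nchar(parent$sequence)))
    }
  }
  variants_at(parent, positions)
}

#' Full single-point mutant library
#'
#' All nonsynonymous single substitutions of a parent sequence: exactly
#' `19 * L` variants for a parent of length `L` (7,220 for a 380-residue
#' protein), ordered by position then mutant residue.
#'
#' @inheritParams site_knockout_variants
#' @return A data frame as in [site_knockout_variants()].
#' @export
full_single_mutant_library <- function(parent) {
  parent <- as_parent(parent)
  variants_at(parent, seq_len(nchar(parent$sequence)))
}

as_parent <- function(parent) {
  if (is.data.frame(parent)) {
    stopifnot(nrow(parent) == 1L)
    parent <- as.list(parent)
  }
  seq <- toupper(parent$sequence)
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seq)) {
    stop("parent sequence contains non-canonical residues")
  }
  list(record_id = parent$record_id %||% "parent", sequence = seq)
}

variants_at <- function(parent, positions) {
  if (!length(positions)) {
    return(data.frame(parent_id = character(0), position = integer(0),
                      wt_aa = character(0), mut_aa = character(0),
                      name = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(parent$sequence, "")[[1]]
  rows <- lapply(positions, function(p) {
    wt <- chars[p]
    muts <- setdiff(AA_ALPHABET, wt)   # already A->Y sorted
    seqs <- vapply(muts, function(m) {
      s <- chars; s[p] <- m; paste(s, collapse = "")
    }, "", USE.NAMES = FALSE)
    data.frame(parent_id = parent$record_id, position = p, wt_aa = wt,
               mut_aa = muts, name = paste0(wt, p, muts), sequence = seqs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a variant table to sequence records
#'
#' @param variants Output of [site_knockout_variants()] or
#'   [full_single_mutant_library()].
#' @param species Species string attached to every variant record.
#' @return A `seq_records` data frame whose ids are
#'   `<parent_id>_<variant name>`.
#' @export
variants_to_records <- function(variants, species = "") {
  make_seq_records(paste0(variants$parent_id, "_", variants$name),
                   variants$sequence, species = species)
}
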