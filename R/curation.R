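#' Deterministic mock annotator keyed on genus lists
#'
#' Stand-in for an external species-level annotation service.  An annotator
#' is any object of class `enzact_annotator`: a list with an
#' `annotate(species, sequence)` function returning
#' `list(activity, temperature)` (activity in `HIGH`/`LOW`, temperature in
#' `THERMOPHILIC`/`MESOPHILIC`/`PSYCHROPHILIC`), deterministic for fixed
#' inputs.  The mock assigns `HIGH` to genera on `high_genera` (emulating
#' ecological priors such as pathogen-associated selective pressure) and
#' `LOW` otherwise, and assigns temperature classes from the corresponding
#' genus lists (boundaries: thermophilic > 45 degrees C, mesophilic 15-45,
#' psychrophilic <= 15).  Records without a species are refused
#' (annotation failure) since the mock is metadata-driven.
#'
#' @param high_genera Character vector of genera labeled `HIGH`.
#' @param thermophilic_genera,psychrophilic_genera Genera assigned the
#'   non-mesophilic temperature classes.
#' @return An `enzact_annotator` object.
#' @export
mock_annotator <- function(high_genera = character(0),
                           thermophilic_genera = character(0),
                           psychrophilic_genera = character(0)) {
  ann <- list(
    kind = "mock",
    config = list(high_genera = high_genera,
                  thermophilic_genera = thermophilic_genera,
                  psychrophilic_genera = psychrophilic_genera),
    annotate = function(species, sequence) {
      if (is.na(species) || !nzchar(species)) return(NULL)
      genus <- strsplit(species, "[[:space:]]+")[[1]][1]
      activity <- if (genus %in% high_genera) "HIGH" else "LOW"
      temperature <- if (genus %in% thermophilic_genera) "THERMOPHILIC"
        else if (genus %in% psychrophilic_genera) "PSYCHROPHILIC"
        else "MESOPHILIC"
      list(activity = activity, temperature = temperature)
    })
  class(ann) <- "enzact_annotator"
  ann
}

#' Annotate sequence records through a pluggable annotator
#'
#' Applies an annotator to each record, caching results per species so that
#' repeated species are annotated exactly once.  Records the annotator
#' refuses are flagged unannotated and excluded downstream; the count is
#' attached and a warning emitted.
#'
#' @param records A `seq_records` data frame.
#' @param annotator An `enzact_annotator` object, e.g. [mock_annotator()].
#' @return A data frame with columns `record_id`, `activity`,
#'   `temperature`, `annotated` (logical); attribute `n_unannotated`.
#' @export
annotate_records <- function(records, annotator) {
  stopifnot(inherits(annotator, "enzact_annotator"))
  cache <- new.env(parent = emptyenv())
  n <- nrow(records)
  activity <- character(n); temperature <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    sp <- records$species[i]
    key <- if (nzchar(sp)) sp else paste0("\rseq:", records$record_id[i])
    res <- if (nzchar(sp) && !is.null(cache[[key]])) cache[[key]] else {
      r <- annotator$annotate(sp, records$sequence[i])
      if (nzchar(sp) && !is.null(r)) cache[[key]] <- r
      r
    }
    if (is.null(res)) {
      ok[i] <- FALSE; activity[i] <- NA_character_; temperature[i] <- NA_character_
    } else {
      stopifnot(res$activity %in% c("HIGH", "LOW"),
                res$temperature %in% TEMPERATURE_LEVELS)
      ok[i] <- TRUE; activity[i] <- res$activity; temperature[i] <- res$temperature
    }
  }
  if (any(!ok)) {
    warning(sprintf("%d record(s) could not be annotated and are flagged for exclusion",
                    sum(!ok)))
  }
  out <- data.frame(record_id = records$record_id, activity = activity,
                    temperature = temperature, annotated = ok,
                    stringsAsFactors = FALSE)
  attr(out, "n_unannotated") <- sum(!ok)
  out
}

#' Run the curation pipeline
#'
#' Assembles the training dataset from annotated records: exact-sequence
#' duplicates are removed (first occurrence kept), unannotated records are
#' dropped, thermophilic and psychrophilic records are removed, and the
#' artificial "no activity" penalty records are appended with label `NONE`.
#' Provenance counters are populated so that
#' `n_final = n_deduplicated - n_unannotated_removed - n_temperature_removed`.
#'
#' @param records A `seq_records` data frame.
#' @param annotations Output of [annotate_records()] covering all records.
#' @param penalty_records Optional `seq_records` of penalty sequences
#'   (labeled `NONE`); a penalty sequence duplicating a natural sequence is
#'   kept but logged as a collision.
#' @return A `curated_dataset`: list with `records` (columns of the input
#'   plus `activity`, `temperature`, `source`) and `counters`.
#' @export
curate_dataset <- function(records, annotations, penalty_records = NULL) {
  stopifnot(nrow(annotations) == nrow(records),
            all(annotations$record_id == records$record_id))
  n_input <- nrow(records)

  keep <- !duplicated(records$sequence)
  recs <- records[keep, , drop = FALSE]
  ann <- annotations[keep, , drop = FALSE]
  n_deduplicated <- nrow(recs)

  annotated <- ann$annotated
  n_unannotated_removed <- sum(!annotated)
  recs <- recs[annotated, , drop = FALSE]
  ann <- ann[annotated, , drop = FALSE]

  meso <- ann$temperature == "MESOPHILIC"
  n_temperature_removed <- sum(!meso)
  recs <- recs[meso, , drop = FALSE]
  ann <- ann[meso, , drop = FALSE]
  n_final <- nrow(recs)

  recs$activity <- ann$activity
  recs$temperature <- ann$temperature
  recs$source <- "natural"

  n_penalty_added <- 0L
  if (!is.null(penalty_records) && nrow(penalty_records) > 0L) {
    n_collisions <- sum(penalty_records$sequence %in% recs$sequence)
    if (n_collisions > 0L) {
      message(sprintf("%d penalty sequence(s) collide with natural sequences (kept)",
                      n_collisions))
    }
    pen <- penalty_records
    pen$activity <- "NONE"
    pen$temperature <- "MESOPHILIC"
    pen$source <- "penalty"
    common <- intersect(names(recs), names(pen))
    recs <- rbind(recs[common], pen[common])
    n_penalty_added <- nrow(pen)
  }
  rownames(recs) <- NULL
  out <- list(records = recs,
              counters = list(n_input = n_input,
                              n_deduplicated = n_deduplicated,
                              n_unannotated_removed = n_unannotated_removed,
                              n_temperature_removed = n_temperature_removed,
                              n_final = n_final,
                              n_penalty_added = n_penalty_added))
  class(out) <- "curated_dataset"
  out
}

#' @export
print.curated_dataset <- function(x, ...) {
  ct <- x$counters
  cat("Curated dataset\n")
  cat(sprintf("  input records:        %d\n", ct$n_input))
  cat(sprintf("  after deduplication:  %d\n", ct$n_deduplicated))
  if (ct$n_unannotated_removed > 0)
    cat(sprintf("  unannotated removed:  %d\n", ct$n_unannotated_removed))
  cat(sprintf("  non-mesophilic removed: %d\n", ct$n_temperature_removed))
  cat(sprintf("  final natural:        %d\n", ct$n_final))
  cat(sprintf("  penalty added:        %d\n", ct$n_penalty_added))
  tab <- table(factor(x$records$activity, levels = ACTIVITY_LEVELS))
  cat("  class counts: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a curated dataset as TSV
#'
#' @param dataset A `curated_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(dataset, path) {
  df <- dataset$records
  cols <- c("record_id", "accession", "species", "genus", "length",
            "activity", "temperature", "source")
  write.table(df[intersect(cols, names(df))], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
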