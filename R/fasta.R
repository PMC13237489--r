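#' Parse UniProt-style FASTA into sequence records
#'
#' Reads FASTA text and returns one row per entry, in file order.  Headers
#' in the UniProt dialect (`>sp|P12345|NAME ... OS=Genus species OX=...`)
#' have the accession extracted from the second `|`-delimited field and the
#' species taken from the `OS=` field, up to the next `KEY=` token or the
#' end of the header.  Records whose sequence contains a non-canonical
#' residue (anything outside the 20 standard letters) are excluded with a
#' warning carrying the count; this includes B, J, O, U, X and Z.
#'
#' @param input Path to a FASTA file, or a character vector of FASTA lines.
#' @return A data frame of class `seq_records` with columns `record_id`,
#'   `accession`, `species`, `genus`, `sequence` and `length`.  The number
#'   of excluded non-canonical records is attached as attribute
#'   `n_noncanonical`.
#' @examples
#' recs <- parse_fasta(c(">sp|P0X|TEST OS=Staphylococcus aureus OX=1280",
#'                       "MKVLA"))
#' recs$species  # "Staphylococcus aureus"
#' @export
parse_fasta <- function(input) {
  lines <- if (length(input) == 1L && !startsWith(input[1], ">") &&
               file.exists(input)) readLines(input) else input
  lines <- sub("\r$", "", lines)
  ids <- character(0); heads <- character(0); seqs <- character(0)
  cur <- NULL; cur_seq <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      heads <<- c(heads, cur)
      seqs <<- c(seqs, paste(cur_seq, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      cur <- sub("^>", "", ln)
      cur_seq <- character(0)
    } else {
      if (is.null(cur)) {
        stop(sprintf("malformed FASTA: sequence data before any header at line %d", i))
      }
      cur_seq <- c(cur_seq, gsub("[[:space:]]", "", toupper(ln)))
    }
  }
  flush()
  if (length(heads) == 0L) return(empty_seq_records())

  record_id <- vapply(strsplit(heads, "[[:space:]]+"), `[`, "", 1L)
  accession <- vapply(record_id, function(id) {
    parts <- strsplit(id, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 3L && parts[1] %in% c("sp", "tr")) parts[2] else ""
  }, "", USE.NAMES = FALSE)
  species <- vapply(heads, extract_os_field, "", USE.NAMES = FALSE)
  genus <- vapply(strsplit(species, "[[:space:]]+"), function(x)
    if (length(x)) x[1] else "", "")

  canonical <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  n_bad <- sum(!canonical)
  if (n_bad > 0L) {
    warning(sprintf("excluded %d record(s) containing non-canonical residues", n_bad))
  }
  out <- data.frame(record_id = record_id, accession = accession,
                    species = species, genus = genus, sequence = seqs,
                    length = nchar(seqs), stringsAsFactors = FALSE)
  out <- out[canonical, , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$record_id)) {
    warning("duplicate record ids in FASTA input")
  }
  attr(out, "n_noncanonical") <- n_bad
  class(out) <- c("seq_records", "data.frame")
  out
}

empty_seq_records <- function() {
  out <- data.frame(record_id = character(0), accession = character(0),
                    species = character(0), genus = character(0),
                    sequence = character(0), length = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_noncanonical") <- 0L
  class(out) <- c("seq_records", "data.frame")
  out
}

# Species from "OS=..." up to the next "XX=" key or end of header.
extract_os_field <- function(header) {
  m <- regexpr("OS=", header, fixed = TRUE)
  if (m < 0) return("")
  rest <- substring(header, m + 3L)
  nxt <- regexpr("[[:space:]][A-Z][A-Za-z0-9]*=", rest)
  if (nxt > 0) rest <- substring(rest, 1L, nxt - 1L)
  trimws(rest)
}

#' Write sequence records as FASTA
#'
#' Inverse of [parse_fasta()] for valid records: `parse_fasta(write_fasta(x))`
#' restores ids, species and sequences.  The species, when present, is
#' emitted as an `OS=` field.
#'
#' @param records A `seq_records` data frame (or any data frame with
#'   `record_id`, `sequence` and optionally `species` columns).
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @param width Sequence line wrap width.
#' @return The FASTA lines, invisibly.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- paste0(">", records$record_id[i])
    sp <- if ("species" %in% names(records)) records$species[i] else ""
    if (nzchar(sp)) hdr <- paste0(hdr, " OS=", sp)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    c(hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Minimal constructor used by generators and tests.
make_seq_records <- function(record_id, sequence, species = "",
                             accession = "") {
  species <- rep_len(species, length(record_id))
  out <- data.frame(
    record_id = record_id,
    accession = rep_len(accession, length(record_id)),
    species = species,
    genus = vapply(strsplit(species, "[[:space:]]+"),
                   function(x) if (length(x)) x[1] else "", ""),
    sequence = toupper(sequence),
    length = nchar(sequence),
    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}
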