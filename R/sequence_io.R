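## Sequence and table input/output, and the canonical conventions used by
## every other module:
##   * residue positions are 1-based,
##   * peptide bond i joins residues i and i+1 (1 <= i <= L-1),
##   * sequences are strings over the 20 canonical one-letter codes;
##     non-canonical letters (B, J, O, U, X, Z) are rejected, never skipped,
##     because the digestion rules are defined only over the 20-letter
##     alphabet.

#' Validate a protein or peptide sequence
#'
#' Uppercases, strips whitespace and gap characters, and rejects any letter
#' outside the 20-residue alphabet with an error naming the offending
#' position.
#'
#' @param seq Character scalar.
#' @param what Label used in error messages.
#' @return The normalised sequence (character scalar).
#' @export
#' @examples
#' validate_sequence("mk v") # "MKV"
validate_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("%s must be a single character string", what))
  }
  seq <- toupper(gsub("[\\s\\-\\.\\*]", "", seq, perl = TRUE))
  if (nchar(seq) == 0L) {
    abort(sprintf("%s is empty after removing whitespace/gaps", what))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s contains non-canonical residue '%s' at position %d",
      what, chars[bad[1]], bad[1]
    ))
  }
  seq
}

#' Read protein records from a FASTA file
#'
#' Thin validating layer over [Biostrings::readAAStringSet()]: sequences are
#' uppercased, whitespace/gaps are stripped, and any character outside the
#' 20-letter amino-acid alphabet raises an error naming its position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (the full FASTA header word) and
#'   `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x demo", "MKV"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(sprintf("failed to parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' contains no records", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- as.character(set)
  tibble(
    id = ids,
    sequence = vapply(
      seq_along(seqs),
      function(i) validate_sequence(seqs[i], what = sprintf("record '%s'", ids[i])),
      character(1)
    )
  )
}

#' Construct a peptide table
#'
#' The peptide tibble is the package's common currency: one row per peptide,
#' with provenance (`parent_id`, 1-based inclusive `start`/`end` span) and
#' the `treatment` label of the enzyme treatment that produced it. Extra
#' annotation columns (activity, per-stage verdicts) are carried along by
#' every downstream verb.
#'
#' @param sequence Character vector of peptide sequences.
#' @param parent_id,start,end,treatment Optional provenance columns.
#' @return A tibble with at least the columns
#'   `sequence, parent_id, start, end, treatment`.
#' @export
peptide_tbl <- function(sequence, parent_id = NA_character_, start = NA_integer_,
                        end = NA_integer_, treatment = NA_character_) {
  sequence <- vapply(sequence, validate_sequence, character(1), what = "peptide")
  tibble(
    sequence = unname(sequence),
    parent_id = parent_id,
    start = as.integer(start),
    end = as.integer(end),
    treatment = as.character(treatment)
  )
}

#' Write a peptide table to TSV
#'
#' Columns are written in a stable order (`sequence, parent_id, start, end,
#' treatment`, then any annotation columns in their current order) and rows
#' are sorted by parent, span, then sequence, so identical inputs produce
#' byte-identical files.
#'
#' @param peptides Peptide tibble (see [peptide_tbl()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  stopifnot(is.data.frame(peptides))
  core <- c("sequence", "parent_id", "start", "end", "treatment")
  for (col in core) {
    if (!col %in% names(peptides)) peptides[[col]] <- NA
  }
  extra <- setdiff(names(peptides), core)
  out <- peptides[, c(core, extra), drop = FALSE]
  # flatten list-columns (e.g. treatment sets from merge_unique)
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(
        out[[col]],
        function(x) paste(as.character(x), collapse = ","), character(1)
      )
    }
  }
  out <- arrange(out, .data$parent_id, .data$start, .data$end, .data$sequence)
  ok <- tryCatch(
    {
      readr::write_tsv(out, path, progress = FALSE)
      TRUE
    },
    error = function(e) abort(sprintf("cannot write peptide table to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read a peptide table written by [write_peptide_table()]
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("peptide table not found: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
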