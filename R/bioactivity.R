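## Activity annotation.
##
## Di- and tripeptides are annotated by exact lookup in a reference table of
## known ACE-inhibitory sequences with pIC50; tetra- to hexapeptides are
## annotated by a pluggable scorer (a peptide is labelled active when its
## score is STRICTLY above the threshold, default 0.0). The trained SVM of
## the external activity-prediction server is deliberately not
## reimplemented: the file-backed scorer injects scores exported from such a
## server, and the built-in baseline is a clearly-labelled
## composition-based stand-in for testing the plumbing.

#' Load a reference table of bioactive peptides
#'
#' @param path Path to a TSV with columns `sequence`, `pIC50`, `source`
#'   (`#` comments allowed). Defaults to the packaged ACE di-/tripeptide
#'   table.
#' @return A tibble with an added logical `lookup_eligible` flag (length
#'   2-3); longer entries are kept but flagged, and a warning names them.
#' @export
load_reference_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference", "ace_reference.tsv",
                                package = "pepscreen")
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sequence", "pIC50") %in% names(tbl)))
  tbl$sequence <- vapply(tbl$sequence, validate_sequence, character(1),
                         what = "reference sequence", USE.NAMES = FALSE)
  if (any(!is.finite(tbl$pIC50))) abort("reference table contains non-finite pIC50 values")
  tbl$lookup_eligible <- nchar(tbl$sequence) %in% 2:3
  if (any(!tbl$lookup_eligible)) {
    warn(sprintf(
      "reference table entries outside length 2-3 are flagged and skipped by the lookup stage: %s",
      paste(tbl$sequence[!tbl$lookup_eligible], collapse = ", ")
    ))
  }
  tbl
}

#' Annotate di-/tripeptides by reference lookup
#'
#' Case-normalised, exact-sequence, exact-length lookup: peptides of length
#' 2-3 found in the table become active with the table's pIC50; all other
#' peptides are left inactive at this step.
#'
#' @param peptides Peptide tibble or character vector.
#' @param table Reference tibble from [load_reference_table()].
#' @return Peptide tibble with columns `is_active`, `activity_method`
#'   (`"lookup"` or `NA`), `activity_score` (the pIC50 for lookup hits).
#' @export
match_known <- function(peptides, table = load_reference_table()) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = toupper(as.character(peptides)))
  lut <- table[table$lookup_eligible %||% (nchar(table$sequence) %in% 2:3), ]
  scores <- setNames(lut$pIC50, lut$sequence)
  peptides |>
    mutate(
      is_active = nchar(.data$sequence) %in% 2:3 & .data$sequence %in% names(scores),
      activity_method = if_else(.data$is_active, "lookup", NA_character_),
      activity_score = if_else(.data$is_active, unname(scores[.data$sequence]), NA_real_)
    )
}

#' Scorers for the activity predictor
#'
#' `scorer_file()` reads a `sequence <TAB> score` TSV (e.g. scores exported
#' from an external prediction web server) and errors on sequences it has no
#' score for. `scorer_baseline()` is a built-in stand-in for pipeline
#' testing: a fixed linear model on amino-acid composition (hydrophobic and
#' aromatic content, C-terminal proline/aromatic bonuses) centred so that
#' typical random peptides fall on both sides of 0 -- it is NOT a
#' reimplementation of any trained predictor and its scores carry no
#' literature meaning.
#'
#' @param path TSV of sequence/score pairs.
#' @return A function `sequences -> numeric scores`.
#' @export
scorer_file <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sequence", "score") %in% names(tbl)))
  lut <- setNames(tbl$score, toupper(tbl$sequence))
  function(sequences) {
    sequences <- toupper(sequences)
    missing <- setdiff(sequences, names(lut))
    if (length(missing) > 0L) {
      abort(sprintf("scorer file has no score for sequence '%s'", missing[1]))
    }
    unname(lut[sequences])
  }
}

#' @rdname scorer_file
#' @export
scorer_baseline <- function() {
  # fixed, documented weights; deterministic by construction
  w <- c(
    A = 0.10, R = -0.15, N = -0.05, D = -0.20, C = 0.00, Q = -0.05, E = -0.20,
    G = 0.05, H = 0.10, I = 0.25, L = 0.20, K = -0.10, M = 0.10, F = 0.30,
    P = 0.25, S = -0.05, T = 0.00, V = 0.20, W = 0.30, Y = 0.30
  )
  function(sequences) {
    vapply(sequences, function(s) {
      ch <- seq_chars(s)
      cterm_bonus <- if (tail(ch, 1) %in% c("P", "F", "W", "Y")) 0.3 else 0
      sum(w[ch]) / length(ch) + cterm_bonus - 0.15
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Predict activity of tetra- to hexapeptides with a pluggable scorer
#'
#' A peptide is labelled active when its score is strictly greater than
#' `threshold` (a score exactly at the threshold is inactive).
#'
#' @param peptides Peptide tibble or character vector; every sequence must
#'   have length 4-6.
#' @param scorer A function from [scorer_file()] or [scorer_baseline()].
#' @param threshold Activity threshold (default 0.0).
#' @return Peptide tibble with `is_active`, `activity_method`
#'   (`"predicted"`), `activity_score`, `threshold_used`.
#' @export
predict_activity <- function(peptides, scorer, threshold = 0) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = toupper(as.character(peptides)))
  len <- nchar(peptides$sequence)
  if (any(len < 4L | len > 6L)) {
    abort(sprintf(
      "predict_activity is defined for peptides of length 4-6; got '%s' (length %d)",
      peptides$sequence[which(len < 4L | len > 6L)[1]], len[which(len < 4L | len > 6L)[1]]
    ))
  }
  stopifnot(is.function(scorer))
  peptides |>
    mutate(
      activity_score = as.numeric(scorer(.data$sequence)),
      is_active = .data$activity_score > threshold,
      activity_method = "predicted",
      threshold_used = threshold
    )
}

#' Annotate a mixed-length peptide pool
#'
#' Dispatches by length: 2-3 to [match_known()], 4-6 to [predict_activity()]
#' (when a scorer is supplied), everything else inactive.
#'
#' @inheritParams predict_activity
#' @param table Reference table for the lookup stage.
#' @return The pool with activity columns appended.
#' @export
annotate_activity <- function(peptides, table = load_reference_table(),
                              scorer = NULL, threshold = 0) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = toupper(as.character(peptides)))
  len <- nchar(peptides$sequence)
  short <- match_known(peptides[len <= 3L, , drop = FALSE], table)
  mid <- peptides[len >= 4L & len <= 6L, , drop = FALSE]
  if (nrow(mid) > 0L) {
    if (is.null(scorer)) {
      mid <- mid |> mutate(is_active = FALSE, activity_method = NA_character_,
                           activity_score = NA_real_)
    } else {
      mid <- predict_activity(mid, scorer, threshold)
    }
  }
  long <- peptides[len > 6L, , drop = FALSE]
  if (nrow(long) > 0L) {
    long <- long |> mutate(is_active = FALSE, activity_method = NA_character_,
                           activity_score = NA_real_)
  }
  bind_rows(short, mid, long)
}

#' Partition screened peptides into known and novel
#'
#' @param peptides Peptide tibble or character vector of final candidates.
#' @param known Character vector (or tibble with `sequence`) of known
#'   antihypertensive sequences; defaults to the packaged reference.
#' @return A list with sorted tibbles `known` and `novel`, and integer
#'   counts `n_known`, `n_novel`. The two lists are disjoint and jointly
#'   exhaust the input sequences.
#' @export
classify_novel <- function(peptides, known = NULL) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = toupper(as.character(peptides)))
  if (is.null(known)) {
    known <- readr::read_tsv(
      system.file("extdata", "reference", "known_aht.tsv", package = "pepscreen"),
      comment = "#", show_col_types = FALSE, progress = FALSE
    )
  }
  known_seqs <- as_sequence_set(known)
  is_known <- peptides$sequence %in% known_seqs
  list(
    known = arrange(peptides[is_known, , drop = FALSE], .data$sequence),
    novel = arrange(peptides[!is_known, , drop = FALSE], .data$sequence),
    n_known = sum(is_known),
    n_novel = sum(!is_known)
  )
}
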