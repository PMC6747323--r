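## Quantitative proteolysis statistics.
##
## DH  — degree of hydrolysis: percentage of the substrate's peptide bonds
##       (L - 1 of them) cleaved by the full treatment, counting stage-2
##       cleavages mapped back to parent coordinates.
## A_E — release frequency: number of released bioactive peptides (with
##       multiplicity) divided by the substrate's residue count.
## W   — relative release frequency: released bioactive count divided by
##       the number of bioactive-peptide occurrences embedded in the
##       substrate (overlapping occurrences counted); under exhaustive
##       digestion W <= 1.

single_parent <- function(result) {
  stopifnot(inherits(result, "digest_result"))
  if (nrow(result$parents) != 1L) {
    abort("this statistic is defined for a single-substrate digest_result")
  }
  result$parents
}

#' Degree of hydrolysis of a digestion
#'
#' @param result A `digest_result` (see [digest()], [sequential_digest()]).
#' @return DH in percent, in `[0, 100]`.
#' @export
degree_of_hydrolysis <- function(result) {
  parent <- single_parent(result)
  L <- nchar(parent$sequence)
  if (L < 2L) abort("degree of hydrolysis is undefined for a single-residue substrate (no bonds)")
  100 * length(result$cleaved_bonds[[1]]) / (L - 1L)
}

as_sequence_set <- function(reference) {
  if (is.data.frame(reference)) reference <- reference$sequence
  unique(vapply(as.character(reference), validate_sequence, character(1),
                what = "reference peptide"))
}

#' Count occurrences of reference peptides in a protein
#'
#' Counts, with multiplicity, the positions at which any reference sequence
#' occurs as a substring; overlapping occurrences are all counted.
#'
#' @param protein A sequence string or one-row protein tibble.
#' @param reference Character vector (or tibble with a `sequence` column) of
#'   reference peptide sequences.
#' @return Integer total count.
#' @export
#' @examples
#' occurrence_count("AYAY", c("AY", "YA")) # 3
occurrence_count <- function(protein, reference) {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    protein <- protein$sequence
  }
  protein <- validate_sequence(protein)
  reference <- as_sequence_set(reference)
  sum(vapply(reference, function(r) {
    hits <- gregexpr(paste0("(?=", r, ")"), protein, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0L else length(hits)
  }, integer(1)))
}

released_active_count <- function(released, reference) {
  if (is.data.frame(released)) released <- released$sequence
  reference <- as_sequence_set(reference)
  sum(released %in% reference)
}

#' Release frequency A_E
#'
#' @param released Released peptides: character vector or peptide tibble.
#' @param reference Reference set of bioactive sequences.
#' @param protein_length Residue count of the substrate protein.
#' @return A_E (fraction).
#' @export
release_frequency_AE <- function(released, reference, protein_length) {
  stopifnot(protein_length >= 1L)
  released_active_count(released, reference) / protein_length
}

#' Relative release frequency W
#'
#' @inheritParams release_frequency_AE
#' @param protein Substrate sequence (string or one-row protein tibble).
#' @return W (fraction, in `[0, 1]` under exhaustive digestion).
#' @export
relative_frequency_W <- function(released, reference, protein) {
  denom <- occurrence_count(protein, reference)
  if (denom == 0L) {
    abort("relative release frequency W is undefined: no reference peptide occurs in the substrate (zero denominator)")
  }
  released_active_count(released, reference) / denom
}

#' Run a panel of enzyme treatments and tabulate DH (and A_E/W)
#'
#' Each treatment is a list with `stage1` (enzymes applied simultaneously to
#' the intact protein) and optional `stage2` (supplemental digestion of the
#' stage-1 products, honouring substrate length caps). When a reference set
#' of bioactive sequences is supplied, A_E and W are added; when reported DH
#' values are supplied (named by treatment), the per-treatment discrepancy
#' against them is reported so packaged rule tables can be audited against a
#' given specificity-database snapshot.
#'
#' @param protein One-row protein tibble or sequence string.
#' @param treatments Named list of treatments, e.g.
#'   `list(papain = list(stage1 = "papain"),
#'         `papain+prep` = list(stage1 = "papain", stage2 = "prep"))`.
#' @param reference Optional reference bioactive sequences.
#' @param reference_dh Optional named numeric of reported DH values (%).
#' @return A tibble with one row per treatment: `treatment`, `n_bonds_cut`,
#'   `n_peptides`, `dh`, and when available `ae`, `w`, `reference_dh`,
#'   `dh_discrepancy`.
#' @export
hydrolysis_report <- function(protein, treatments, reference = NULL,
                              reference_dh = NULL) {
  protein <- as_protein_tbl(protein)
  stopifnot(nrow(protein) == 1L, length(treatments) >= 1L, !is.null(names(treatments)))
  rows <- lapply(names(treatments), function(nm) {
    tr <- treatments[[nm]]
    res <- if (is.null(tr$stage2)) {
      digest(protein, tr$stage1, treatment = nm)
    } else {
      sequential_digest(protein, tr$stage1, tr$stage2, treatment = nm)
    }
    row <- tibble(
      treatment = nm,
      n_bonds_cut = length(res$cleaved_bonds[[1]]),
      n_peptides = nrow(res$peptides),
      dh = degree_of_hydrolysis(res)
    )
    if (!is.null(reference)) {
      row$ae <- release_frequency_AE(res$peptides, reference, nchar(protein$sequence))
      row$w <- tryCatch(
        relative_frequency_W(res$peptides, reference, protein),
        error = function(e) NA_real_
      )
    }
    row
  })
  out <- bind_rows(rows)
  if (!is.null(reference_dh)) {
    out$reference_dh <- unname(reference_dh[out$treatment])
    out$dh_discrepancy <- out$dh - out$reference_dh
  }
  out
}
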