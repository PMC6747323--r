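## Exhaustive in silico digestion.
##
## Digestion is modelled as deterministic and exhaustive: every bond whose
## subsite window matches a rule is cut, with no partial-digest
## stochasticity. By default the engine iterates to a fixpoint: released
## fragments are re-examined (each enzyme sees the fragment, including its
## new termini and the fragment's own length against any substrate length
## cap) until no new cleavage appears. This is the physical model of an
## enzyme acting on reaction products, and it guarantees that re-digesting
## any released peptide yields no further cleavage. `refine = FALSE` gives
## the single-pass semantics (sites found on the intact substrate only);
## the two coincide for rules whose constraints never reference positions
## beyond P1/P1'.

cut_sequence <- function(seq, sites) {
  L <- nchar(seq)
  sites <- sort(unique(as.integer(sites)))
  starts <- c(1L, sites + 1L)
  ends <- c(sites, L)
  tibble(
    start = starts, end = ends,
    sequence = substring(seq, starts, ends)
  )
}

## Sites for one fragment (local coordinates), union over enzymes.
fragment_sites <- function(seq, enzymes) {
  sort(unique(unlist(lapply(enzymes, function(e) find_cleavage_sites(seq, e)))))
}

## Exhaustive digestion of one sequence; returns parent-coordinate bond set.
digest_sequence <- function(seq, enzymes, refine = TRUE) {
  bonds <- fragment_sites(seq, enzymes)
  if (refine) {
    repeat {
      frags <- cut_sequence(seq, bonds)
      new_bonds <- unlist(lapply(seq_len(nrow(frags)), function(k) {
        local <- fragment_sites(frags$sequence[k], enzymes)
        if (length(local) == 0L) return(integer(0))
        frags$start[k] + local - 1L
      }))
      new_bonds <- setdiff(new_bonds, bonds)
      if (length(new_bonds) == 0L) break
      bonds <- sort(c(bonds, new_bonds))
    }
  }
  bonds
}

as_protein_tbl <- function(protein) {
  if (is.character(protein)) {
    protein <- tibble(
      id = if (!is.null(names(protein))) names(protein) else
        paste0("protein", seq_along(protein)),
      sequence = unname(protein)
    )
  }
  stopifnot(is.data.frame(protein), all(c("id", "sequence") %in% names(protein)))
  protein$sequence <- vapply(protein$sequence, validate_sequence, character(1),
                             USE.NAMES = FALSE)
  as_tibble(protein[, c("id", "sequence")])
}

as_enzyme_list <- function(enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  if (is.character(enzymes)) enzymes <- load_enzymes(enzymes)
  if (length(enzymes) == 0L) abort("at least one enzyme is required")
  stopifnot(all(vapply(enzymes, inherits, logical(1), "enzyme_spec")))
  setNames(enzymes, vapply(enzymes, `[[`, character(1), "name"))
}

#' Digest proteins with one or more enzymes acting simultaneously
#'
#' All enzymes see the substrate at once: the cleaved-bond set is the union
#' of every enzyme's sites, cut exhaustively (see `refine`). Released
#' peptides carry 1-based inclusive provenance spans and tile the parent
#' exactly.
#'
#' @param protein A protein tibble (columns `id`, `sequence`, e.g. from
#'   [read_fasta()]) or a character vector of sequences.
#' @param enzymes An `enzyme_spec`, a list of them, or packaged table names
#'   (see [load_enzymes()]).
#' @param treatment Treatment label recorded on the released peptides;
#'   defaults to the enzyme names joined with `+`.
#' @param refine Iterate re-digestion of fragments to a fixpoint (default
#'   `TRUE`); `FALSE` cuts only sites found on the intact substrate.
#' @return A `digest_result`: list with `parents` (tibble), `cleaved_bonds`
#'   (named list of parent-coordinate bond indices), `peptides` (peptide
#'   tibble), `treatment` and `enzymes`. [tidy()] extracts the peptide
#'   tibble.
#' @export
#' @examples
#' after_k <- enzyme_spec("after_K", rules = "P1=K")
#' digest(c(p = "AKAKA"), after_k)$peptides
digest <- function(protein, enzymes, treatment = NULL, refine = TRUE) {
  protein <- as_protein_tbl(protein)
  enzymes <- as_enzyme_list(enzymes)
  treatment <- treatment %||% paste(names(enzymes), collapse = "+")
  bonds <- lapply(seq_len(nrow(protein)), function(k) {
    digest_sequence(protein$sequence[k], enzymes, refine = refine)
  })
  names(bonds) <- protein$id
  peptides <- bind_rows(lapply(seq_len(nrow(protein)), function(k) {
    frags <- cut_sequence(protein$sequence[k], bonds[[k]])
    tibble(
      sequence = frags$sequence, parent_id = protein$id[k],
      start = frags$start, end = frags$end, treatment = treatment
    )
  }))
  structure(
    list(parents = protein, cleaved_bonds = bonds, peptides = peptides,
         treatment = treatment, enzymes = names(enzymes)),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf(
    "<digest_result> treatment '%s': %d parent(s), %d cleaved bond(s), %d peptide(s)\n",
    x$treatment, nrow(x$parents), sum(lengths(x$cleaved_bonds)), nrow(x$peptides)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.digest_result <- function(x, ...) x$peptides

#' Two-stage (sequential) digestion
#'
#' Stage-1 enzymes digest the intact protein simultaneously; each stage-1
#' product is then digested by the stage-2 enzymes, honouring every stage-2
#' enzyme's `substrate_max_len` against the product's length (a prolyl
#' endopeptidase capped at 30 residues passes a 35-residue product through
#' uncleaved). Spans are composed back to parent coordinates, so the final
#' peptides still tile the parent.
#'
#' @inheritParams digest
#' @param stage1,stage2 Enzymes for each stage (same forms as `enzymes` in
#'   [digest()]).
#' @return A `digest_result` whose `cleaved_bonds` are in parent coordinates
#'   and whose `treatment` is `"<stage1>--><stage2>"`.
#' @export
sequential_digest <- function(protein, stage1, stage2, treatment = NULL, refine = TRUE) {
  protein <- as_protein_tbl(protein)
  stage1 <- as_enzyme_list(stage1)
  stage2 <- as_enzyme_list(stage2)
  treatment <- treatment %||%
    paste0(paste(names(stage1), collapse = "+"), "-->", paste(names(stage2), collapse = "+"))
  bonds <- lapply(seq_len(nrow(protein)), function(k) {
    seq1 <- protein$sequence[k]
    b1 <- digest_sequence(seq1, stage1, refine = refine)
    products <- cut_sequence(seq1, b1)
    b2 <- unlist(lapply(seq_len(nrow(products)), function(j) {
      local <- digest_sequence(products$sequence[j], stage2, refine = refine)
      if (length(local) == 0L) return(integer(0))
      products$start[j] + local - 1L
    }))
    sort(unique(c(b1, b2)))
  })
  names(bonds) <- protein$id
  peptides <- bind_rows(lapply(seq_len(nrow(protein)), function(k) {
    frags <- cut_sequence(protein$sequence[k], bonds[[k]])
    tibble(
      sequence = frags$sequence, parent_id = protein$id[k],
      start = frags$start, end = frags$end, treatment = treatment
    )
  }))
  structure(
    list(parents = protein, cleaved_bonds = bonds, peptides = peptides,
         treatment = treatment, enzymes = c(names(stage1), names(stage2))),
    class = "digest_result"
  )
}

#' Merge peptide sets from several treatments into unique sequences
#'
#' @param ... Peptide tibbles (or a single list of them).
#' @return A tibble with one row per distinct sequence, sorted by sequence,
#'   with `treatments` a list-column of the contributing treatment labels
#'   and `n_treatments` its length.
#' @export
merge_unique <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !is.data.frame(sets[[1]])) sets <- sets[[1]]
  all <- bind_rows(lapply(sets, function(s) {
    stopifnot(is.data.frame(s), "sequence" %in% names(s))
    if (!"treatment" %in% names(s)) s$treatment <- NA_character_
    s[, c("sequence", "treatment")]
  }))
  all |>
    group_by(.data$sequence) |>
    summarise(
      treatments = list(sort(unique(stats::na.omit(.data$treatment)))),
      .groups = "drop"
    ) |>
    mutate(n_treatments = lengths(.data$treatments)) |>
    arrange(.data$sequence)
}
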