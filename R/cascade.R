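## The screening cascade: gastrointestinal stability (with fragment
## re-entry), allergenicity, toxicity, then rule-of-5 permeability, with
## per-stage bookkeeping (input = pass + fail at every stage).
##
## The allergen and toxin stages consume externally computed verdicts
## (file-backed), because the underlying classifiers are trained models that
## this package does not reimplement; a constant predicate is provided for
## testing and for "screen everything through" runs. A predicate must have a
## verdict for every queried sequence -- a missing verdict is an error, not
## a silent pass.

#' Allergen/toxin predicates
#'
#' `predicate_file()` wraps a verdict TSV (columns `sequence` and the
#' predicate's `kind`, values `yes`/`no`); `predicate_constant()` returns a
#' fixed verdict for every sequence.
#'
#' @param path Verdict TSV.
#' @param kind `"allergen"` or `"toxin"` (also the column read from the
#'   file).
#' @param flagged Constant verdict for `predicate_constant()`: `FALSE`
#'   (default) means nothing is flagged.
#' @return A function `sequences -> logical` (`TRUE` = flagged, i.e. fails
#'   the stage), carrying attributes `kind` and `backend`.
#' @export
predicate_file <- function(path, kind = c("allergen", "toxin")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("predicate verdict file not found: %s", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!all(c("sequence", kind) %in% names(tbl))) {
    abort(sprintf("predicate file '%s' must have columns 'sequence' and '%s'", path, kind))
  }
  verdicts <- setNames(tolower(tbl[[kind]]) %in% c("yes", "true", "1"), toupper(tbl$sequence))
  f <- function(sequences) {
    sequences <- toupper(sequences)
    missing <- setdiff(sequences, names(verdicts))
    if (length(missing) > 0L) {
      abort(sprintf("%s predicate has no verdict for sequence '%s'", kind, missing[1]))
    }
    unname(verdicts[sequences])
  }
  structure(f, kind = kind, backend = "file")
}

#' @rdname predicate_file
#' @export
predicate_constant <- function(kind = c("allergen", "toxin"), flagged = FALSE) {
  kind <- match.arg(kind)
  structure(
    function(sequences) rep(flagged, length(sequences)),
    kind = kind, backend = "constant"
  )
}

#' Gastrointestinal-stability stage
#'
#' Peptides with zero predicted cleavage sites under the gastrointestinal
#' enzyme set are classified stable. The others are digested exhaustively
#' (to the re-digestion fixpoint) and their distinct fragments of length at
#' least 2 form the new-fragment list that re-enters the cascade; single
#' residues are dropped (they are no longer peptides).
#'
#' @param peptides Peptide tibble or character vector.
#' @param enzymes GI enzyme set (default: packaged pepsin pH 1.3, trypsin,
#'   chymotrypsin high-specificity tables).
#' @return A list: `stable` (tibble of input rows predicted stable),
#'   `fragments` (tibble of distinct new fragments, with `gi_parent` the
#'   sequences they came from), `unstable` (input rows that were cleaved).
#' @export
gi_stability_stage <- function(peptides,
                               enzymes = c("pepsin_ph1.3", "trypsin", "chymotrypsin_high")) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = toupper(as.character(peptides)))
  enzymes <- as_enzyme_list(enzymes)
  bonds <- lapply(peptides$sequence, digest_sequence, enzymes = enzymes, refine = TRUE)
  stable_idx <- lengths(bonds) == 0L
  stable <- peptides[stable_idx, , drop = FALSE]
  unstable <- peptides[!stable_idx, , drop = FALSE]
  frag_rows <- purrr::map2(
    peptides$sequence[!stable_idx], bonds[!stable_idx],
    function(s, b) {
      frags <- cut_sequence(s, b)
      tibble(sequence = frags$sequence, gi_parent = s)
    }
  )
  fragments <- bind_rows(frag_rows)
  if (nrow(fragments) > 0L) {
    fragments <- fragments |>
      filter(nchar(.data$sequence) >= 2L) |>
      group_by(.data$sequence) |>
      summarise(gi_parent = paste(sort(unique(.data$gi_parent)), collapse = ","),
                .groups = "drop") |>
      arrange(.data$sequence)
  } else {
    fragments <- tibble(sequence = character(), gi_parent = character())
  }
  list(stable = stable, fragments = fragments, unstable = unstable)
}

#' Run the full screening cascade
#'
#' Stage order: gastrointestinal stability (with distinct new fragments
#' re-entering the pool, their provenance recorded) -> allergenicity ->
#' toxicity -> rule-of-5 permeability, followed by a known/novel partition
#' of the finalists.
#'
#' @param peptides Initial candidate peptides (tibble or character vector).
#' @param allergen,toxin Predicates from [predicate_file()] /
#'   [predicate_constant()].
#' @param gi_enzymes GI enzyme set (see [gi_stability_stage()]).
#' @param known Known-antihypertensive reference for [classify_novel()].
#' @param max_violations Rule-of-5 verdict convention (see
#'   [rule_of_five()]).
#' @param logp_backend Passed to [physchem_profile()].
#' @param gi Set `FALSE` to skip the GI stage (the downstream stages then
#'   see the input pool unchanged).
#' @return A `cascade_report`: list with `stages` (per-stage counts:
#'   `stage`, `n_input`, `n_pass`, `n_fail`, `n_new_fragments`), `final`
#'   (profiled finalist tibble), `known`/`novel` partitions and counts, and
#'   `pools` (the peptide tibble entering each stage). `tidy()` returns the
#'   stage table.
#' @export
run_cascade <- function(peptides,
                        allergen = predicate_constant("allergen"),
                        toxin = predicate_constant("toxin"),
                        gi_enzymes = c("pepsin_ph1.3", "trypsin", "chymotrypsin_high"),
                        known = NULL,
                        max_violations = 1L,
                        logp_backend = NULL,
                        gi = TRUE) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = toupper(as.character(peptides)))
  peptides$sequence <- vapply(peptides$sequence, validate_sequence, character(1),
                              USE.NAMES = FALSE)
  stages <- list()
  pools <- list(input = peptides)

  if (gi) {
    gi_res <- gi_stability_stage(peptides, enzymes = gi_enzymes)
    stable <- gi_res$stable |> mutate(gi_origin = "stable")
    fragments <- gi_res$fragments |>
      filter(!.data$sequence %in% stable$sequence) |>
      mutate(gi_origin = "fragment")
    pool <- bind_rows(stable, fragments)
    stages[["gi_stability"]] <- tibble(
      stage = "gi_stability",
      n_input = nrow(peptides),
      n_pass = nrow(gi_res$stable),
      n_fail = nrow(gi_res$unstable),
      n_new_fragments = nrow(fragments)
    )
  } else {
    pool <- peptides
  }
  pools$allergenicity <- pool

  flagged_all <- allergen(pool$sequence)
  stages[["allergenicity"]] <- tibble(
    stage = "allergenicity", n_input = nrow(pool),
    n_pass = sum(!flagged_all), n_fail = sum(flagged_all),
    n_new_fragments = 0L
  )
  pool <- pool[!flagged_all, , drop = FALSE]
  pools$toxicity <- pool

  flagged_tox <- toxin(pool$sequence)
  stages[["toxicity"]] <- tibble(
    stage = "toxicity", n_input = nrow(pool),
    n_pass = sum(!flagged_tox), n_fail = sum(flagged_tox),
    n_new_fragments = 0L
  )
  pool <- pool[!flagged_tox, , drop = FALSE]
  pools$permeability <- pool

  profiled <- rule_of_five(physchem_profile(pool, logp_backend = logp_backend),
                           max_violations = max_violations)
  stages[["permeability"]] <- tibble(
    stage = "permeability", n_input = nrow(pool),
    n_pass = sum(profiled$ro5_pass), n_fail = sum(!profiled$ro5_pass),
    n_new_fragments = 0L
  )
  final <- profiled[profiled$ro5_pass, , drop = FALSE]
  partition <- classify_novel(final, known = known)

  structure(
    list(
      stages = bind_rows(stages),
      final = final,
      known = partition$known, novel = partition$novel,
      n_known = partition$n_known, n_novel = partition$n_novel,
      pools = pools
    ),
    class = "cascade_report"
  )
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(as.data.frame(x$stages), row.names = FALSE)
  cat(sprintf("final: %d peptide(s) (%d known, %d novel)\n",
              nrow(x$final), x$n_known, x$n_novel))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cascade_report <- function(x, ...) x$stages

#' Serialise a cascade report to JSON
#'
#' @param report A `cascade_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_report <- function(report, path) {
  stopifnot(inherits(report, "cascade_report"))
  jsonlite::write_json(
    list(
      stages = report$stages,
      final = report$final,
      n_known = report$n_known,
      n_novel = report$n_novel,
      known = report$known$sequence,
      novel = report$novel$sequence
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
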