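## Config-driven pipeline driver: digest -> annotate -> screen -> report.
## The same entry point backs the command-line interface; everything is a
## thin composition of the exported module functions, so results are
## reproducible from the config file and seed alone.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "pepscreen_out",
    protein = list(fasta = NULL, synthetic = list(length = 300L)),
    treatments = list(
      papain = list(stage1 = "papain"),
      ficin = list(stage1 = "ficin"),
      `papain+ficin` = list(stage1 = c("papain", "ficin")),
      `papain-->prep` = list(stage1 = "papain", stage2 = "prep"),
      `ficin-->prep` = list(stage1 = "ficin", stage2 = "prep"),
      `papain+ficin-->prep` = list(stage1 = c("papain", "ficin"), stage2 = "prep")
    ),
    reference_table = NULL,
    known_aht = NULL,
    scorer_file = NULL,
    activity_threshold = 0,
    predicates = list(allergen = "constant_pass", toxin = "constant_pass"),
    gi_enzymes = c("pepsin_ph1.3", "trypsin", "chymotrypsin_high"),
    ro5_max_violations = 1L
  )
}

#' Print the default pipeline configuration as YAML
#'
#' @return The default config (invisibly); prints YAML to the console.
#' @export
print_config <- function() {
  cfg <- default_config()
  cat(yaml::as.yaml(cfg))
  invisible(cfg)
}

merge_config <- function(user, defaults = default_config()) {
  for (key in names(user)) defaults[[key]] <- user[[key]]
  defaults
}

validate_config <- function(cfg) {
  for (f in c(cfg$protein$fasta, cfg$reference_table, cfg$known_aht, cfg$scorer_file)) {
    if (!is.null(f) && !file.exists(f)) {
      abort(sprintf("config references a missing file: %s", f))
    }
  }
  for (kind in c("allergen", "toxin")) {
    p <- cfg$predicates[[kind]]
    if (!is.null(p) && !identical(p, "constant_pass") && !file.exists(p)) {
      abort(sprintf("config references a missing %s predicate file: %s", kind, p))
    }
  }
  if (cfg$activity_threshold < -10 || cfg$activity_threshold > 10) {
    abort("activity_threshold outside the documented range [-10, 10]")
  }
  if (cfg$ro5_max_violations < 0 || cfg$ro5_max_violations > 4) {
    abort("ro5_max_violations must be between 0 and 4")
  }
  invisible(cfg)
}

config_predicate <- function(spec, kind) {
  if (is.null(spec) || identical(spec, "constant_pass")) {
    predicate_constant(kind)
  } else {
    predicate_file(spec, kind)
  }
}

table_versions <- function() {
  dir <- system.file("extdata", package = "pepscreen")
  files <- list.files(dir, recursive = TRUE, full.names = TRUE, pattern = "\\.(txt|tsv)$")
  vapply(files, function(f) {
    ln <- grep("version", readLines(f, n = 12L, warn = FALSE), value = TRUE)
    if (length(ln) == 0L) "unversioned" else str_trim(ln[1])
  }, character(1))
}

#' Run the full pipeline from a configuration
#'
#' Executes digest -> activity annotation -> screening cascade and writes
#' per-treatment peptide tables, the hydrolysis report, the cascade report
#' (JSON) and a run log recording the seed, thresholds and the version line
#' of every rule/reference table used. On error, partial outputs from this
#' run are removed and the error is re-thrown.
#'
#' @param config A config list, or path to a YAML config file. See
#'   [print_config()] for the defaults and structure.
#' @return A list with `hydrolysis` (tibble), `cascade` (a
#'   `cascade_report`), `candidates` (annotated peptide pool) and `paths`
#'   (written files), invisibly.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(merge_config(config))

  written <- character(0)
  result <- tryCatch({
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    protein <- if (!is.null(cfg$protein$fasta)) {
      read_fasta(cfg$protein$fasta)[1, ]
    } else {
      random_protein(cfg$protein$synthetic$length %||% 300L,
                     seed = derive_seed(cfg$seed, 1L))
    }

    reference <- load_reference_table(cfg$reference_table)
    scorer <- if (!is.null(cfg$scorer_file)) scorer_file(cfg$scorer_file) else NULL

    results <- lapply(names(cfg$treatments), function(nm) {
      tr <- cfg$treatments[[nm]]
      if (is.null(tr$stage2)) digest(protein, tr$stage1, treatment = nm)
      else sequential_digest(protein, tr$stage1, tr$stage2, treatment = nm)
    })
    names(results) <- names(cfg$treatments)
    hydro <- hydrolysis_report(
      protein, cfg$treatments,
      reference = reference$sequence[reference$lookup_eligible]
    )

    for (nm in names(results)) {
      p <- file.path(cfg$out_dir, sprintf("peptides_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", nm)))
      write_peptide_table(results[[nm]]$peptides, p)
      written <- c(written, p)
    }

    merged <- merge_unique(lapply(results, function(r) r$peptides))
    candidates <- merged |> filter(nchar(.data$sequence) >= 2L, nchar(.data$sequence) <= 6L)
    candidates <- annotate_activity(candidates, table = reference, scorer = scorer,
                                    threshold = cfg$activity_threshold)
    p <- file.path(cfg$out_dir, "candidates.tsv")
    write_peptide_table(candidates, p); written <- c(written, p)

    active <- candidates |> filter(.data$is_active)
    cascade <- run_cascade(
      active,
      allergen = config_predicate(cfg$predicates$allergen, "allergen"),
      toxin = config_predicate(cfg$predicates$toxin, "toxin"),
      gi_enzymes = cfg$gi_enzymes,
      known = if (!is.null(cfg$known_aht)) readr::read_tsv(cfg$known_aht, comment = "#",
                                                           show_col_types = FALSE) else NULL,
      max_violations = cfg$ro5_max_violations
    )

    p <- file.path(cfg$out_dir, "hydrolysis_report.tsv")
    readr::write_tsv(hydro, p, progress = FALSE); written <- c(written, p)
    p <- file.path(cfg$out_dir, "cascade_report.json")
    write_cascade_report(cascade, p); written <- c(written, p)

    log_path <- file.path(cfg$out_dir, "run_log.txt")
    versions <- table_versions()
    writeLines(c(
      sprintf("pepscreen %s", as.character(utils::packageVersion("pepscreen"))),
      sprintf("seed: %d", cfg$seed),
      sprintf("activity_threshold: %g", cfg$activity_threshold),
      sprintf("ro5_max_violations: %d", cfg$ro5_max_violations),
      sprintf("gi_enzymes: %s", paste(cfg$gi_enzymes, collapse = ",")),
      "table versions:",
      sprintf("  %s: %s", basename(names(versions)), unname(versions))
    ), log_path)
    written <- c(written, log_path)

    list(hydrolysis = hydro, cascade = cascade, candidates = candidates,
         paths = written)
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline run failed (partial outputs removed): %s",
                  conditionMessage(e)))
  })
  invisible(result)
}
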