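## Declarative cleavage-specificity rules.
##
## A specificity rule is a set of subsite constraints on the window around a
## scissile bond. Offsets use the Schechter-Berger nomenclature relative to
## bond i (the bond following residue i):
##
##   P4   P3   P2   P1  |  P1'  P2'
##  i-3  i-2  i-1   i   |  i+1  i+2
##
## A rule matches bond i when every constrained offset is inside the
## sequence AND its residue is in the allowed set; a constrained offset that
## falls outside the sequence fails the match (so "not Pro at P2" cannot be
## satisfied by a missing P2). A bond is cleaved when at least one rule
## matches and no block/exception pattern (rule-local or global) matches.
## Block patterns match only when all their constrained offsets are present.

OFFSET_MAP <- c("P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
                "P1'" = 1L, "P2'" = 2L)

parse_subsite_pattern <- function(text, where = "pattern") {
  tokens <- strsplit(str_trim(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) abort(sprintf("empty subsite %s", where))
  accept <- list()
  for (tok in tokens) {
    parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% names(OFFSET_MAP)) {
      abort(sprintf("cannot parse subsite token '%s' in %s (expected e.g. P1=KR or P2=!P)", tok, where))
    }
    set_txt <- parts[2]
    negate <- startsWith(set_txt, "!")
    if (negate) set_txt <- substring(set_txt, 2L)
    residues <- strsplit(toupper(set_txt), "", fixed = TRUE)[[1]]
    bad <- setdiff(residues, AA_ALPHABET)
    if (length(bad) > 0L) {
      abort(sprintf("unknown residue letter '%s' in %s", bad[1], where))
    }
    if (negate) residues <- setdiff(AA_ALPHABET, residues)
    accept[[parts[1]]] <- residues
  }
  accept
}

parse_rule_line <- function(line, where = "rule") {
  pieces <- strsplit(line, ";", fixed = TRUE)[[1]]
  accept <- parse_subsite_pattern(pieces[1], where = where)
  blocks <- list()
  if (length(pieces) > 1L) {
    for (p in pieces[-1]) {
      p <- str_trim(p)
      if (!grepl("^block\\s*:", p)) {
        abort(sprintf("expected 'block: ...' after ';' in %s, got '%s'", where, p))
      }
      blocks[[length(blocks) + 1L]] <-
        parse_subsite_pattern(sub("^block\\s*:", "", p), where = paste(where, "block"))
    }
  }
  list(accept = accept, blocks = blocks)
}

#' Construct an enzyme specificity object
#'
#' @param name Enzyme name (unique within a registry).
#' @param rules Character vector of rule lines, each of the form
#'   `"P2=W P1=K P1'=P"` with optional rule-local exceptions appended as
#'   `"; block: P1'=P"`. Sets may be negated with `!` (e.g. `P1'=!P`).
#' @param ec EC number (free text).
#' @param substrate_max_len Optional maximum substrate length (residues);
#'   the enzyme does not act on longer substrates. Must be `>= 2` when set.
#' @param global_blocks Character vector of block patterns applying to every
#'   rule.
#' @param source,version Provenance strings carried into reports.
#' @return An object of class `enzyme_spec`.
#' @export
#' @examples
#' after_k <- enzyme_spec("after_K", rules = "P1=K ; block: P1'=P")
#' find_cleavage_sites("AKAKA", after_k)
enzyme_spec <- function(name, rules, ec = NA_character_,
                        substrate_max_len = NA_integer_,
                        global_blocks = character(),
                        source = NA_character_, version = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, length(rules) >= 1L)
  if (!is.na(substrate_max_len) && substrate_max_len < 2L) {
    abort("substrate_max_len must be >= 2 when set")
  }
  parsed <- lapply(seq_along(rules), function(i) {
    parse_rule_line(rules[i], where = sprintf("%s rule %d", name, i))
  })
  gb <- lapply(global_blocks, parse_subsite_pattern, where = paste(name, "global block"))
  structure(
    list(
      name = name, ec = ec, rules = parsed,
      substrate_max_len = if (is.na(substrate_max_len)) NA_integer_ else as.integer(substrate_max_len),
      global_blocks = gb, source = source, version = version
    ),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s (EC %s)\n", x$name, x$ec %||% NA))
  if (!is.na(x$substrate_max_len)) {
    cat(sprintf("  substrate_max_len: %d residues\n", x$substrate_max_len))
  }
  cat(sprintf("  rules: %d, global blocks: %d\n", length(x$rules), length(x$global_blocks)))
  if (!is.na(x$version)) cat(sprintf("  table version: %s\n", x$version))
  invisible(x)
}

#' Load an enzyme rule table from a plain-text file
#'
#' The file format is line-oriented: `#` comments, `key: value` headers
#' (`name`, `ec`, `version`, `source`, `substrate_max_len`), one `rule:` line
#' per specificity pattern, and optional `global_block:` lines. See the
#' packaged tables under `system.file("extdata/enzymes", package =
#' "pepscreen")` for worked examples.
#'
#' @param path Path to a rule file.
#' @return An `enzyme_spec`.
#' @export
load_enzyme <- function(path) {
  if (!file.exists(path)) abort(sprintf("enzyme rule file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- str_trim(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list(); rules <- character(); gblocks <- character()
  for (ln in lines) {
    key <- str_trim(sub(":.*$", "", ln))
    val <- str_trim(sub("^[^:]*:", "", ln))
    if (key == "rule") rules <- c(rules, val)
    else if (key == "global_block") gblocks <- c(gblocks, val)
    else kv[[key]] <- val
  }
  if (is.null(kv$name)) abort(sprintf("rule file '%s' has no 'name:' line", path))
  if (length(rules) == 0L) abort(sprintf("rule file '%s' has no 'rule:' lines", path))
  enzyme_spec(
    name = kv$name, rules = rules, ec = kv$ec %||% NA_character_,
    substrate_max_len = as.integer(kv$substrate_max_len %||% NA),
    global_blocks = gblocks,
    source = kv$source %||% NA_character_, version = kv$version %||% NA_character_
  )
}

#' List or load packaged enzyme rule tables
#'
#' Packaged tables: `papain`, `ficin`, `prep` (prolyl endopeptidase,
#' substrate length capped at 30 residues and blocked at Pro-Pro contexts),
#' and the gastrointestinal set `pepsin_ph1.3`, `trypsin`,
#' `chymotrypsin_high`.
#'
#' @param names Character vector of packaged table names (see
#'   [list_enzymes()]), or paths to rule files.
#' @return For `load_enzymes()`, a named list of `enzyme_spec` objects; for
#'   `list_enzymes()`, a character vector of packaged table names.
#' @export
load_enzymes <- function(names) {
  specs <- lapply(names, function(nm) {
    if (file.exists(nm)) return(load_enzyme(nm))
    path <- system.file("extdata", "enzymes", paste0(nm, ".txt"), package = "pepscreen")
    if (!nzchar(path)) {
      abort(sprintf("no packaged enzyme '%s' (known: %s) and no such file", nm,
                    paste(list_enzymes(), collapse = ", ")))
    }
    load_enzyme(path)
  })
  setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' @rdname load_enzymes
#' @export
list_enzymes <- function() {
  dir <- system.file("extdata", "enzymes", package = "pepscreen")
  sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$"))
}

## Does `pattern` (named list offset -> allowed set) match the window around
## bond i? `chars` is the residue vector. Missing constrained offsets fail
## unless allow_missing_fail = FALSE (blocks simply do not apply then).
pattern_matches <- function(pattern, chars, i) {
  L <- length(chars)
  for (off_name in names(pattern)) {
    pos <- i + OFFSET_MAP[[off_name]]
    if (pos < 1L || pos > L) return(FALSE)
    if (!chars[pos] %in% pattern[[off_name]]) return(FALSE)
  }
  TRUE
}

#' Find cleavage sites of an enzyme on a sequence
#'
#' Returns the bond indices (bond i follows residue i) at which the enzyme
#' cleaves, applying the accept/block subsite logic described in
#' [enzyme_spec()]. If the enzyme carries a `substrate_max_len` and the
#' sequence is longer, the enzyme does not act and the result is empty.
#'
#' @param seq A sequence string (validated).
#' @param enzyme An `enzyme_spec`.
#' @return Sorted integer vector of cleaved bond indices (possibly empty).
#' @export
find_cleavage_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  seq <- validate_sequence(seq)
  L <- nchar(seq)
  if (L < 2L) return(integer(0))
  if (!is.na(enzyme$substrate_max_len) && L > enzyme$substrate_max_len) {
    return(integer(0))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sites <- integer(0)
  for (i in seq_len(L - 1L)) {
    hit <- FALSE
    for (rule in enzyme$rules) {
      if (pattern_matches(rule$accept, chars, i)) {
        blocked <- any(vapply(rule$blocks, pattern_matches, logical(1),
                              chars = chars, i = i))
        if (!blocked) { hit <- TRUE; break }
      }
    }
    if (hit && length(enzyme$global_blocks) > 0L) {
      if (any(vapply(enzyme$global_blocks, pattern_matches, logical(1),
                     chars = chars, i = i))) {
        hit <- FALSE
      }
    }
    if (hit) sites <- c(sites, i)
  }
  sites
}
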