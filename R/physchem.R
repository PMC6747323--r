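## Sequence-derived physicochemical properties of linear peptides, used by
## the permeability (rule-of-5) stage. All quantities are pure functions of
## the sequence, computed for the neutral linear form (no pH-dependent
## protonation states), which is the usual convention for rule-of-5 style
## property counting.
##
## Counting conventions (see the methods vignette for the full atom
## bookkeeping):
##   * H-bond donors are donor ATOMS: N or O bearing at least one hydrogen
##     (free alpha-amino N -- including proline's secondary amine -- each
##     non-proline backbone amide N-H, the C-terminal carboxyl O-H, and
##     side-chain N-H/O-H atoms from a per-residue table). Thiol S-H is not
##     a donor (N/O only).
##   * H-bond acceptors are N and O atoms EXCLUDING amide nitrogens
##     (backbone and side-chain amide N): the alpha-amino N, one backbone
##     carbonyl O per peptide bond, both carboxyl oxygens, plus side-chain
##     N/O per the table.
## Per-residue constants live in a versioned data file,
## extdata/reference/residue_properties.tsv.

.residue_props_cache <- new.env(parent = emptyenv())

#' Per-residue property table
#'
#' Average residue masses (Da), side-chain donor/acceptor atom counts, and
#' additive side-chain logP increments, read from the packaged, versioned
#' table `extdata/reference/residue_properties.tsv`.
#'
#' @return A tibble with columns `residue`, `avg_mass`, `sc_donors`,
#'   `sc_acceptors`, `logp_side`.
#' @export
residue_properties <- function() {
  if (is.null(.residue_props_cache$tbl)) {
    path <- system.file("extdata", "reference", "residue_properties.tsv",
                        package = "pepscreen")
    .residue_props_cache$tbl <- readr::read_tsv(
      path, comment = "#", show_col_types = FALSE, progress = FALSE
    )
  }
  .residue_props_cache$tbl
}

prop_lookup <- function(column) {
  tbl <- residue_properties()
  setNames(tbl[[column]], tbl$residue)
}

seq_chars <- function(sequence) {
  strsplit(validate_sequence(sequence), "", fixed = TRUE)[[1]]
}

## Mass of one water, average (Da); added once per peptide (condensation).
WATER_MASS <- 18.01528

#' Average molecular weight of peptides
#'
#' Sum of standard average residue masses plus one water.
#'
#' @param sequence Character vector of peptide sequences.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' molecular_weight("AK") # 217.27
molecular_weight <- function(sequence) {
  masses <- prop_lookup("avg_mass")
  vapply(sequence, function(s) {
    sum(masses[seq_chars(s)]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hydrogen-bond donor atom count
#'
#' @inheritParams molecular_weight
#' @return Integer vector of donor-atom counts.
#' @export
#' @examples
#' hbond_donors("NPPK") # 5
hbond_donors <- function(sequence) {
  sc <- prop_lookup("sc_donors")
  vapply(sequence, function(s) {
    ch <- seq_chars(s)
    n <- length(ch)
    backbone_nh <- if (n > 1L) sum(ch[-1] != "P") else 0L
    # alpha-amino N (1) + backbone N-H (non-Pro, positions 2..n) + COOH (1)
    as.integer(1L + backbone_nh + 1L + sum(sc[ch]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Hydrogen-bond acceptor count (amide nitrogens excluded)
#'
#' @inheritParams molecular_weight
#' @return Integer vector of acceptor counts.
#' @export
#' @examples
#' hbond_acceptors("NPPK") # 8
hbond_acceptors <- function(sequence) {
  sc <- prop_lookup("sc_acceptors")
  vapply(sequence, function(s) {
    ch <- seq_chars(s)
    n <- length(ch)
    # alpha-amino N (1) + backbone carbonyl O per bond (n-1) + carboxyl (2)
    as.integer(1L + (n - 1L) + 2L + sum(sc[ch]))
  }, integer(1), USE.NAMES = FALSE)
}

## Backbone/termini increments of the additive logP scheme. Calibrated so a
## single glycine reproduces the experimental octanol-water logP of glycine
## (about -3.2); each further backbone unit contributes a fixed amide
## penalty. Side-chain increments are the Fauchere-Pliska octanol scale.
LOGP_TERMINI <- -2.65
LOGP_BACKBONE_UNIT <- -0.56

#' Estimated octanol-water logP of peptides
#'
#' The default backend is an additive residue-contribution scheme (termini
#' constant + per-residue backbone unit + packaged side-chain increments).
#' It is a documented approximation for screening purposes, not a
#' reimplementation of an atom-typed calculator such as XLOGP3; supply
#' `backend` to substitute externally computed values.
#'
#' @inheritParams molecular_weight
#' @param backend `NULL` for the additive scheme; a named numeric vector of
#'   per-sequence logP values; or a function `sequences -> numeric`.
#' @return Numeric vector of logP estimates.
#' @export
logp <- function(sequence, backend = NULL) {
  sequence <- vapply(sequence, validate_sequence, character(1), USE.NAMES = FALSE)
  if (is.function(backend)) return(as.numeric(backend(sequence)))
  if (is.numeric(backend)) {
    missing <- setdiff(sequence, names(backend))
    if (length(missing) > 0L) {
      abort(sprintf("logP backend has no value for sequence '%s'", missing[1]))
    }
    return(unname(backend[sequence]))
  }
  side <- prop_lookup("logp_side")
  vapply(sequence, function(s) {
    ch <- seq_chars(s)
    LOGP_TERMINI + length(ch) * LOGP_BACKBONE_UNIT + sum(side[ch])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical profile of peptides
#'
#' @param peptides Peptide tibble (with a `sequence` column) or character
#'   vector.
#' @param logp_backend Passed to [logp()].
#' @return The input as a tibble with columns `mw`, `hbd`, `hba`, `logp`
#'   appended.
#' @export
physchem_profile <- function(peptides, logp_backend = NULL) {
  if (!is.data.frame(peptides)) peptides <- tibble(sequence = as.character(peptides))
  stopifnot("sequence" %in% names(peptides))
  peptides |>
    mutate(
      mw = molecular_weight(.data$sequence),
      hbd = hbond_donors(.data$sequence),
      hba = hbond_acceptors(.data$sequence),
      logp = logp(.data$sequence, backend = logp_backend)
    )
}

#' Rule-of-5 permeability filter
#'
#' Flags the four classical conditions (strict inequalities): MW > 500 Da,
#' more than 5 H-bond donors, more than 10 H-bond acceptors, logP > 5. As in
#' the original formulation of the alert, poor absorption is predicted when
#' at least two conditions are violated, so the default verdict passes a
#' profile with at most `max_violations = 1` violation; set
#' `max_violations = 0` for the stricter any-violation-fails convention.
#'
#' @param profile A profile tibble from [physchem_profile()] (or peptides,
#'   which will be profiled first).
#' @param max_violations Maximum number of violated conditions still
#'   compatible with a pass (default 1).
#' @return The profile with logical columns `viol_mw`, `viol_hbd`,
#'   `viol_hba`, `viol_logp`, integer `n_violations`, character `violations`
#'   and logical `ro5_pass` appended.
#' @export
rule_of_five <- function(profile, max_violations = 1L) {
  if (!is.data.frame(profile) || !all(c("mw", "hbd", "hba", "logp") %in% names(profile))) {
    profile <- physchem_profile(profile)
  }
  profile |>
    mutate(
      viol_mw = .data$mw > 500,
      viol_hbd = .data$hbd > 5L,
      viol_hba = .data$hba > 10L,
      viol_logp = .data$logp > 5,
      n_violations = as.integer(.data$viol_mw) + as.integer(.data$viol_hbd) +
        as.integer(.data$viol_hba) + as.integer(.data$viol_logp),
      violations = purrr::pmap_chr(
        list(.data$viol_mw, .data$viol_hbd, .data$viol_hba, .data$viol_logp),
        function(m, d, a, l) {
          paste(c("mw>500", "hbd>5", "hba>10", "logp>5")[c(m, d, a, l)], collapse = ";")
        }
      ),
      ro5_pass = .data$n_violations <= max_violations
    )
}
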