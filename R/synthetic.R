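## Seeded synthetic-data generators. Every generator is a pure function of
## its arguments and seed (the caller's RNG state is saved and restored), so
## multi-stage fixtures are reproducible from one global seed via
## derive_seed() substreams.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a substream seed from a global seed
#'
#' Deterministic mixing that stays below 2^31, so one pipeline seed yields
#' independent, reproducible seeds for each generator.
#'
#' @param seed Global integer seed.
#' @param stream Substream index (1, 2, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 2654435761 + stream * 40503) %% 2147483647)
}

#' Generate a random protein
#'
#' @param length Protein length (residues).
#' @param composition Named residue weights (default uniform over the 20
#'   canonical residues); weights are normalised to sum to 1.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param id Record id.
#' @return A one-row protein tibble (`id`, `sequence`).
#' @export
random_protein <- function(length, composition = NULL, seed, id = "synthetic") {
  stopifnot(length >= 1L)
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(!is.null(names(composition)), all(names(composition) %in% AA_ALPHABET),
            all(composition >= 0), sum(composition) > 0)
  composition <- composition / sum(composition)
  seqn <- with_seed(seed, paste(
    sample(names(composition), length, replace = TRUE, prob = composition),
    collapse = ""
  ))
  tibble(id = id, sequence = seqn)
}

## A residue alphabet over which the enzyme has zero cleavage sites: for
## every rule, at least one constrained offset has an accept set disjoint
## from the alphabet (so the rule can never match inside a backbone drawn
## from it). Built greedily by removing each rule's smallest accept set.
safe_alphabet <- function(enzyme) {
  S <- AA_ALPHABET
  for (rule in enzyme$rules) {
    sets <- rule$accept
    if (length(sets) == 0L) return(character(0))
    disabled <- any(vapply(sets, function(a) length(intersect(a, S)) == 0L, logical(1)))
    if (disabled) next
    S <- setdiff(S, sets[[which.min(lengths(sets))]])
  }
  all_disabled <- all(vapply(enzyme$rules, function(rule) {
    any(vapply(rule$accept, function(a) length(intersect(a, S)) == 0L, logical(1)))
  }, logical(1)))
  if (!all_disabled) character(0) else S
}

#' Spike cleavable motifs into a protein with guaranteed-release flanks
#'
#' The base protein is first sanitised: any residue that could participate
#' in a specificity match of `enzyme` is replaced by a residue outside every
#' accept/block set, so the backbone carries zero cleavage sites. Each motif
#' copy is then inserted behind a linker residue drawn from the enzyme's P1
#' accept set, making the bond before the motif cleavable; the motif's own
#' last residue must also lie in the P1 accept set so the bond after it is
#' cleaved. Release is verified against the digestion engine, making the
#' recorded ground truth provable rather than probabilistic: under
#' exhaustive digestion every spiked copy is released, so the relative
#' release frequency W of the spiked motifs is exactly 1.
#'
#' @param protein One-row protein tibble (e.g. from [random_protein()]).
#' @param motifs Named integer vector `c(AYK = 3)` or tibble with columns
#'   `motif`, `count`.
#' @param enzyme An `enzyme_spec` whose rules constrain P1 (e.g. a
#'   trypsin-like enzyme).
#' @param seed Integer seed for insertion positions.
#' @return A list: `protein` (spiked one-row tibble), `ground_truth` (tibble
#'   `sequence, start, end` of the expected released motif copies), and
#'   `enzyme` (its name).
#' @export
spike_motifs <- function(protein, motifs, enzyme, seed) {
  protein <- as_protein_tbl(protein)
  stopifnot(nrow(protein) == 1L, inherits(enzyme, "enzyme_spec"))
  if (!is.data.frame(motifs)) {
    motifs <- tibble(motif = names(motifs), count = as.integer(motifs))
  }
  stopifnot(all(c("motif", "count") %in% names(motifs)), all(motifs$count >= 0L))
  motifs$motif <- vapply(motifs$motif, validate_sequence, character(1))

  accept_p1 <- unique(unlist(lapply(enzyme$rules, function(r) r$accept[["P1"]])))
  if (length(accept_p1) == 0L) {
    abort("spike_motifs requires an enzyme whose rules constrain P1")
  }
  safe <- safe_alphabet(enzyme)
  if (length(safe) == 0L) abort("enzyme constrains every residue; no safe backbone alphabet")
  linker <- accept_p1[1]

  base <- seq_chars(protein$sequence)
  base[!base %in% safe] <- safe[1]

  copies <- motifs[rep(seq_len(nrow(motifs)), motifs$count), , drop = FALSE]
  if (nrow(copies) == 0L) {
    return(list(
      protein = tibble(id = protein$id, sequence = paste(base, collapse = "")),
      ground_truth = tibble(sequence = character(), start = integer(), end = integer()),
      enzyme = enzyme$name
    ))
  }
  bad <- !substr(copies$motif, nchar(copies$motif), nchar(copies$motif)) %in% accept_p1
  if (any(bad)) {
    abort(sprintf(
      "motif '%s' cannot be released by %s: its last residue is not in the enzyme's P1 accept set (append one of %s)",
      copies$motif[which(bad)[1]], enzyme$name, paste(accept_p1, collapse = ",")
    ))
  }
  if (length(base) < nrow(copies) + 1L) {
    abort("base protein too short for the requested number of motif copies")
  }
  # insertion points after distinct backbone positions (keeps blocks apart)
  pos <- with_seed(seed, sort(sample(seq_len(length(base) - 1L), nrow(copies))))
  order_idx <- with_seed(derive_seed(seed, 2L), sample(nrow(copies)))
  copies <- copies[order_idx, , drop = FALSE]

  out <- character(0); truth <- list(); cursor <- 0L; prev <- 0L
  for (k in seq_len(nrow(copies))) {
    seg <- base[(prev + 1L):pos[k]]
    out <- c(out, seg, linker)
    cursor <- cursor + length(seg) + 1L
    m <- seq_chars(copies$motif[k])
    truth[[k]] <- tibble(sequence = copies$motif[k],
                         start = cursor + 1L, end = cursor + length(m))
    out <- c(out, m)
    cursor <- cursor + length(m)
    prev <- pos[k]
  }
  out <- c(out, base[(prev + 1L):length(base)])
  spiked <- tibble(id = protein$id, sequence = paste(out, collapse = ""))
  truth <- bind_rows(truth)

  # verify the construction against the digestion engine
  res <- digest(spiked, list(enzyme))
  released <- res$peptides
  for (k in seq_len(nrow(truth))) {
    hit <- released$start == truth$start[k] & released$end == truth$end[k] &
      released$sequence == truth$sequence[k]
    if (!any(hit)) {
      abort(sprintf(
        "motif construction conflict: copy of '%s' at %d-%d is not released intact (overlapping or internally cleavable motif)",
        truth$sequence[k], truth$start[k], truth$end[k]
      ))
    }
  }
  list(protein = spiked, ground_truth = arrange(truth, .data$start), enzyme = enzyme$name)
}

#' Simulate logistic dose-response measurements
#'
#' `inhibition = 100 / (1 + (ic50 / conc)^hill) + N(0, noise_sd)`, seeded.
#'
#' @param concentrations Molar concentrations (should bracket the IC50 for
#'   downstream fitting).
#' @param ic50 True molar IC50.
#' @param hill True Hill slope.
#' @param noise_sd Gaussian noise standard deviation (percent inhibition).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return Tibble `conc, inhibition, true_inhibition`.
#' @export
synth_dose_response <- function(concentrations, ic50, hill = 1, noise_sd = 0,
                                replicates = 1L, seed = 1L) {
  stopifnot(all(concentrations > 0), ic50 > 0, noise_sd >= 0, replicates >= 1L)
  conc <- rep(concentrations, each = replicates)
  true <- 100 / (1 + (ic50 / conc)^hill)
  noise <- if (noise_sd > 0) with_seed(seed, rnorm(length(conc), 0, noise_sd)) else 0
  tibble(conc = conc, inhibition = true + noise, true_inhibition = true)
}

## Random 3D rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate a toy trajectory with known displacement structure
#'
#' Frames are rigid-body copies of a random base structure (optional random
#' rotation + translation per frame) plus per-atom Gaussian jitter, with one
#' designated flexible atom displaced by `+amplitude`/`-amplitude`
#' alternately along the x axis of the body frame. With zero jitter and an
#' even frame count the flexible atom's fluctuation about its mean is
#' exactly `amplitude` (its analytic RMSF), and all other atoms have RMSF 0
#' when `rigid = FALSE`.
#'
#' @param n_atoms Number of atoms (one residue per atom).
#' @param n_frames Number of frames.
#' @param amplitude Flexible-atom displacement amplitude (Angstrom).
#' @param jitter_sd Per-atom Gaussian jitter sd (Angstrom).
#' @param rigid Apply a random rigid-body motion to every frame (default
#'   `TRUE`); `FALSE` leaves frames in the body frame for closed-form
#'   checks.
#' @param dt Frame spacing (ps).
#' @param seed Integer seed.
#' @return A list: `trajectory` (a `pep_trajectory`), `expected`
#'   (`flexible_atom`, `amplitude`, `jitter_sd`).
#' @export
synth_trajectory <- function(n_atoms = 10L, n_frames = 20L, amplitude = 1,
                             jitter_sd = 0, rigid = TRUE, dt = 10, seed = 1L) {
  stopifnot(n_atoms >= 2L, n_frames >= 2L, amplitude >= 0, jitter_sd >= 0)
  with_seed(seed, {
    base <- matrix(runif(n_atoms * 3, -10, 10), ncol = 3)
    flexible <- 1L
    coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
    for (m in seq_len(n_frames)) {
      fr <- base
      fr[flexible, 1] <- fr[flexible, 1] + amplitude * if (m %% 2 == 0) 1 else -1
      if (jitter_sd > 0) fr <- fr + matrix(rnorm(n_atoms * 3, 0, jitter_sd), ncol = 3)
      if (rigid) {
        fr <- fr %*% t(random_rotation())
        fr <- sweep(fr, 2, runif(3, -5, 5), `+`)
      }
      coords[m, , ] <- fr
    }
    atoms <- tibble(
      name = paste0("C", seq_len(n_atoms)), element = "C",
      resid = seq_len(n_atoms), resname = "GLY", chain = "A"
    )
    list(
      trajectory = trajectory3d(atoms, coords, times = (seq_len(n_frames) - 1) * dt),
      expected = list(flexible_atom = flexible, amplitude = amplitude,
                      jitter_sd = jitter_sd)
    )
  })
}
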