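# Independent oracle implementations used for dual-route checks. These are
# deliberately written with different mechanics (substr/regex instead of
# character vectors and %in%) than the package code they validate.

screened_fixture <- function() {
  readr::read_tsv(
    system.file("extdata", "reference", "screened_peptides.tsv", package = "pepscreen"),
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
}

# Brute-force window-scan cleavage-site oracle.
oracle_sites <- function(seq, enzyme) {
  L <- nchar(seq)
  if (L < 2L) return(integer(0))
  if (!is.na(enzyme$substrate_max_len) && L > enzyme$substrate_max_len) {
    return(integer(0))
  }
  offs <- c("P4" = -3, "P3" = -2, "P2" = -1, "P1" = 0, "P1'" = 1, "P2'" = 2)
  pat_ok <- function(pat, i) {
    for (nm in names(pat)) {
      p <- i + offs[[nm]]
      if (p < 1 || p > L) return(FALSE)
      ch <- substr(seq, p, p)
      if (!grepl(ch, paste(pat[[nm]], collapse = ""), fixed = TRUE)) return(FALSE)
    }
    TRUE
  }
  out <- integer(0)
  for (i in 1:(L - 1)) {
    cut <- FALSE
    for (rule in enzyme$rules) {
      if (pat_ok(rule$accept, i)) {
        blocked <- FALSE
        for (b in rule$blocks) if (pat_ok(b, i)) { blocked <- TRUE; break }
        if (!blocked) { cut <- TRUE; break }
      }
    }
    if (cut) {
      for (g in enzyme$global_blocks) if (pat_ok(g, i)) { cut <- FALSE; break }
    }
    if (cut) out <- c(out, i)
  }
  out
}

# Independent exhaustive-digestion oracle: cut, then keep re-cutting the
# fragment strings until nothing changes; returns the fragment multiset.
oracle_digest_frags <- function(seq, enzymes) {
  frags <- seq
  repeat {
    nxt <- unlist(lapply(frags, function(f) {
      sites <- sort(unique(unlist(lapply(enzymes, function(e) oracle_sites(f, e)))))
      if (length(sites) == 0L) return(f)
      substring(f, c(1L, sites + 1L), c(sites, nchar(f)))
    }), use.names = FALSE)
    if (identical(nxt, frags)) break
    frags <- nxt
  }
  frags
}

# Horn quaternion RMSD oracle (closed-form optimal superposition).
horn_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P))
}

# Monte-Carlo SASA oracle: random points on each expanded sphere, buried if
# inside any other expanded sphere.
mc_sasa <- function(xyz, radii, probe = 1.4, n_mc = 20000L) {
  rr <- radii + probe
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(n_mc * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rr[i], 2, xyz[i, ], `+`)
    buried <- rep(FALSE, n_mc)
    for (j in seq_len(n)[-i]) {
      buried <- buried | rowSums(sweep(pts, 2, xyz[j, ])^2) < rr[j]^2
    }
    total <- total + 4 * pi * rr[i]^2 * mean(!buried)
  }
  total
}

random_test_sequence <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
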