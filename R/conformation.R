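## Conformational metrics on coordinate data (single structures and
## multi-model trajectories). PDB parsing is delegated to bio3d; the metrics
## themselves are implemented here:
##   * RMSD with optional Kabsch (SVD) superposition,
##   * per-residue RMSF about the time-averaged positions,
##   * mass-weighted radius of gyration,
##   * Shrake-Rupley solvent-accessible surface area with a deterministic
##     golden-spiral point set,
##   * geometric hydrogen-bond counting (distance + donor-H-acceptor angle),
##   * metal-coordination distance series,
##   * an equilibration check on an RMSD series (sliding-window range).

ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, ZN = 65.38, FE = 55.845, MG = 24.305, CA = 40.078, "NA" = 22.990,
  K = 39.098, CL = 35.45, F = 18.998
)

## Van der Waals radii (Angstrom) used for SASA; override per structure via
## the `radii` field.
ELEMENT_VDW <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
  ZN = 1.39, FE = 1.52, MG = 1.73, CA = 2.31, CL = 1.75, F = 1.47
)

#' Construct a structure (one conformation)
#'
#' @param atoms Tibble with at least `name` and `element`; optional `resid`,
#'   `resname`, `chain`.
#' @param xyz Numeric n-by-3 coordinate matrix (Angstrom).
#' @param masses Optional atomic masses; defaults to an element lookup.
#' @param radii Optional van der Waals radii for SASA.
#' @return An object of class `pep_structure`.
#' @export
structure3d <- function(atoms, xyz, masses = NULL, radii = NULL) {
  atoms <- as_tibble(atoms)
  stopifnot("element" %in% names(atoms))
  if (!"name" %in% names(atoms)) atoms$name <- atoms$element
  if (!"resid" %in% names(atoms)) atoms$resid <- 1L
  if (!"resname" %in% names(atoms)) atoms$resname <- NA_character_
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == nrow(atoms))
  if (any(!is.finite(xyz))) abort("structure coordinates must be finite")
  if (is.null(masses)) masses <- unname(ELEMENT_MASSES[toupper(atoms$element)])
  structure(
    list(atoms = atoms, xyz = xyz, masses = masses, radii = radii),
    class = "pep_structure"
  )
}

#' Construct a trajectory (ordered frames over one atom table)
#'
#' @param atoms Atom tibble shared by all frames.
#' @param coords Numeric array `frames x atoms x 3` or a list of n-by-3
#'   matrices.
#' @param times Frame times (ps), strictly increasing; defaults to
#'   `0, 1, ...`.
#' @inheritParams structure3d
#' @return An object of class `pep_trajectory`.
#' @export
trajectory3d <- function(atoms, coords, times = NULL, masses = NULL, radii = NULL) {
  if (is.list(coords)) {
    coords <- array(
      unlist(lapply(coords, t)),
      dim = c(3L, nrow(coords[[1]]), length(coords))
    )
    coords <- aperm(coords, c(3L, 2L, 1L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_frames <- dim(coords)[1]
  times <- times %||% seq(0, length.out = n_frames)
  stopifnot(length(times) == n_frames, all(diff(times) > 0) || n_frames == 1L)
  frame1 <- structure3d(atoms, coords[1, , , drop = TRUE], masses = masses, radii = radii)
  structure(
    list(atoms = frame1$atoms, coords = coords, times = times,
         masses = frame1$masses, radii = radii),
    class = "pep_trajectory"
  )
}

#' @export
print.pep_structure <- function(x, ...) {
  cat(sprintf("<pep_structure> %d atoms, %d residue(s)\n",
              nrow(x$atoms), length(unique(x$atoms$resid))))
  invisible(x)
}

#' @export
print.pep_trajectory <- function(x, ...) {
  cat(sprintf("<pep_trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              dim(x$coords)[1], nrow(x$atoms), min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pep_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory as a structure
#' @param traj A `pep_trajectory`.
#' @param i Frame index (1-based).
#' @return A `pep_structure`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure3d(traj$atoms, traj$coords[i, , , drop = TRUE],
              masses = traj$masses, radii = traj$radii)
}

#' Read a (possibly multi-model) PDB file
#'
#' Wraps [bio3d::read.pdb()]. A single-model file yields a `pep_structure`;
#' a multi-model file yields a `pep_trajectory` whose frame times are
#' `(model - 1) * dt`.
#'
#' @param path PDB file.
#' @param dt Time spacing between models, ps (default 1).
#' @return `pep_structure` or `pep_trajectory`.
#' @export
read_structure_pdb <- function(path, dt = 1) {
  if (!file.exists(path)) abort(sprintf("PDB file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- tibble(
    name = pdb$atom$elety,
    element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                     substr(gsub("[0-9]", "", pdb$atom$elety), 1, 1),
                     pdb$atom$elesy),
    resid = pdb$atom$resno,
    resname = pdb$atom$resid,
    chain = pdb$atom$chain
  )
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  if (is.null(n_models) || n_models == 1L) {
    return(structure3d(atoms, matrix(as.numeric(xyz), ncol = 3, byrow = TRUE)))
  }
  coords <- array(NA_real_, dim = c(n_models, nrow(atoms), 3L))
  for (m in seq_len(n_models)) {
    coords[m, , ] <- matrix(as.numeric(xyz[m, ]), ncol = 3, byrow = TRUE)
  }
  trajectory3d(atoms, coords, times = (seq_len(n_models) - 1) * dt)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A `pep_trajectory` (or `pep_structure` for a single model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(traj, path) {
  if (inherits(traj, "pep_structure")) {
    traj <- trajectory3d(traj$atoms, array(traj$xyz, dim = c(1L, nrow(traj$xyz), 3L)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  for (m in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    for (k in seq_len(nrow(at))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        k, substr(at$name[k], 1, 4), substr(at$resname[k] %||% "UNK", 1, 3),
        ifelse(is.na(at$chain[k]) || !nzchar(at$chain[k]), "A", at$chain[k]),
        at$resid[k],
        traj$coords[m, k, 1], traj$coords[m, k, 2], traj$coords[m, k, 3],
        1, 0, toupper(at$element[k])
      ), con)
    }
    writeLines(c("ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

coords_of <- function(x, selection = NULL) {
  m <- if (inherits(x, "pep_structure")) x$xyz else as.matrix(x)
  if (!is.null(selection)) m <- m[selection, , drop = FALSE]
  m
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of `mobile` onto `target`
#' (rotation via SVD with proper-rotation correction, plus translation).
#'
#' @param mobile,target n-by-3 coordinate matrices with matched rows.
#' @return The transformed `mobile` coordinates.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(all(dim(mobile) == dim(target)), ncol(mobile) == 3L)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2, ct, `+`)
}

#' Root-mean-square deviation between two conformations
#'
#' @param a,b `pep_structure`s or n-by-3 matrices with matched atoms.
#' @param superpose Apply Kabsch superposition first (default `TRUE`).
#' @param selection Optional integer atom indices used for both structures.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = TRUE, selection = NULL) {
  A <- coords_of(a, selection); B <- coords_of(b, selection)
  if (!all(dim(A) == dim(B))) {
    abort(sprintf("mismatched selections: %d vs %d atoms", nrow(A), nrow(B)))
  }
  if (superpose) A <- kabsch_superpose(A, B)
  sqrt(mean(rowSums((A - B)^2)))
}

#' RMSD of every trajectory frame to a reference
#'
#' @param traj A `pep_trajectory`.
#' @param ref Reference frame index (default 1) or a `pep_structure`.
#' @inheritParams rmsd
#' @return Tibble with `frame`, `time`, `rmsd`.
#' @export
rmsd_series <- function(traj, ref = 1L, superpose = TRUE, selection = NULL) {
  R <- if (inherits(ref, "pep_structure")) coords_of(ref, selection)
       else coords_of(traj_frame(traj, ref), selection)
  tibble(
    frame = seq_len(n_frames(traj)),
    time = traj$times,
    rmsd = vapply(seq_len(n_frames(traj)), function(m) {
      rmsd(traj$coords[m, , , drop = TRUE], R, superpose = superpose,
           selection = selection)
    }, numeric(1))
  )
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the first frame, then each atom's
#' mean-square deviation from its time-averaged position is computed; a
#' residue's RMSF is the square root of the mean MSF over its atoms.
#'
#' @param traj A `pep_trajectory` with at least 2 frames.
#' @param superpose Superpose frames onto frame 1 first (default `TRUE`).
#' @return Tibble with `resid`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2L) abort("RMSF requires at least 2 frames")
  n_atoms <- nrow(traj$atoms)
  ref <- traj$coords[1, , , drop = TRUE]
  aligned <- array(NA_real_, dim = dim(traj$coords))
  for (m in seq_len(nf)) {
    fr <- traj$coords[m, , , drop = TRUE]
    aligned[m, , ] <- if (superpose) kabsch_superpose(fr, ref) else fr
  }
  mean_pos <- apply(aligned, c(2, 3), mean)
  msf <- vapply(seq_len(n_atoms), function(k) {
    d <- sweep(aligned[, k, , drop = TRUE], 2, mean_pos[k, ])
    mean(rowSums(d^2))
  }, numeric(1))
  tibble(resid = traj$atoms$resid, resname = traj$atoms$resname, msf = msf) |>
    group_by(.data$resid) |>
    summarise(resname = dplyr::first(.data$resname),
              rmsf = sqrt(mean(.data$msf)), .groups = "drop")
}

#' Radius of gyration
#'
#' `sqrt(sum(m_i * |r_i - r_com|^2) / sum(m_i))`, mass-weighted by default.
#'
#' @param x A `pep_structure` or `pep_trajectory`.
#' @param mass_weighted Use atomic masses (default); otherwise unit weights.
#' @return A single value for a structure; a tibble `frame, time, rg` for a
#'   trajectory.
#' @export
radius_of_gyration <- function(x, mass_weighted = TRUE) {
  rg_one <- function(xyz, masses) {
    w <- if (mass_weighted) masses else rep(1, nrow(xyz))
    if (any(!is.finite(w))) abort("missing atomic mass; supply masses explicitly")
    W <- sum(w)
    if (W <= 0) abort("total mass must be positive")
    com <- colSums(xyz * w) / W
    sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)) / W)
  }
  if (inherits(x, "pep_structure")) return(rg_one(x$xyz, x$masses))
  stopifnot(inherits(x, "pep_trajectory"))
  tibble(
    frame = seq_len(n_frames(x)), time = x$times,
    rg = vapply(seq_len(n_frames(x)), function(m) {
      rg_one(x$coords[m, , , drop = TRUE], x$masses)
    }, numeric(1))
  )
}

## Deterministic, roughly uniform unit-sphere point set (golden spiral).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius `r_vdw + probe` is sampled with a
#' deterministic golden-spiral point set; points inside any neighbouring
#' atom's expanded sphere are buried. Fixed `n_points` gives bit-reproducible
#' results.
#'
#' @param x A `pep_structure`.
#' @param probe Probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960).
#' @param radii Optional per-atom radii; defaults to `x$radii` or the
#'   packaged element table. A missing radius is an error naming the atom.
#' @return A list: `total` (Angstrom^2) and `per_atom` tibble.
#' @export
sasa <- function(x, probe = 1.4, n_points = 960L, radii = NULL) {
  stopifnot(inherits(x, "pep_structure"))
  n <- nrow(x$atoms)
  radii <- radii %||% x$radii %||% unname(ELEMENT_VDW[toupper(x$atoms$element)])
  if (any(is.na(radii))) {
    k <- which(is.na(radii))[1]
    abort(sprintf("no van der Waals radius for atom %d (element '%s'); supply `radii`",
                  k, x$atoms$element[k]))
  }
  pts <- sphere_points(n_points)
  rr <- radii + probe
  xyz <- x$xyz
  per_atom <- vapply(seq_len(n), function(i) {
    # neighbours that can bury points of atom i
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rr[i] + rr)^2 & seq_len(n) != i)
    surf <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      still <- which(accessible)
      if (length(still) == 0L) break
      dj2 <- rowSums(sweep(surf[still, , drop = FALSE], 2, xyz[j, ])^2)
      accessible[still[dj2 < rr[j]^2]] <- FALSE
    }
    4 * pi * rr[i]^2 * sum(accessible) / n_points
  }, numeric(1))
  list(
    total = sum(per_atom),
    per_atom = tibble(atom = seq_len(n), name = x$atoms$name,
                      element = x$atoms$element, area = per_atom)
  )
}

## SASA per frame of a trajectory.
#' @rdname sasa
#' @param traj A `pep_trajectory`.
#' @export
sasa_series <- function(traj, probe = 1.4, n_points = 960L, radii = NULL) {
  tibble(
    frame = seq_len(n_frames(traj)), time = traj$times,
    sasa = vapply(seq_len(n_frames(traj)), function(m) {
      sasa(traj_frame(traj, m), probe = probe, n_points = n_points, radii = radii)$total
    }, numeric(1))
  )
}

angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Geometric hydrogen-bond count
#'
#' A donor/acceptor pair is hydrogen-bonded when the donor-acceptor distance
#' is at most `d_max` and the donor-H-acceptor angle is at least
#' `angle_min`. The criteria are exposed because published analyses vary;
#' the defaults (3.5 Angstrom, 120 degrees) are common molecular-dynamics
#' practice.
#'
#' @param x A `pep_structure`.
#' @param donors Data frame with integer columns `donor` and `hydrogen`
#'   (atom indices).
#' @param acceptors Acceptor atoms (indices or names).
#' @param d_max Maximum donor-acceptor distance (Angstrom).
#' @param angle_min Minimum donor-H-acceptor angle (degrees).
#' @return Integer hydrogen-bond count.
#' @export
count_hbonds <- function(x, donors, acceptors, d_max = 3.5, angle_min = 120) {
  stopifnot(inherits(x, "pep_structure"), is.data.frame(donors),
            all(c("donor", "hydrogen") %in% names(donors)))
  xyz <- x$xyz
  di <- vapply(donors$donor, function(s) resolve_atoms(x, s)[1], integer(1))
  hi <- vapply(donors$hydrogen, function(s) resolve_atoms(x, s)[1], integer(1))
  ai <- resolve_atoms(x, acceptors)
  n <- 0L
  for (k in seq_along(di)) {
    d <- di[k]; h <- hi[k]
    for (a in ai) {
      if (a == d) next
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > d_max) next
      if (angle_deg(xyz[d, ], xyz[h, ], xyz[a, ]) >= angle_min) n <- n + 1L
    }
  }
  n
}

#' Hydrogen-bond count per frame and its frequency histogram
#'
#' @param traj A `pep_trajectory`.
#' @inheritParams count_hbonds
#' @return A list: `series` (tibble `frame, time, n_hbonds`) and `histogram`
#'   (tibble `n_hbonds, frequency`, frequencies summing to 1).
#' @export
hbond_trajectory <- function(traj, donors, acceptors, d_max = 3.5, angle_min = 120) {
  counts <- vapply(seq_len(n_frames(traj)), function(m) {
    count_hbonds(traj_frame(traj, m), donors, acceptors, d_max, angle_min)
  }, integer(1))
  histogram <- tibble(n_hbonds = sort(unique(counts))) |>
    mutate(frequency = vapply(.data$n_hbonds, function(k) mean(counts == k), numeric(1)))
  list(
    series = tibble(frame = seq_len(n_frames(traj)), time = traj$times, n_hbonds = counts),
    histogram = histogram
  )
}

resolve_atoms <- function(x, spec) {
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (any(idx < 1L | idx > nrow(x$atoms))) abort("atom index out of range")
    return(idx)
  }
  idx <- which(x$atoms$name %in% spec)
  if (length(idx) == 0L) {
    abort(sprintf("cannot resolve atom name(s): %s", paste(spec, collapse = ", ")))
  }
  idx
}

#' Coordination distances from a centre atom
#'
#' Euclidean distances from a centre atom (e.g. a catalytic Zn(II)) to each
#' partner atom, per frame.
#'
#' @param x A `pep_structure` or `pep_trajectory`.
#' @param center One atom (index or name).
#' @param partners Atom indices or names.
#' @return Tibble `frame, time, partner, distance` (a structure is treated
#'   as a single frame at time 0).
#' @export
coordination_distances <- function(x, center, partners) {
  if (inherits(x, "pep_structure")) {
    x <- trajectory3d(x$atoms, array(x$xyz, dim = c(1L, nrow(x$xyz), 3L)),
                      masses = x$masses)
  }
  fr1 <- traj_frame(x, 1L)
  ci <- resolve_atoms(fr1, center)
  if (length(ci) != 1L) abort("`center` must resolve to exactly one atom")
  pi_ <- resolve_atoms(fr1, partners)
  labels <- paste0(x$atoms$name[pi_], "_", pi_)
  bind_rows(lapply(seq_len(n_frames(x)), function(m) {
    xyz <- x$coords[m, , , drop = TRUE]
    tibble(
      frame = m, time = x$times[m], partner = labels,
      distance = sqrt(rowSums(sweep(xyz[pi_, , drop = FALSE], 2, xyz[ci, ])^2))
    )
  }))
}

#' Equilibration check on an RMSD series
#'
#' The system is considered equilibrated from the earliest time after which
#' every sliding window of `window` consecutive samples has a range
#' (max - min) within `tolerance` — e.g. an RMSD trace fluctuating within
#' 0.1 nm (1 Angstrom, the default) of itself.
#'
#' @param series Numeric RMSD values, or the tibble from [rmsd_series()].
#' @param window Window length in samples (must not exceed the series).
#' @param tolerance Maximum in-window range, same units as the series
#'   (default 1.0, i.e. 0.1 nm for Angstrom series).
#' @return A list: `stable` (logical), `first_stable_index` (NA when never
#'   stable) and `first_stable_time` when times are available.
#' @export
equilibration_check <- function(series, window, tolerance = 1.0) {
  times <- NULL
  if (is.data.frame(series)) {
    times <- series$time
    col <- intersect(c("rmsd", "value"), names(series))
    if (length(col) == 0L) abort("series data frame needs an 'rmsd' or 'value' column")
    series <- series[[col[1]]]
  }
  n <- length(series)
  if (window > n) abort("window is longer than the series")
  if (window < 2L) abort("window must span at least 2 samples")
  starts <- seq_len(n - window + 1L)
  ok <- vapply(starts, function(t0) {
    w <- series[t0:(t0 + window - 1L)]
    (max(w) - min(w)) <= tolerance
  }, logical(1))
  # earliest start from which every later window is within tolerance
  first <- NA_integer_
  if (any(ok)) {
    suffix_ok <- rev(cumprod(rev(ok))) == 1
    if (any(suffix_ok)) first <- starts[which(suffix_ok)[1]]
  }
  list(
    stable = !is.na(first),
    first_stable_index = first,
    first_stable_time = if (!is.na(first) && !is.null(times)) times[first] else NA_real_
  )
}
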