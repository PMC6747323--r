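make_structure <- function(xyz, element = "C") {
  n <- nrow(xyz)
  structure3d(
    tibble::tibble(name = paste0("A", seq_len(n)), element = element,
                   resid = seq_len(n), resname = "GLY", chain = "A"),
    xyz
  )
}

test_that("Kabsch superposition matches the quaternion oracle on random pairs", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    X <- matrix(rnorm(n * 3, sd = 5), ncol = 3)
    Y <- matrix(rnorm(n * 3, sd = 5), ncol = 3)
    expect_lt(abs(rmsd(X, Y, superpose = TRUE) - horn_rmsd(X, Y)), 1e-8)
  }
})

test_that("RMSD of a rigidly moved copy is zero after superposition", {
  set.seed(7)
  X <- matrix(rnorm(30, sd = 4), ncol = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- sweep(X %*% t(R), 2, c(3, -2, 8), `+`)
  expect_lt(rmsd(X, Y, superpose = TRUE), 1e-10)
  expect_gt(rmsd(X, Y, superpose = FALSE), 1)
})

test_that("rmsd validates matched selections", {
  a <- make_structure(matrix(rnorm(12), ncol = 3))
  b <- make_structure(matrix(rnorm(15), ncol = 3))
  expect_error(rmsd(a, b), "mismatched selections")
  expect_silent(rmsd(a, b, selection = 1:4))
})

test_that("rmsd_series is zero at the reference frame and jitter-free trajectories are flat", {
  st <- synth_trajectory(n_atoms = 6, n_frames = 10, amplitude = 0,
                         jitter_sd = 0, rigid = TRUE, seed = 5)
  rs <- rmsd_series(st$trajectory)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-10)
  expect_true(all(rs$rmsd < 1e-8))  # rigid-body motion only
})

test_that("RMSF recovers the analytic flexible-atom amplitude", {
  st <- synth_trajectory(n_atoms = 8, n_frames = 20, amplitude = 1.5,
                         jitter_sd = 0, rigid = FALSE, seed = 3)
  r <- rmsf(st$trajectory, superpose = FALSE)
  expect_equal(r$rmsf[st$expected$flexible_atom], st$expected$amplitude,
               tolerance = 1e-12)
  expect_true(all(r$rmsf[-st$expected$flexible_atom] < 1e-12))
  # with superposition on a rigid-body trajectory the same structure emerges
  st2 <- synth_trajectory(n_atoms = 8, n_frames = 20, amplitude = 1.5,
                          jitter_sd = 0, rigid = TRUE, seed = 3)
  r2 <- rmsf(st2$trajectory, superpose = TRUE)
  expect_identical(which.max(r2$rmsf), st2$expected$flexible_atom)
})

test_that("radius of gyration matches closed forms", {
  # two unit-mass points at +-1 on x: rg = 1
  s <- make_structure(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(radius_of_gyration(s, mass_weighted = FALSE), 1)
  # mass weighting shifts the centre: masses 3 and 1 at x = 0, 4
  s2 <- structure3d(tibble::tibble(name = c("a", "b"), element = "C"),
                    rbind(c(0, 0, 0), c(4, 0, 0)), masses = c(3, 1))
  # com = 1; rg = sqrt((3*1 + 1*9)/4) = sqrt(3)
  expect_equal(radius_of_gyration(s2), sqrt(3), tolerance = 1e-12)
})

test_that("single-sphere SASA is within 1% of 4*pi*(r+probe)^2", {
  s <- make_structure(matrix(0, 1, 3))
  a <- sasa(s, probe = 1.4, n_points = 960L)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(a$total - analytic) / analytic, 0.01)
})

test_that("SASA of overlapping atoms matches a Monte-Carlo oracle within 2%", {
  set.seed(11)
  xyz <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(0.9, 1.4, 0.3), c(0.5, -1.2, 1.0))
  radii <- c(1.7, 1.52, 1.55, 1.7)
  s <- structure3d(tibble::tibble(name = paste0("a", 1:4),
                                  element = c("C", "O", "N", "C")), xyz)
  got <- sasa(s, n_points = 2000L, radii = radii)$total
  want <- mc_sasa(xyz, radii, n_mc = 40000L)
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("SASA decreases when atoms approach (burial) and errors on unknown radii", {
  far <- make_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  near <- make_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_gt(sasa(far)$total, sasa(near)$total)
  odd <- structure3d(tibble::tibble(name = "x", element = "XX"), matrix(0, 1, 3))
  expect_error(sasa(odd), "no van der Waals radius for atom 1")
})

test_that("geometric hydrogen-bond detection applies both criteria", {
  at <- tibble::tibble(name = c("N1", "H1", "O1"), element = c("N", "H", "O"))
  lin <- structure3d(at, rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))
  don <- data.frame(donor = "N1", hydrogen = "H1")
  expect_identical(count_hbonds(lin, don, "O1"), 1L)
  # too far
  far <- structure3d(at, rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0)))
  expect_identical(count_hbonds(far, don, "O1"), 0L)
  # bad angle: acceptor beside the hydrogen (D-H-A near 45 degrees)
  bent <- structure3d(at, rbind(c(0, 0, 0), c(1, 0, 0), c(0.3, 0.9, 0)))
  expect_identical(count_hbonds(bent, don, "O1"), 0L)
})

test_that("hbond_trajectory histogram frequencies sum to 1", {
  at <- tibble::tibble(name = c("N1", "H1", "O1"), element = c("N", "H", "O"))
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0))
  coords <- array(NA_real_, dim = c(4, 3, 3))
  coords[1, , ] <- near; coords[2, , ] <- far; coords[3, , ] <- near; coords[4, , ] <- near
  traj <- trajectory3d(at, coords)
  hb <- hbond_trajectory(traj, data.frame(donor = "N1", hydrogen = "H1"), "O1")
  expect_identical(hb$series$n_hbonds, c(1L, 0L, 1L, 1L))
  expect_equal(sum(hb$histogram$frequency), 1)
  expect_equal(hb$histogram$frequency[hb$histogram$n_hbonds == 1L], 0.75)
})

test_that("coordination distances and equilibration check work on series", {
  st <- synth_trajectory(n_atoms = 5, n_frames = 6, amplitude = 0, rigid = FALSE, seed = 2)
  cd <- coordination_distances(st$trajectory, center = 1L, partners = c(2L, 3L))
  expect_identical(nrow(cd), 12L)  # 6 frames x 2 partners
  expect_true(all(cd$distance > 0))
  # distances are invariant across frames of a static trajectory
  expect_equal(length(unique(round(cd$distance, 9))), 2L)

  drifting <- c(seq(8, 1, length.out = 30), rep(1, 30))
  ec <- equilibration_check(drifting, window = 10, tolerance = 0.5)
  expect_true(ec$stable)
  expect_gt(ec$first_stable_index, 15L)
  never <- equilibration_check(seq(0, 50, length.out = 40), window = 10, tolerance = 0.5)
  expect_false(never$stable)
  expect_true(is.na(never$first_stable_index))
  expect_error(equilibration_check(1:5, window = 10), "longer than the series")
})

test_that("PDB writing and reading round-trip a trajectory", {
  st <- synth_trajectory(n_atoms = 7, n_frames = 5, amplitude = 1, seed = 9)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st$trajectory, path)
  back <- read_structure_pdb(path)
  expect_s3_class(back, "pep_trajectory")
  expect_identical(n_frames(back), 5L)
  expect_identical(nrow(back$atoms), 7L)
  expect_lt(max(abs(back$coords - st$trajectory$coords)), 1e-3)  # PDB has 3 decimals
})
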