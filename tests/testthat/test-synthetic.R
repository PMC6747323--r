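test_that("generators are pure functions of their seed and restore RNG state", {
  set.seed(101)
  before <- .Random.seed
  p1 <- random_protein(50, seed = 9)
  expect_identical(.Random.seed, before)  # caller RNG untouched
  p2 <- random_protein(50, seed = 9)
  expect_identical(p1, p2)
  expect_false(identical(p1$sequence, random_protein(50, seed = 10)$sequence))
})

test_that("derive_seed yields distinct, stable substream seeds below 2^31", {
  s <- vapply(1:50, function(k) derive_seed(123, k), integer(1))
  expect_identical(anyDuplicated(s), 0L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(derive_seed(123, 1), derive_seed(123, 1))
})

test_that("random_protein honours length and composition", {
  p <- random_protein(200, composition = c(A = 1, K = 1), seed = 3)
  expect_identical(nchar(p$sequence), 200L)
  expect_identical(sort(unique(strsplit(p$sequence, "")[[1]])), c("A", "K"))
  expect_error(random_protein(10, composition = c(Z = 1), seed = 1))
})

test_that("spike_motifs ground truth is verified against the digestion engine", {
  tryp <- load_enzymes("trypsin")[["trypsin"]]
  base <- random_protein(150, seed = 21)
  spiked <- spike_motifs(base, c(AGGK = 3L, VVK = 2L), tryp, seed = 4)
  expect_identical(nrow(spiked$ground_truth), 5L)
  # every recorded copy is released intact by an actual digest
  res <- digest(spiked$protein, tryp)
  for (k in seq_len(nrow(spiked$ground_truth))) {
    gt <- spiked$ground_truth[k, ]
    hit <- res$peptides$start == gt$start & res$peptides$end == gt$end &
      res$peptides$sequence == gt$sequence
    expect_true(any(hit), label = sprintf("copy %s at %d", gt$sequence, gt$start))
  }
  # relative release frequency of each motif is exactly 1 by construction
  for (m in c("AGGK", "VVK")) {
    expect_equal(relative_frequency_W(res$peptides, m, spiked$protein), 1)
  }
})

test_that("spike_motifs rejects motifs the enzyme cannot release", {
  tryp <- load_enzymes("trypsin")[["trypsin"]]
  base <- random_protein(80, seed = 2)
  expect_error(spike_motifs(base, c(AGGA = 1L), tryp, seed = 1),
               "last residue is not in the enzyme's P1 accept set")
})

test_that("synth_dose_response follows the logistic with optional seeded noise", {
  concs <- 10^seq(-7, -3, by = 1)
  clean <- synth_dose_response(concs, ic50 = 1e-5, hill = 2)
  expect_equal(clean$inhibition, clean$true_inhibition)
  expect_equal(clean$inhibition[concs == 1e-5], 50)
  noisy1 <- synth_dose_response(concs, 1e-5, noise_sd = 2, replicates = 3, seed = 6)
  noisy2 <- synth_dose_response(concs, 1e-5, noise_sd = 2, replicates = 3, seed = 6)
  expect_identical(noisy1, noisy2)
  expect_identical(nrow(noisy1), length(concs) * 3L)
  expect_false(all(noisy1$inhibition == noisy1$true_inhibition))
})

test_that("synth_trajectory records analytic expectations and is reproducible", {
  a <- synth_trajectory(n_atoms = 5, n_frames = 8, amplitude = 2, seed = 13)
  b <- synth_trajectory(n_atoms = 5, n_frames = 8, amplitude = 2, seed = 13)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$expected$amplitude, 2)
  expect_identical(n_frames(a$trajectory), 8L)
})
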