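test_that("digest releases tiling peptides with correct provenance spans", {
  after_k <- enzyme_spec("after_K", rules = "P1=K")
  res <- digest(c(p = "AKAKA"), after_k)
  expect_s3_class(res, "digest_result")
  expect_identical(res$peptides$sequence, c("AK", "AK", "A"))
  expect_identical(res$peptides$start, c(1L, 3L, 5L))
  expect_identical(res$peptides$end, c(2L, 4L, 5L))
  # tiling: concatenation in span order reproduces the parent
  expect_identical(paste(res$peptides$sequence, collapse = ""), "AKAKA")
  expect_identical(res$treatment, "after_K")
})

test_that("simultaneous digestion is the union of per-enzyme sites", {
  e1 <- enzyme_spec("after_K", rules = "P1=K")
  e2 <- enzyme_spec("after_R", rules = "P1=R")
  res <- digest(c(p = "AKARA"), list(e1, e2))
  expect_identical(res$cleaved_bonds$p, c(2L, 4L))
  expect_identical(res$treatment, "after_K+after_R")
})

test_that("exhaustive digestion reaches a re-digestion fixpoint", {
  specs <- load_enzymes(list_enzymes())
  set.seed(77)
  for (rep in 1:25) {
    s <- random_test_sequence(sample(20:60, 1))
    res <- digest(c(x = s), specs[c("papain", "ficin")])
    for (pep in res$peptides$sequence) {
      again <- digest(c(y = pep), specs[c("papain", "ficin")])
      expect_identical(nrow(again$peptides), 1L,
                       label = sprintf("released peptide %s re-digests", pep))
    }
  }
})

test_that("refine = FALSE gives literal single-pass semantics", {
  # an enzyme whose block references P2' can gain sites after truncation:
  # cutting bond 3 of AKKRA exposes fragment AKK, where the P2'=R block
  # no longer applies to bond 2
  e <- enzyme_spec("ctx", rules = "P1=K ; block: P2'=R")
  single <- digest(c(p = "AKKRA"), e, refine = FALSE)
  full <- digest(c(p = "AKKRA"), e, refine = TRUE)
  expect_identical(single$cleaved_bonds$p, 3L)
  expect_identical(full$cleaved_bonds$p, c(2L, 3L))
})

test_that("digestion engine matches the independent fixpoint oracle on random sequences", {
  specs <- load_enzymes(list_enzymes())
  combos <- list("papain", "trypsin", c("papain", "ficin"),
                 c("pepsin_ph1.3", "trypsin", "chymotrypsin_high"))
  set.seed(99)
  for (rep in 1:40) {
    s <- random_test_sequence(sample(10:45, 1))
    for (cmb in combos) {
      got <- sort(digest(c(x = s), specs[cmb])$peptides$sequence)
      want <- sort(oracle_digest_frags(s, specs[cmb]))
      expect_identical(got, want, label = sprintf("%s | %s", paste(cmb, collapse = "+"), s))
    }
  }
})

test_that("sequential digestion maps stage-2 bonds back to parent coordinates", {
  stage1 <- enzyme_spec("after_K", rules = "P1=K")
  stage2 <- enzyme_spec("after_G", rules = "P1=G")
  res <- sequential_digest(c(p = "AGKAGA"), stage1, stage2)
  expect_identical(res$cleaved_bonds$p, c(2L, 3L, 5L))
  expect_identical(paste(res$peptides$sequence, collapse = ""), "AGKAGA")
  expect_identical(res$treatment, "after_K-->after_G")
})

test_that("stage-2 substrate length caps apply to stage-1 products, not the parent", {
  # PREP (cap 30) must act on short stage-1 products of a long parent
  long <- paste(c(rep("A", 20), "K", rep("A", 10), "P", rep("A", 10)), collapse = "")
  expect_gt(nchar(long), 30L)
  res <- sequential_digest(c(p = long), enzyme_spec("after_K", rules = "P1=K"), "prep")
  expect_true(32L %in% res$cleaved_bonds$p)  # PREP cuts after the Pro at position 32
  # PREP alone cannot act on the full-length parent
  expect_identical(digest(c(p = long), "prep")$cleaved_bonds$p, integer(0))
})

test_that("merge_unique pools treatments per distinct sequence", {
  a <- peptide_tbl(c("VF", "AY"), treatment = "papain")
  b <- peptide_tbl(c("VF", "PG"), treatment = "ficin")
  m <- merge_unique(a, b)
  expect_identical(m$sequence, c("AY", "PG", "VF"))
  expect_identical(m$treatments[[which(m$sequence == "VF")]], c("ficin", "papain"))
  expect_identical(m$n_treatments, c(1L, 1L, 2L))
  # also accepts a single list of tables
  expect_identical(merge_unique(list(a, b)), m)
})
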