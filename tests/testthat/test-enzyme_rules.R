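test_that("subsite patterns parse accept sets, negation and blocks", {
  e <- enzyme_spec("demo", rules = "P2=W P1=KR ; block: P1'=P")
  expect_identical(sort(e$rules[[1]]$accept$P1), c("K", "R"))
  expect_identical(e$rules[[1]]$accept$P2, "W")
  expect_identical(e$rules[[1]]$blocks[[1]]$`P1'`, "P")
  neg <- enzyme_spec("neg", rules = "P1=!P")
  expect_false("P" %in% neg$rules[[1]]$accept$P1)
  expect_length(neg$rules[[1]]$accept$P1, 19L)
})

test_that("malformed rules are rejected", {
  expect_error(enzyme_spec("bad", rules = "Q1=K"), "cannot parse subsite token")
  expect_error(enzyme_spec("bad", rules = "P1=KX1"), "unknown residue")
  expect_error(enzyme_spec("bad", rules = "P1=K ; oops: P2=A"), "expected 'block")
  expect_error(enzyme_spec("bad", rules = "P1=K", substrate_max_len = 1L), ">= 2")
})

test_that("a constrained offset outside the sequence fails the match", {
  # trypsin needs P1=K; for "KA" bond 1 has no P2..P4 constraints -> cleaved,
  # but an enzyme requiring P2 cannot act on a bond whose P2 is missing.
  needs_p2 <- enzyme_spec("needs_p2", rules = "P2=A P1=K")
  expect_identical(find_cleavage_sites("KA", needs_p2), integer(0))
  expect_identical(find_cleavage_sites("AKA", needs_p2), 2L)
})

test_that("block patterns only apply when their offsets are present", {
  e <- enzyme_spec("after_k", rules = "P1=K ; block: P2=C")
  expect_identical(find_cleavage_sites("KA", e), 1L)       # P2 missing: block void
  expect_identical(find_cleavage_sites("CKA", e), integer(0))
})

test_that("packaged PREP table reproduces documented examples", {
  prep <- load_enzymes("prep")[["prep"]]
  expect_identical(find_cleavage_sites("GPGPG", prep), c(2L, 4L))
  # P1'=P blocks bond 2, P2=P blocks bond 3
  expect_identical(find_cleavage_sites("NPPK", prep), integer(0))
  # substrate length cap: no action on substrates > 30 residues
  long <- paste(rep("AP", 20), collapse = "")
  expect_identical(find_cleavage_sites(long, prep), integer(0))
  short <- paste(rep("AP", 10), collapse = "")
  expect_gt(length(find_cleavage_sites(short, prep)), 0L)
})

test_that("packaged trypsin table honours Keil exceptions and overrides", {
  tryp <- load_enzymes("trypsin")[["trypsin"]]
  expect_identical(find_cleavage_sites("AKA", tryp), 2L)
  expect_identical(find_cleavage_sites("ARA", tryp), 2L)
  expect_identical(find_cleavage_sites("AKPA", tryp), integer(0)) # P1'=P
  expect_identical(find_cleavage_sites("ACKDA", tryp), integer(0)) # CKD exception
  expect_identical(find_cleavage_sites("AWKPA", tryp), 3L)        # WKP override
  expect_identical(find_cleavage_sites("AMRPA", tryp), 3L)        # MRP override
})

test_that("packaged chymotrypsin table cleaves after F/Y/W with P1' exceptions", {
  chym <- load_enzymes("chymotrypsin_high")[["chymotrypsin_high"]]
  expect_identical(find_cleavage_sites("AFA", chym), 2L)
  expect_identical(find_cleavage_sites("AYA", chym), 2L)
  expect_identical(find_cleavage_sites("AWA", chym), 2L)
  expect_identical(find_cleavage_sites("AFPA", chym), integer(0))
  expect_identical(find_cleavage_sites("AWMA", chym), integer(0)) # W not before M
  expect_identical(find_cleavage_sites("AYMA", chym), 2L)         # Y before M fine
})

test_that("enzyme rule files round-trip through load_enzyme", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# demo table", "name: demo", "ec: 3.4.99.1", "version: demo-v1",
    "substrate_max_len: 10", "rule: P1=K ; block: P1'=P", "global_block: P2=C"
  ), path)
  e <- load_enzyme(path)
  expect_s3_class(e, "enzyme_spec")
  expect_identical(e$name, "demo")
  expect_identical(e$substrate_max_len, 10L)
  expect_identical(find_cleavage_sites("AKA", e), 2L)
  expect_identical(find_cleavage_sites("CKA", e), integer(0))  # global block
  expect_error(load_enzyme(file.path(tempdir(), "missing.txt")), "not found")
})

test_that("list_enzymes exposes the six packaged tables", {
  expect_setequal(
    list_enzymes(),
    c("papain", "ficin", "prep", "pepsin_ph1.3", "trypsin", "chymotrypsin_high")
  )
  specs <- load_enzymes(list_enzymes())
  for (e in specs) expect_false(is.na(e$version))
})

test_that("find_cleavage_sites agrees with the window-scan oracle on random sequences", {
  specs <- load_enzymes(list_enzymes())
  set.seed(421)
  for (rep in 1:120) {
    s <- random_test_sequence(sample(5:35, 1))
    for (e in specs) {
      expect_identical(find_cleavage_sites(s, e), as.integer(oracle_sites(s, e)),
                       label = sprintf("%s on %s", e$name, s))
    }
  }
})
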