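test_that("file predicates demand a verdict for every sequence", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tallergen", "VF\tno", "QQ\tyes"), path)
  pred <- predicate_file(path, "allergen")
  expect_identical(pred(c("VF", "QQ")), c(FALSE, TRUE))
  expect_error(pred("AY"), "no verdict for sequence 'AY'")
  expect_error(predicate_file(file.path(tempdir(), "missing.tsv"), "toxin"), "not found")
  expect_error(predicate_file(path, "toxin"), "columns 'sequence' and 'toxin'")
  flag_all <- predicate_constant("toxin", flagged = TRUE)
  expect_identical(flag_all(c("A", "B")), c(TRUE, TRUE))
})

test_that("GI stage partitions stable/unstable and collects distinct fragments", {
  # VF is GI-stable (its only bond has no complete pepsin window);
  # AAFAA is cleaved by pepsin after F
  res <- gi_stability_stage(c("VF", "AAFAA"))
  expect_identical(res$stable$sequence, "VF")
  expect_identical(res$unstable$sequence, "AAFAA")
  expect_true(all(nchar(res$fragments$sequence) >= 2L))
  expect_identical(res$fragments$gi_parent, rep("AAFAA", nrow(res$fragments)))
  expect_false(anyDuplicated(res$fragments$sequence) > 0)
  # a stable peptide has zero predicted sites under all three GI tables
  gi <- load_enzymes(c("pepsin_ph1.3", "trypsin", "chymotrypsin_high"))
  expect_true(all(vapply(gi, function(e) length(find_cleavage_sites("VF", e)) == 0L,
                         logical(1))))
})

test_that("cascade stage counts conserve: input = pass + fail at every stage", {
  set.seed(12)
  pool <- unique(replicate(40, random_test_sequence(sample(2:6, 1))))
  rep <- run_cascade(pool)
  st <- rep$stages
  expect_identical(st$n_input, st$n_pass + st$n_fail)
  # the pool entering allergenicity is gi-pass + new fragments
  expect_identical(st$n_input[st$stage == "allergenicity"],
                   st$n_pass[st$stage == "gi_stability"] +
                     st$n_new_fragments[st$stage == "gi_stability"])
  expect_identical(nrow(rep$final), st$n_pass[st$stage == "permeability"])
  expect_identical(rep$n_known + rep$n_novel, nrow(rep$final))
})

test_that("flagged sequences are removed by the allergen and toxin stages", {
  pool <- c("VF", "AY", "IR")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence\tallergen", "VF\tyes", "AY\tno", "IR\tno"), path)
  rep <- run_cascade(pool, allergen = predicate_file(path, "allergen"))
  expect_false("VF" %in% rep$final$sequence)
  expect_identical(rep$stages$n_fail[rep$stages$stage == "allergenicity"], 1L)
  rep2 <- run_cascade(pool, toxin = predicate_constant("toxin", flagged = TRUE))
  expect_identical(nrow(rep2$final), 0L)
})

test_that("cascade reports serialise to JSON deterministically", {
  rep <- run_cascade(c("VF", "AY"))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_cascade_report(rep, p1)
  write_cascade_report(rep, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1)
  expect_identical(length(parsed$stages), 4L)
  expect_identical(parsed$n_known, 2L)
})

test_that("gi = FALSE passes the pool through to the downstream stages", {
  rep <- run_cascade(c("AAFAA"), gi = FALSE)
  expect_false("gi_stability" %in% rep$stages$stage)
  expect_identical(rep$stages$n_input[1], 1L)
  expect_identical(rep$final$sequence, "AAFAA")
})
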