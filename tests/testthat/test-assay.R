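test_that("calibration fit recovers a known line and inverts correctly", {
  set.seed(1)
  std <- tibble::tibble(conc = c(1, 2, 4, 8, 16),
                        response = 3 + 2.5 * c(1, 2, 4, 8, 16) + rnorm(5, 0, 1e-6))
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 2.5, tolerance = 1e-5)
  expect_equal(cal$intercept, 3, tolerance = 1e-4)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  expect_equal(predict_concentration(cal, 3 + 2.5 * 5), 5, tolerance = 1e-5)
  expect_s3_class(tidy(cal), "tbl_df")
  expect_identical(glance(cal)$n_points, 5L)
  expect_error(fit_calibration(std[1:2, ]), "at least 3 points")
  expect_error(fit_calibration(tibble::tibble(conc = c(1, 1, 1), response = 1:3)),
               "all equal")
})

test_that("inhibition percentage follows 100*(A-B)/A without clamping", {
  expect_equal(inhibition_percent(2, 1), 50)
  expect_equal(inhibition_percent(2, 0), 100)
  expect_equal(inhibition_percent(2, 3), -50)   # negative, not clamped
  expect_error(inhibition_percent(0, 1), "A > 0")
  expect_error(inhibition_percent(1, -1), "B >= 0")
})

test_that("pic50 is -log10 of the molar IC50", {
  expect_equal(round(pic50(2.63e-5), 2), 4.58)
  expect_equal(pic50(1e-6), 6)
  expect_error(pic50(0), "ic50 > 0")
  expect_error(pic50(-1), "ic50 > 0")
})

test_that("fit_ic50 recovers noiseless parameters exactly", {
  d <- synth_dose_response(10^seq(-7, -3, by = 0.5), ic50 = 1e-5, hill = 1.3)
  f <- fit_ic50(d[, c("conc", "inhibition")])
  expect_equal(f$ic50, 1e-5, tolerance = 1e-6)
  expect_equal(f$hill, 1.3, tolerance = 1e-6)
  expect_equal(f$pic50, 5, tolerance = 1e-6)
  expect_true(f$converged)
  expect_identical(tidy(f)$term, c("ic50", "hill", "pic50"))
  expect_identical(glance(f)$n_points, nrow(d))
  expect_equal(predict(f, 1e-5), 50, tolerance = 1e-5)
})

test_that("fit_ic50 validates its inputs", {
  expect_error(fit_ic50(tibble::tibble(conc = c(1, 2, 3), inhibition = c(10, 50, 90))),
               "at least 4")
  expect_error(fit_ic50(tibble::tibble(conc = c(-1, 1, 2, 3), inhibition = c(5, 20, 60, 90))),
               "positive")
  expect_error(fit_ic50(tibble::tibble(conc = 1:4, inhibition = c(60, 70, 80, 90))),
               "bracket 50")
})

test_that("IC50 recovery holds at 3% noise across 100 seeded replicates", {
  true_ic50 <- 2.63e-5
  concs <- 10^seq(-7, -3, by = 0.4)
  errs <- vapply(1:100, function(s) {
    d <- synth_dose_response(concs, ic50 = true_ic50, hill = 1,
                             noise_sd = 3, replicates = 3L, seed = s)
    f <- fit_ic50(d[, c("conc", "inhibition")])
    abs(log10(f$ic50) - log10(true_ic50))
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("analyze_assay computes inhibition from A/B and fits per peptide", {
  concs <- 10^seq(-7, -3, by = 0.5)
  d1 <- synth_dose_response(concs, ic50 = 1e-5, seed = 1)
  d2 <- synth_dose_response(concs, ic50 = 1e-4, seed = 2)
  m <- rbind(
    data.frame(peptide = "P1", conc = d1$conc, A = 2, B = 2 * (1 - d1$inhibition / 100)),
    data.frame(peptide = "P2", conc = d2$conc, A = 2, B = 2 * (1 - d2$inhibition / 100))
  )
  res <- analyze_assay(m)
  expect_identical(res$peptide, c("P1", "P2"))
  expect_equal(res$ic50, c(1e-5, 1e-4), tolerance = 1e-4)
  expect_s3_class(res$fit[[1]], "ic50_fit")
})

test_that("autoplot methods return ggplot objects", {
  d <- synth_dose_response(10^seq(-7, -3, by = 0.5), ic50 = 1e-5, noise_sd = 1, seed = 4)
  f <- fit_ic50(d[, c("conc", "inhibition")])
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  cal <- fit_calibration(tibble::tibble(conc = 1:4, response = c(2.1, 3.9, 6.2, 8.0)))
  expect_s3_class(ggplot2::autoplot(cal), "ggplot")
  rep <- run_cascade(c("VF", "AY"))
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
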