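## In vitro assay mathematics: hippuric-acid (HA) calibration, inhibition
## percentage, IC50 from dose-response, pIC50.
##
## The inhibition readout is bounded by construction -- 100 * (A - B) / A
## with A the HA concentration of the uninhibited reaction -- so the
## dose-response model is a two-parameter logistic with floor 0 and ceiling
## 100: inhibition(c) = 100 / (1 + (IC50 / c)^h). Fitting is done in
## log10-concentration space (symmetric error structure), initialised from
## log-linear interpolation of the 50% crossing. Replicates are fitted as
## individual points, never pre-averaged.

#' Fit a calibration curve (response vs concentration)
#'
#' Ordinary least squares of `response ~ concentration`.
#'
#' @param standards Data frame with columns `conc` and `response`, or two
#'   numeric vectors.
#' @param response Response vector when `standards` is a numeric vector.
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `n_points` and the underlying `lm` fit.
#'   Supports [tidy()], [glance()] and [predict_concentration()].
#' @export
fit_calibration <- function(standards, response = NULL) {
  if (!is.data.frame(standards)) standards <- tibble(conc = standards, response = response)
  stopifnot(all(c("conc", "response") %in% names(standards)))
  if (nrow(standards) < 3L) abort("calibration requires at least 3 points")
  if (length(unique(standards$conc)) < 2L) abort("calibration concentrations are all equal")
  fit <- lm(response ~ conc, data = standards)
  r2 <- summary(fit)$r.squared
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2, n_points = nrow(standards), fit = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> response = %.6g + %.6g * conc (n = %d, R^2 = %.4f)\n",
              x$intercept, x$slope, x$n_points, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm), estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
    p_value = unname(sm[, 4])
  )
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n_points = x$n_points)
}

#' Inverse prediction from a calibration curve
#'
#' @param curve A `calibration_curve`.
#' @param response Numeric responses to convert to concentrations.
#' @return Numeric concentrations.
#' @export
predict_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (abs(curve$slope) < .Machine$double.eps) abort("calibration slope is zero; cannot invert")
  (response - curve$intercept) / curve$slope
}

#' Inhibition percentage
#'
#' `100 * (A - B) / A`, where `A` is the product concentration of the
#' uninhibited reaction and `B` that in the presence of inhibitor. Values
#' are reported as computed (negative if `B > A`), never clamped.
#'
#' @param A Positive numeric (uninhibited product concentration).
#' @param B Non-negative numeric (inhibited product concentration).
#' @return Percent inhibition.
#' @export
#' @examples
#' inhibition_percent(2, 1) # 50
inhibition_percent <- function(A, B) {
  if (any(A <= 0)) abort("inhibition_percent requires A > 0")
  if (any(B < 0)) abort("inhibition_percent requires B >= 0")
  100 * (A - B) / A
}

#' pIC50 from a molar IC50
#'
#' @param ic50 Positive molar IC50 value(s).
#' @return `-log10(ic50)`.
#' @export
#' @examples
#' pic50(2.63e-5) # 4.58 to 2 d.p.
pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) abort("pic50 requires ic50 > 0")
  -log10(ic50)
}

## 50% crossing by log-linear interpolation; used as the fit initialiser.
interpolate_ic50 <- function(conc, inhibition) {
  o <- order(conc)
  conc <- conc[o]; inhibition <- inhibition[o]
  # collapse replicate concentrations to their mean for the initializer only
  agg <- tapply(inhibition, conc, mean)
  cc <- as.numeric(names(agg)); yy <- as.numeric(agg)
  below <- which(yy < 50); above <- which(yy >= 50)
  if (length(below) == 0L || length(above) == 0L) return(NA_real_)
  i <- max(below[below < max(above)], na.rm = TRUE)
  j <- min(above[above > i])
  lx <- log10(cc[c(i, j)]); ly <- yy[c(i, j)]
  10^(lx[1] + (50 - ly[1]) * diff(lx) / diff(ly))
}

#' Fit an IC50 from dose-response points
#'
#' Least-squares fit of `inhibition = 100 / (1 + (IC50/conc)^h)` with the
#' IC50 parametrised on the log10 scale, via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]).
#'
#' @param points Data frame with columns `conc` (molar) and `inhibition`
#'   (percent), or a numeric concentration vector.
#' @param inhibition Inhibition vector when `points` is numeric.
#' @return An `ic50_fit` with fields `ic50`, `hill`, `pic50`, `converged`,
#'   `residual_sd`, `n_points`, the `nls` fit, and a per-concentration
#'   summary tibble. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_ic50 <- function(points, inhibition = NULL) {
  if (!is.data.frame(points)) points <- tibble(conc = points, inhibition = inhibition)
  stopifnot(all(c("conc", "inhibition") %in% names(points)))
  if (nrow(points) < 4L) abort("IC50 fitting requires at least 4 dose-response points")
  if (any(points$conc <= 0)) abort("concentrations must be positive")
  if (!any(points$inhibition < 50) || !any(points$inhibition > 50)) {
    abort(paste(
      "dose-response points do not bracket 50% inhibition;",
      "extend the concentration range below and above the IC50"
    ))
  }
  init_ic50 <- interpolate_ic50(points$conc, points$inhibition)
  if (!is.finite(init_ic50)) init_ic50 <- exp(mean(log(points$conc)))
  fit <- minpack.lm::nlsLM(
    inhibition ~ 100 / (1 + 10^(h * (log_ic50 - log10(conc)))),
    data = points,
    start = list(log_ic50 = log10(init_ic50), h = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  ic50 <- 10^unname(est["log_ic50"])
  summary_tbl <- points |>
    group_by(.data$conc) |>
    summarise(mean_inhibition = mean(.data$inhibition),
              sd_inhibition = if (dplyr::n() > 1) sd(.data$inhibition) else NA_real_,
              n = dplyr::n(), .groups = "drop")
  structure(
    list(
      ic50 = ic50, hill = unname(est["h"]), pic50 = -log10(ic50),
      converged = fit$convInfo$isConv %||% TRUE,
      residual_sd = sqrt(mean(residuals(fit)^2)),
      n_points = nrow(points),
      fit = fit, data = as_tibble(points), by_concentration = summary_tbl
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf(
    "<ic50_fit> IC50 = %.4g M (pIC50 = %.2f), Hill slope = %.3f, n = %d, residual sd = %.3g%s\n",
    x$ic50, x$pic50, x$hill, x$n_points, x$residual_sd,
    if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ic50_fit <- function(x, ...) {
  tibble(
    term = c("ic50", "hill", "pic50"),
    estimate = c(x$ic50, x$hill, x$pic50)
  )
}

#' @exportS3Method generics::glance
glance.ic50_fit <- function(x, ...) {
  tibble(
    ic50 = x$ic50, pic50 = x$pic50, hill = x$hill,
    residual_sd = x$residual_sd, n_points = x$n_points,
    converged = isTRUE(x$converged)
  )
}

#' Predicted inhibition from an `ic50_fit`
#'
#' @param object An `ic50_fit`.
#' @param conc Concentrations (molar) at which to evaluate the curve.
#' @param ... Unused.
#' @return Predicted inhibition percentages.
#' @export
predict.ic50_fit <- function(object, conc, ...) {
  100 / (1 + (object$ic50 / conc)^object$hill)
}

#' Analyse an inhibition-assay measurement table
#'
#' Takes raw `A`/`B` product concentrations (or a precomputed `inhibition`
#' column), computes inhibition per row, and fits one IC50 per peptide.
#'
#' @param measurements Data frame with columns `peptide`, `conc` and either
#'   `A`,`B` or `inhibition`.
#' @return A tibble with one row per peptide: `peptide`, `ic50`, `pic50`,
#'   `hill`, `converged`, `residual_sd`, `n_points` and a list-column `fit`.
#' @export
analyze_assay <- function(measurements) {
  stopifnot(is.data.frame(measurements), all(c("peptide", "conc") %in% names(measurements)))
  if (!"inhibition" %in% names(measurements)) {
    stopifnot(all(c("A", "B") %in% names(measurements)))
    measurements$inhibition <- inhibition_percent(measurements$A, measurements$B)
  }
  measurements |>
    group_by(.data$peptide) |>
    group_modify(function(df, key) {
      f <- fit_ic50(df[, c("conc", "inhibition")])
      tibble(ic50 = f$ic50, pic50 = f$pic50, hill = f$hill,
             converged = isTRUE(f$converged), residual_sd = f$residual_sd,
             n_points = f$n_points, fit = list(f))
    }) |>
    ungroup()
}
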