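# ---------------------------------------------------------------------------
# Chou-Talalay median-effect analysis.  The median-effect equation
#   fa / (1 - fa) = (D / Dm)^m
# linearises to  log10(fa/(1-fa)) = m (log10 D - log10 Dm),  so a straight-
# line fit of log10(fa/fu) on log10 D yields the sigmoidicity m and the
# median-effect dose Dm (the IC50 when fa is 1 - relative viability).
# Combination index at effect level fa:  CI = d1/Dx1(fa) + d2/Dx2(fa),
# with Dx the single-agent dose producing fa.
# ---------------------------------------------------------------------------

#' Fit the median-effect model to a dose-response curve
#'
#' Least-squares line through `(log10 D, log10(fa/(1-fa)))`.  Fractions
#' affected exactly 0 or 1 (possible in viability assays) are clamped to
#' `[clamp_delta, 1 - clamp_delta]` with a warning, or rejected when
#' `strict = TRUE`.
#'
#' @param formula,data Model-formula interface, `fa ~ dose`, with `data` a
#'   data frame; alternatively call `median_effect(dose = , fa = )`.
#' @param dose,fa Numeric vectors (used when no formula is given): positive
#'   doses and fractions affected in (0, 1).
#' @param clamp_delta Boundary clamp for fa (default `1e-4`).
#' @param strict Reject boundary fa instead of clamping (default `FALSE`).
#' @return An object of class `median_effect` with components `m` (slope),
#'   `dm` (median-effect dose, dose units), `r` (correlation coefficient of
#'   the linearised points), `fit` (the underlying `lm`), and the data.
#' @examples
#' d <- c(2.5, 5, 10, 20, 40)
#' fa <- (d / 10)^2 / (1 + (d / 10)^2)
#' fit <- median_effect(dose = d, fa = fa)
#' coef(fit)   # m = 2, dm = 10
#' ic50(fit)   # 10
#' @export
median_effect <- function(formula = NULL, data = NULL, dose = NULL,
                          fa = NULL, clamp_delta = 1e-4, strict = FALSE) {
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    fa <- mf[[1]]
    dose <- mf[[2]]
  }
  if (is.null(dose) || is.null(fa)) stop("supply a formula or dose and fa")
  stopifnot(length(dose) == length(fa))
  if (length(dose) < 3) stop("need at least 3 dose-response points")
  if (length(unique(dose)) < 2) stop("need at least 2 distinct doses")
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(fa < 0 | fa > 1)) stop("fraction affected must lie in [0, 1]")
  at_bound <- fa <= 0 | fa >= 1
  if (any(at_bound)) {
    if (strict) {
      stop(sum(at_bound), " fraction(s) affected exactly 0 or 1; the ",
           "median-effect linearisation is undefined at the boundary")
    }
    warning(sum(at_bound), " fraction(s) affected clamped to [",
            clamp_delta, ", ", 1 - clamp_delta, "]")
    fa <- pmin(pmax(fa, clamp_delta), 1 - clamp_delta)
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  if (!is.finite(m) || m <= 0) {
    warning("non-positive median-effect slope; curve is not monotone ",
            "increasing in dose")
  }
  dm <- 10^(-unname(coef(fit)[1]) / m)
  r <- unname(cor(x, y))
  structure(list(m = m, dm = dm, r = r, fit = fit,
                 data = data.frame(dose = dose, fa = fa),
                 clamped = sum(at_bound)),
            class = "median_effect")
}

#' @export
print.median_effect <- function(x, digits = 4, ...) {
  cat("Median-effect fit: fa/(1-fa) = (D/Dm)^m\n")
  cat(sprintf("  m  = %s (sigmoidicity)\n  Dm = %s (median-effect dose, IC50)\n  r  = %s (linearised fit)\n",
              format(x$m, digits = digits), format(x$dm, digits = digits),
              format(x$r, digits = digits)))
  invisible(x)
}

#' @method summary median_effect
#' @export
summary.median_effect <- function(object, ...) {
  out <- list(m = object$m, dm = object$dm, r = object$r,
              n = nrow(object$data), clamped = object$clamped,
              lm_summary = summary(object$fit))
  class(out) <- "summary.median_effect"
  out
}

#' @export
print.summary.median_effect <- function(x, ...) {
  cat(sprintf("Median-effect fit on %d points (%d clamped)\n", x$n,
              x$clamped))
  cat(sprintf("  m = %.6g   Dm = %.6g   r = %.6g\n", x$m, x$dm, x$r))
  invisible(x)
}

#' @method coef median_effect
#' @export
coef.median_effect <- function(object, ...) {
  c(m = object$m, dm = object$dm)
}

#' Predicted fraction affected at new doses
#'
#' @param object A `median_effect` fit.
#' @param newdata Optional data frame with a `dose` column (or a numeric
#'   vector via `dose`); defaults to the fitted doses.
#' @param dose Numeric vector alternative to `newdata`.
#' @param ... Unused.
#' @return Numeric vector of fractions affected.
#' @method predict median_effect
#' @export
predict.median_effect <- function(object, newdata = NULL, dose = NULL, ...) {
  if (is.null(dose)) {
    dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  }
  fa_at_dose(object, dose)
}

#' @method residuals median_effect
#' @export
residuals.median_effect <- function(object, ...) {
  residuals(object$fit)
}

#' Median-effect plot
#'
#' Plots the linearised points `log10(fa/fu)` versus `log10 D` with the
#' fitted line; the x-intercept is `log10 Dm`.
#'
#' @param x A `median_effect` fit.
#' @param ... Passed to [plot()].
#' @method plot median_effect
#' @export
plot.median_effect <- function(x, ...) {
  lx <- log10(x$data$dose)
  ly <- log10(x$data$fa / (1 - x$data$fa))
  plot(lx, ly, xlab = "log10 dose", ylab = "log10(fa / fu)",
       main = sprintf("Median-effect plot (m = %.3g, Dm = %.3g, r = %.3g)",
                      x$m, x$dm, x$r), ...)
  graphics::abline(x$fit)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Dose producing a given effect level
#'
#' Inverts the fitted median-effect equation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit A `median_effect` fit.
#' @param fa Effect level(s) in (0, 1).
#' @return Dose(s) in the fitted units.
#' @examples
#' # dose_for_effect(fit, 0.5) == coef(fit)["dm"]
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect"))
  if (any(fa <= 0 | fa >= 1)) stop("effect level must lie strictly in (0, 1)")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Fraction affected at a dose
#'
#' @param fit A `median_effect` fit.
#' @param dose Dose(s), `>= 0`.
#' @return Fraction(s) affected under the fitted model.
#' @export
fa_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "median_effect"))
  if (any(dose < 0)) stop("doses must be non-negative")
  ratio <- (dose / fit$dm)^fit$m
  ratio / (1 + ratio)
}

#' IC50 of a fitted dose-response
#'
#' The dose producing half-maximal effect; identically the median-effect
#' dose `Dm`.
#'
#' @param fit A `median_effect` fit.
#' @return The IC50 in the fitted dose units.
#' @export
ic50 <- function(fit) {
  dose_for_effect(fit, 0.5)
}

#' Combination index for a drug-pair measurement
#'
#' Chou-Talalay CI at the combination's observed effect level:
#' `CI = d1 / Dx1(fa) + d2 / Dx2(fa)`.  CI < 1 indicates synergism, 1
#' additivity, > 1 antagonism.
#'
#' @param d1,d2 Doses of drug 1 and drug 2 in the combination (not both 0);
#'   vectorised.
#' @param fa Observed fraction affected of the combination, in (0, 1).
#' @param fit1,fit2 Single-agent `median_effect` fits (units matching `d1`,
#'   `d2`).
#' @return Numeric CI value(s).
#' @examples
#' # a single agent at its own Dx is additive with itself: CI = 1
#' @export
combination_index <- function(d1, d2, fa, fit1, fit2) {
  stopifnot(length(d1) == length(d2), length(d1) == length(fa))
  if (any(d1 < 0 | d2 < 0)) stop("doses must be non-negative")
  if (any(d1 == 0 & d2 == 0)) stop("at least one drug dose must be positive")
  unname(d1 / dose_for_effect(fit1, fa) + d2 / dose_for_effect(fit2, fa))
}

#' Combination-index table for measured combinations
#'
#' @param combos Data frame with columns `d1`, `d2`, `fa`.
#' @param fit1,fit2 Single-agent fits.
#' @param epsilon Additivity tolerance passed to [classify_ci()].
#' @return The input with `ci` and `interaction` columns appended.
#' @export
ci_table <- function(combos, fit1, fit2, epsilon = 0.05) {
  stopifnot(all(c("d1", "d2", "fa") %in% names(combos)))
  combos$ci <- combination_index(combos$d1, combos$d2, combos$fa, fit1, fit2)
  combos$interaction <- classify_ci(combos$ci, epsilon)
  combos
}

#' Classify a combination index
#'
#' CI below `1 - epsilon` is synergism, within `1 ± epsilon` additive,
#' above `1 + epsilon` antagonism.  `epsilon = 0` degenerates to the strict
#' trichotomy (CI < 1 / = 1 / > 1).
#'
#' @param ci Positive CI value(s).
#' @param epsilon Additivity tolerance (default 0.05).
#' @return Character vector: `"synergism"`, `"additive"` or
#'   `"antagonism"`.
#' @examples
#' classify_ci(c(0.6, 1, 1.3))
#' @export
classify_ci <- function(ci, epsilon = 0.05) {
  if (any(ci <= 0)) stop("CI must be positive")
  stopifnot(epsilon >= 0)
  ifelse(ci < 1 - epsilon, "synergism",
         ifelse(ci > 1 + epsilon, "antagonism", "additive"))
}

#' Isobologram axis intercepts at an effect level
#'
#' The additivity line at effect level `fa` joins `(Dx1(fa), 0)` and
#' `(0, Dx2(fa))`; a measured combination below the line has CI < 1.
#'
#' @param fit1,fit2 Single-agent fits.
#' @param fa Effect level in (0, 1) (default 0.5, the IC50 isobole).
#' @return Named numeric vector `c(dx1 = , dx2 = )`.
#' @export
isobologram_points <- function(fit1, fit2, fa = 0.5) {
  c(dx1 = dose_for_effect(fit1, fa), dx2 = dose_for_effect(fit2, fa))
}
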