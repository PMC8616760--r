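# Median-effect fitting, dose inversion, combination index and its
# classification.

exact_curve <- function(m, dm, doses) {
  (doses / dm)^m / (1 + (doses / dm)^m)
}

test_that("noiseless curves are recovered to numerical precision", {
  d <- c(2.5, 5, 10, 20, 40)
  fit <- median_effect(dose = d, fa = exact_curve(2, 10, d))
  expect_equal(unname(coef(fit)["m"]), 2, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["dm"]), 10, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # fa at the median-effect dose is 0.5 by definition
  expect_equal(fa_at_dose(fit, coef(fit)["dm"]), c(dm = 0.5))
  expect_equal(ic50(fit), 10, tolerance = 1e-9)
})

test_that("the formula interface matches the default interface", {
  d <- c(1, 3, 9, 27)
  df <- data.frame(conc = d, affected = exact_curve(1.4, 4, d))
  f1 <- median_effect(affected ~ conc, df)
  f2 <- median_effect(dose = df$conc, fa = df$affected)
  expect_equal(coef(f1), coef(f2))
  expect_equal(predict(f1, data.frame(dose = c(2, 4))),
               c(exact_curve(1.4, 4, 2), 0.5), tolerance = 1e-9)
})

test_that("boundary fractions are clamped with a warning, rejected in strict mode", {
  d <- c(1, 2, 4, 8)
  fa <- c(0, 0.4, 0.8, 1)
  expect_warning(fit <- median_effect(dose = d, fa = fa), "clamped")
  expect_true(all(fit$data$fa > 0 & fit$data$fa < 1))
  expect_error(median_effect(dose = d, fa = fa, strict = TRUE), "boundary")
  expect_error(median_effect(dose = c(1, 1, 1), fa = c(0.2, 0.3, 0.4)),
               "distinct")
})

test_that("dose_for_effect inverts the fitted curve", {
  fit <- median_effect(dose = c(2.5, 5, 10, 20, 40),
                       fa = exact_curve(1.7, 8, c(2.5, 5, 10, 20, 40)))
  expect_equal(dose_for_effect(fit, 0.5), fit$dm)
  for (x in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(fa_at_dose(fit, dose_for_effect(fit, x)), x,
                 tolerance = 1e-12)
  }
  expect_error(dose_for_effect(fit, 1), "\\(0, 1\\)")
})

test_that("stochastic curves recover dm with small median relative error", {
  doses <- c(1.25, 2.5, 5, 10, 20, 40, 80)
  err <- vapply(1:200, function(i) {
    dr <- generate_dose_response(2, 10, doses, logit_noise_sd = 0.1,
                                 seed = 9000 + i)
    fit <- median_effect(dose = dr$dose, fa = dr$fa)
    abs(fit$dm - 10) / 10
  }, numeric(1))
  expect_lt(median(err), 0.10)
})

test_that("single-agent self-consistency gives CI = 1", {
  fit1 <- median_effect(dose = c(2.5, 5, 10, 20, 40),
                        fa = exact_curve(2, 10, c(2.5, 5, 10, 20, 40)))
  fit2 <- median_effect(dose = c(1, 2, 4, 8),
                        fa = exact_curve(1.3, 3, c(1, 2, 4, 8)))
  fa <- 0.37
  expect_equal(combination_index(dose_for_effect(fit1, fa), 0, fa,
                                 fit1, fit2), 1, tolerance = 1e-9)
  expect_equal(combination_index(0, dose_for_effect(fit2, fa), fa,
                                 fit1, fit2), 1, tolerance = 1e-9)
  expect_error(combination_index(0, 0, 0.5, fit1, fit2), "positive")
})

test_that("identical drugs pooled behave additively: CI = 1 at every fa", {
  d <- c(2.5, 5, 10, 20, 40)
  fit <- median_effect(dose = d, fa = exact_curve(2, 10, d))
  for (fa in seq(0.1, 0.9, by = 0.1)) {
    dx <- dose_for_effect(fit, fa)
    # the pooled dose dx split across the two identical agents
    expect_equal(combination_index(0.3 * dx, 0.7 * dx, fa, fit, fit), 1,
                 tolerance = 1e-9)
  }
})

test_that("a constructed Loewe-additive pair is additive everywhere", {
  d1 <- c(2.5, 5, 10, 20, 40)
  d2 <- c(0.5, 1, 2, 4, 8)
  fit1 <- median_effect(dose = d1, fa = exact_curve(1.6, 12, d1))
  fit2 <- median_effect(dose = d2, fa = exact_curve(2.2, 2, d2))
  combos <- generate_additive_combos(fit1, fit2,
                                     fa_levels = seq(0.05, 0.95, by = 0.05),
                                     lambda = 0.4)
  tab <- ci_table(combos, fit1, fit2)
  expect_equal(tab$ci, rep(1, nrow(tab)), tolerance = 1e-9)
  expect_true(all(tab$interaction == "additive"))
})

test_that("CI is invariant under dose-unit rescaling", {
  d1 <- c(2.5, 5, 10, 20, 40)
  d2 <- c(0.5, 1, 2, 4, 8)
  fit1 <- median_effect(dose = d1, fa = exact_curve(1.6, 12, d1))
  fit2 <- median_effect(dose = d2, fa = exact_curve(2.2, 2, d2))
  ci <- combination_index(6, 1.5, 0.62, fit1, fit2)
  # express drug 1 in a 1000x smaller unit everywhere
  fit1s <- median_effect(dose = d1 * 1000, fa = exact_curve(1.6, 12, d1))
  expect_equal(combination_index(6000, 1.5, 0.62, fit1s, fit2), ci,
               tolerance = 1e-9)
})

test_that("classification follows the CI trichotomy with tolerance band", {
  expect_equal(classify_ci(c(0.6, 1.0, 1.3)),
               c("synergism", "additive", "antagonism"))
  expect_equal(classify_ci(0.96), "additive")
  expect_equal(classify_ci(0.96, epsilon = 0), "synergism")
  expect_equal(classify_ci(1 + 1e-12, epsilon = 0), "antagonism")
  expect_error(classify_ci(-1), "positive")
})

test_that("isobologram intercepts are the single-agent equi-effect doses", {
  d <- c(2.5, 5, 10, 20, 40)
  fit1 <- median_effect(dose = d, fa = exact_curve(2, 10, d))
  fit2 <- median_effect(dose = d, fa = exact_curve(1.5, 20, d))
  pts <- isobologram_points(fit1, fit2, 0.5)
  expect_equal(unname(pts), c(10, 20), tolerance = 1e-9)
  # a point on the additivity line has CI 1; at half-scale CI 0.5
  fa <- 0.7
  pts <- isobologram_points(fit1, fit2, fa)
  lam <- 0.35
  on_line <- c(lam * pts["dx1"], (1 - lam) * pts["dx2"])
  expect_equal(combination_index(on_line[1], on_line[2], fa, fit1, fit2),
               1, tolerance = 1e-9)
  expect_equal(combination_index(on_line[1] / 2, on_line[2] / 2, fa,
                                 fit1, fit2), 0.5, tolerance = 1e-9)
})
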