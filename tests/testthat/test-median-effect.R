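test_that("noiseless series are recovered exactly across the parameter grid", {
  for (Dm in c(0.1, 1, 10)) {
    for (m in c(0.5, 1, 2, 4)) {
      s <- simulate_dose_response(median_effect_params(Dm, m),
                                  Dm * 2^seq(-2, 2, by = 0.5))
      fit <- fit_median_effect(s)
      expect_equal(fit$Dm, Dm, tolerance = 1e-10)
      expect_equal(fit$m, m, tolerance = 1e-10)
      expect_equal(fit$r, 1, tolerance = 1e-12)
    }
  }
})

test_that("saturated points are filtered out and counted", {
  dose <- c(0.001, 0.5, 1, 2, 4, 8, 10000)
  fa <- 1 / (1 + (2 / dose)^1.5)
  fa[1] <- 0
  fa[7] <- 1
  fit <- fit_median_effect(dose = dose, fa = fa)
  expect_identical(fit$n_used, 5L)
  expect_identical(fit$n_excluded, 2L)
  expect_equal(fit$Dm, 2, tolerance = 1e-10)
})

test_that("degenerate series raise classed fitting errors", {
  expect_error(fit_median_effect(dose = c(1, 2), fa = c(0.3, 0.6)),
               class = "fit_impossible")
  expect_error(fit_median_effect(dose = c(1, 2, 4, 8), fa = c(0.999, 0.998, 0.3, 0.5)),
               class = "fit_impossible")  # saturated points excluded, 2 usable left
  expect_error(fit_median_effect(dose = c(1, 2, 4, 8), fa = c(0.8, 0.6, 0.4, 0.2)),
               class = "model_violation")
  expect_error(fit_median_effect(dose = c(-1, 2, 4), fa = c(0.2, 0.4, 0.6)),
               class = "invalid_dose")
})

test_that("noisy fits agree with the brute-force least-squares oracle", {
  set.seed(77)
  for (i in 1:20) {
    Dm <- 10^runif(1, -1, 1)
    m <- runif(1, 0.5, 3)
    s <- simulate_dose_response(median_effect_params(Dm, m),
                                Dm * 2^seq(-3, 3), noise_sd = 0.03, seed = i)
    fit <- tryCatch(fit_median_effect(s), error = function(e) NULL)
    if (is.null(fit)) next  # noise produced a degenerate series
    orc <- oracle_median_effect(s$dose, s$fa)
    expect_equal(me_sse(fit$Dm, fit$m, s$dose, s$fa), orc$sse, tolerance = 1e-6)
  }
})

test_that("dose_for_fa inverts the model", {
  expect_equal(dose_for_fa(list(Dm = 7, m = 0.8), 0.5), 7)
  expect_equal(dose_for_fa(list(Dm = 2, m = 1), 0.8), 8)
  expect_equal(dose_for_fa(list(Dm = 1, m = 2), 0.9), 3)
  expect_error(dose_for_fa(list(Dm = 2, m = 1), 1), class = "invalid_effect_level")
  expect_error(dose_for_fa(list(Dm = 2, m = 1), 0), class = "invalid_effect_level")
  # strictly increasing in fa
  fit <- list(Dm = 3, m = 1.7)
  fas <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(dose_for_fa(fit, fas)) > 0))
})

test_that("sham self-combinations give CI = 1 at every effect level and ratio", {
  s <- simulate_dose_response(median_effect_params(2, 1.5), 2 * 2^seq(-3, 3))
  f <- fit_median_effect(s)
  for (p in c(0.2, 0.5, 0.8)) {
    ci <- combination_index(f, f, f, ratio = c(p, 1 - p),
                            fa_levels = c(0.25, 0.5, 0.75))
    expect_equal(ci$CI, rep(1, 3), tolerance = 1e-10)
    expect_true(all(ci$classification == "additivity"))
  }
})

test_that("a potency-shifted self-combination yields CI equal to the shift", {
  p <- median_effect_params(2, 1.5)
  sim <- simulate_combo_matrix(p, p, potency_shift = 0.5)
  ci <- combination_index(fit_median_effect(sim$drug_a),
                          fit_median_effect(sim$drug_b),
                          fit_median_effect(sim$combo),
                          fa_levels = c(0.25, 0.5, 0.75))
  expect_equal(ci$CI, rep(0.5, 3), tolerance = 1e-9)
  expect_true(all(ci$classification == "synergism"))
})

test_that("an unequal-potency Loewe-additive combination gives CI = 1 against the bisection oracle", {
  pa <- median_effect_params(2, 1.5)
  pb <- median_effect_params(8, 1.5)
  sim <- simulate_combo_matrix(pa, pb, ratio = c(0.5, 0.5), potency_shift = 1)
  fa_levels <- c(0.25, 0.5, 0.75)
  ci <- combination_index(fit_median_effect(sim$drug_a),
                          fit_median_effect(sim$drug_b),
                          fit_median_effect(sim$combo), fa_levels = fa_levels)
  expect_equal(ci$CI, rep(1, 3), tolerance = 1e-6)
  # the combination's total dose matches the oracle's Loewe-additive dose
  for (i in seq_along(fa_levels)) {
    expect_equal(ci$D_total[i],
                 oracle_loewe_dose(pa, pb, c(0.5, 0.5), fa_levels[i]),
                 tolerance = 1e-6)
  }
})

test_that("CI falls strictly as the combination gets more potent", {
  p <- median_effect_params(2, 1.5)
  f <- fit_median_effect(simulate_dose_response(p, 2 * 2^seq(-3, 3)))
  ci_at <- function(s) {
    sim <- simulate_combo_matrix(p, p, potency_shift = s)
    combination_index(f, f, fit_median_effect(sim$combo), fa_levels = 0.5)$CI
  }
  cis <- vapply(c(0.25, 0.5, 1, 2), ci_at, numeric(1))
  expect_true(all(diff(cis) > 0))
  expect_equal(cis, c(0.25, 0.5, 1, 2), tolerance = 1e-9)
})

test_that("IC50, fold shift and resistance factor follow their definitions", {
  f <- fit_median_effect(simulate_dose_response(median_effect_params(0.7, 3),
                                                0.7 * 2^seq(-2, 2)))
  expect_equal(ic50(f), 0.7, tolerance = 1e-10)
  expect_equal(ic50(f), dose_for_fa(f, 0.5), tolerance = 1e-12)
  expect_equal(ic50_fold_shift(list(Dm = 10), list(Dm = 2)), 5)
  expect_equal(ic50_fold_shift(f, f), 1)
  rf <- resistance_factor(list(Dm = 50), list(Dm = 5))
  expect_equal(rf$ratio, 10)
  expect_true(rf$is_resistant)  # threshold is inclusive
  expect_false(resistance_factor(list(Dm = 9.99), list(Dm = 1))$is_resistant)
})

test_that("sensitization halving the IC50 is recovered within 10% under noise", {
  ratios <- vapply(1:50, function(s) {
    alone <- simulate_dose_response(median_effect_params(4, 1.5),
                                    4 * 2^seq(-3, 3), noise_sd = 0.02, seed = s)
    with_sens <- simulate_dose_response(median_effect_params(2, 1.5),
                                        2 * 2^seq(-3, 3), noise_sd = 0.02,
                                        seed = s + 1000)
    ic50_fold_shift(fit_median_effect(alone), fit_median_effect(with_sens))
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})
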