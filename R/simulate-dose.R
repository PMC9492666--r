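#' Median-effect model parameters
#'
#' Parameters of the mass-action median-effect dose-response model
#' `fa/fu = (D/Dm)^m` with `fu = 1 - fa`: at dose `Dm` the fraction affected
#' is exactly 0.5, and `m` controls the sigmoidicity of the curve.
#'
#' @param Dm median-effect dose (concentration units, > 0); the model's IC50.
#' @param m sigmoidicity slope (> 0).
#' @return an object of class `median_effect_params`.
#' @export
median_effect_params <- function(Dm, m) {
  check_number(Dm, "Dm", lower = 0, strict_lower = TRUE)
  check_number(m, "m", lower = 0, strict_lower = TRUE)
  structure(list(Dm = Dm, m = m), class = "median_effect_params")
}

#' @export
print.median_effect_params <- function(x, ...) {
  cat(sprintf("<median_effect_params> Dm = %g, m = %g\n", x$Dm, x$m))
  invisible(x)
}

# noiseless median-effect fraction affected
median_effect_fa <- function(D, Dm, m) 1 / (1 + (Dm / D)^m)

#' Simulate a dose-response series from the median-effect model
#'
#' Fraction affected at dose `D` is `1 / (1 + (Dm/D)^m)`, plus optional
#' additive Gaussian noise clipped to `[0, 1]`. With `noise_sd = 0` the
#' emitted values equal the model values exactly.
#'
#' @param params a [median_effect_params()].
#' @param doses strictly positive concentrations.
#' @param noise_sd standard deviation of additive noise on the fa scale.
#' @param seed optional integer seed (required when `noise_sd > 0`).
#' @param drug_id label carried in the output series.
#' @return a tibble with columns `drug_id`, `dose`, `fa`.
#' @examples
#' simulate_dose_response(median_effect_params(Dm = 2, m = 1), doses = c(0.5, 2, 8))
#' @export
simulate_dose_response <- function(params, doses, noise_sd = 0, seed = NULL,
                                   drug_id = "drug") {
  stopifnot(inherits(params, "median_effect_params"))
  if (!is.numeric(doses) || length(doses) == 0 || any(!is.finite(doses)) ||
      any(doses <= 0)) {
    ss_stop("invalid_dose", "all doses must be strictly positive (log-domain model)")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  fa <- median_effect_fa(doses, params$Dm, params$m)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(check_count(seed, "seed", min = 0L))
    fa <- pmin(1, pmax(0, fa + stats::rnorm(length(doses), 0, noise_sd)))
  }
  tibble::tibble(drug_id = drug_id, dose = as.numeric(doses), fa = fa)
}

# geometric dose ladder (factor 2) centered on Dm
dose_ladder <- function(Dm, n) Dm * 2^(seq_len(n) - (n + 1) / 2)

#' Simulate a constant-ratio two-drug combination experiment
#'
#' Generates single-agent series for two drugs plus a combination series in
#' which the mixture, dosed at a fixed ratio and treated as one agent on
#' total dose, itself follows the median-effect model. The combination's
#' median-effect dose is `potency_shift * Dm_ref`, where `Dm_ref` is the
#' Loewe-additive reference total dose for the chosen ratio,
#' `1 / (p/Dm_a + q/Dm_b)`. When the two components share a slope the
#' Loewe-additive combination is exactly median-effect at every effect
#' level; `potency_shift = 1` therefore yields Combination Index 1, and
#' `potency_shift = s` yields CI = s (s < 1 encodes synergy). The combination
#' slope is the ratio-weighted mean of the component slopes.
#'
#' @param params_a,params_b [median_effect_params()] of the two components.
#' @param ratio length-2 positive dose fractions summing to 1 (component a,
#'   component b share of the total dose).
#' @param potency_shift multiplicative shift `s > 0` of the combination's
#'   median-effect dose relative to the Loewe-additive reference.
#' @param n_doses number of dose levels per series (geometric ladder, factor
#'   2, centered on each series' Dm).
#' @param noise_sd additive fa-scale noise (0 for exact model values).
#' @param seed optional integer seed used when `noise_sd > 0`.
#' @return a list with tibbles `drug_a`, `drug_b`, `combo` and a `truth`
#'   list recording `Dm_ref`, `Dm_combo`, `m_combo` and `potency_shift`.
#' @examples
#' p <- median_effect_params(2, 1.5)
#' sim <- simulate_combo_matrix(p, p, potency_shift = 0.5)
#' sim$truth$Dm_combo  # half the sham-combination reference
#' @export
simulate_combo_matrix <- function(params_a, params_b, ratio = c(0.5, 0.5),
                                  potency_shift = 1, n_doses = 9,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params_a, "median_effect_params"),
            inherits(params_b, "median_effect_params"))
  if (length(ratio) != 2 || any(ratio <= 0) || abs(sum(ratio) - 1) > 1e-12) {
    ss_stop("invalid_argument", "ratio must be two positive fractions summing to 1")
  }
  check_number(potency_shift, "potency_shift", lower = 0, strict_lower = TRUE)
  n_doses <- check_count(n_doses, "n_doses", min = 3L)

  Dm_ref <- 1 / (ratio[1] / params_a$Dm + ratio[2] / params_b$Dm)
  Dm_combo <- potency_shift * Dm_ref
  m_combo <- ratio[1] * params_a$m + ratio[2] * params_b$m

  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  list(
    drug_a = simulate_dose_response(params_a, dose_ladder(params_a$Dm, n_doses),
                                    noise_sd, seeds[[1]], drug_id = "drug_a"),
    drug_b = simulate_dose_response(params_b, dose_ladder(params_b$Dm, n_doses),
                                    noise_sd, seeds[[2]], drug_id = "drug_b"),
    combo = simulate_dose_response(median_effect_params(Dm_combo, m_combo),
                                   dose_ladder(Dm_combo, n_doses),
                                   noise_sd, seeds[[3]], drug_id = "combo"),
    truth = list(Dm_ref = Dm_ref, Dm_combo = Dm_combo, m_combo = m_combo,
                 potency_shift = potency_shift, ratio = as.numeric(ratio))
  )
}
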