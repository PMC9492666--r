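#' Fit the median-effect model to a dose-response series
#'
#' The mass-action median-effect model `fa/fu = (D/Dm)^m` (`fu = 1 - fa`)
#' linearizes to `log10(fa/(1-fa)) = m * log10(D) - m * log10(Dm)`. The fit
#' is unweighted ordinary least squares on that median-effect plot — the
#' method's canonical linearization, chosen over nonlinear refinement so
#' results are exactly reproducible. Points with fa outside the open
#' interval `fa_bounds` are excluded (fa of 0 or 1 has no log-odds) and
#' counted in `n_excluded`.
#'
#' @param series tibble with columns `dose` and `fa` (e.g. from
#'   [simulate_dose_response()]), or `NULL` when `dose`/`fa` vectors are
#'   given directly.
#' @param dose,fa alternative vector interface.
#' @param fa_bounds open filtering interval for usable fa values
#'   (default `c(0.005, 0.995)`).
#' @param drug_id label stored in the fit.
#' @return an object of class `median_effect_fit` with elements `Dm`
#'   (median-effect dose, the model IC50), `m` (slope), `r` (Pearson
#'   correlation of the median-effect plot), `n_used`, `n_excluded`.
#' @examples
#' s <- simulate_dose_response(median_effect_params(2, 1.5), c(0.5, 1, 2, 4, 8))
#' fit_median_effect(s)
#' @export
fit_median_effect <- function(series = NULL, dose = NULL, fa = NULL,
                              fa_bounds = c(0.005, 0.995), drug_id = NULL) {
  if (!is.null(series)) {
    if (!all(c("dose", "fa") %in% names(series))) {
      ss_stop("missing_column", "series needs columns `dose` and `fa`")
    }
    dose <- series$dose
    fa <- series$fa
    if (is.null(drug_id) && "drug_id" %in% names(series)) {
      drug_id <- series$drug_id[1]
    }
  }
  if (length(dose) != length(fa)) {
    ss_stop("invalid_argument", "dose and fa must have equal length")
  }
  if (any(dose <= 0)) {
    ss_stop("invalid_dose", "doses must be strictly positive")
  }
  usable <- fa > fa_bounds[1] & fa < fa_bounds[2]
  n_excluded <- sum(!usable)
  x <- log10(dose[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  if (length(x) < 3) {
    ss_stop("fit_impossible",
            "fewer than 3 usable points after filtering fa to (%g, %g)",
            fa_bounds[1], fa_bounds[2])
  }
  co <- stats::coef(stats::lm(y ~ x))
  m <- unname(co[2])
  if (!is.finite(m) || m <= 0) {
    ss_stop("model_violation",
            "median-effect slope is not positive: non-monotone dose-response")
  }
  Dm <- 10^(-unname(co[1]) / m)
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(
    list(Dm = Dm, m = m, r = r, n_used = length(x), n_excluded = n_excluded,
         drug_id = drug_id),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit%s> Dm = %.5g, m = %.4g, r = %.5f (n = %d, excluded %d)\n",
              if (is.null(x$drug_id)) "" else paste0(": ", x$drug_id),
              x$Dm, x$m, x$r, x$n_used, x$n_excluded))
  invisible(x)
}

#' Dose producing a given fraction affected
#'
#' Inverts the median-effect model: `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a [fit_median_effect()] result (or anything with `Dm`, `m`).
#' @param fa effect level(s), each strictly inside (0, 1).
#' @return dose(s) achieving `fa`.
#' @examples
#' f <- list(Dm = 2, m = 1)
#' dose_for_fa(f, 0.8)  # 8
#' @export
dose_for_fa <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) {
    ss_stop("invalid_effect_level",
            "fa must lie strictly in (0, 1): the required dose is otherwise infinite")
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay Combination Index at chosen effect levels
#'
#' For a constant-ratio combination fitted as a single agent on total dose:
#' at each effect level `fa`, the total combination dose achieving `fa` is
#' split into component doses `d1 = ratio[1] * D_total`,
#' `d2 = ratio[2] * D_total`, and compared with the single-agent doses
#' `Dx1`, `Dx2` achieving the same effect. The (mutually exclusive,
#' two-term) Combination Index is `CI = d1/Dx1 + d2/Dx2`; CI < 1 indicates
#' synergism and CI > 1 antagonism, with additivity only at equality
#' (within `tol`).
#'
#' @param fit_a,fit_b single-agent [fit_median_effect()] results.
#' @param fit_combo fit of the combination series on total dose.
#' @param ratio length-2 positive dose fractions of the two components,
#'   summing to 1.
#' @param fa_levels effect levels at which to evaluate CI (default
#'   `c(0.5, 0.75, 0.9)`).
#' @param tol half-width of the additivity band around CI = 1 (default
#'   1e-9).
#' @return a tibble with one row per effect level: `fa`, `D_total`, `d1`,
#'   `d2`, `Dx1`, `Dx2`, `CI`, `classification`.
#' @examples
#' s <- simulate_dose_response(median_effect_params(2, 1.5), c(0.5, 1, 2, 4, 8))
#' f <- fit_median_effect(s)
#' combination_index(f, f, f)  # sham self-combination: CI = 1 everywhere
#' @export
combination_index <- function(fit_a, fit_b, fit_combo, ratio = c(0.5, 0.5),
                              fa_levels = c(0.5, 0.75, 0.9), tol = 1e-9) {
  if (length(ratio) != 2 || any(ratio <= 0) || abs(sum(ratio) - 1) > 1e-12) {
    ss_stop("invalid_argument", "ratio must be two positive fractions summing to 1")
  }
  if (any(fa_levels <= 0 | fa_levels >= 1)) {
    ss_stop("invalid_effect_level", "every fa level must lie strictly in (0, 1)")
  }
  D_total <- dose_for_fa(fit_combo, fa_levels)
  d1 <- ratio[1] * D_total
  d2 <- ratio[2] * D_total
  Dx1 <- dose_for_fa(fit_a, fa_levels)
  Dx2 <- dose_for_fa(fit_b, fa_levels)
  CI <- d1 / Dx1 + d2 / Dx2
  tibble::tibble(
    fa = fa_levels, D_total = D_total, d1 = d1, d2 = d2,
    Dx1 = Dx1, Dx2 = Dx2, CI = CI,
    classification = ifelse(CI < 1 - tol, "synergism",
                            ifelse(CI > 1 + tol, "antagonism", "additivity"))
  )
}

#' IC50 of a fitted dose-response
#'
#' Under the median-effect model the dose giving half-maximal inhibition is
#' the median-effect dose itself: `ic50(fit)` returns `Dm`, identically
#' `dose_for_fa(fit, 0.5)`.
#'
#' @param fit a [fit_median_effect()] result.
#' @return the IC50 (same concentration units as the doses).
#' @export
ic50 <- function(fit) fit$Dm

#' IC50 fold shift caused by a sensitizer
#'
#' Ratio of the IC50 without a sensitizer to the IC50 with it; values above
#' 1 mean the sensitizer lowered the IC50 (sensitization).
#'
#' @param fit_alone fit of the drug alone.
#' @param fit_with_sensitizer fit in the presence of the sensitizer.
#' @return the fold shift.
#' @export
ic50_fold_shift <- function(fit_alone, fit_with_sensitizer) {
  ic50(fit_alone) / ic50(fit_with_sensitizer)
}

#' Resistance factor of a drug-tolerant line
#'
#' Ratio of a drug-tolerant line's IC50 to the parental line's; the line is
#' flagged resistant when the ratio reaches `threshold` (inclusive),
#' mirroring selection protocols that passage cells until the IC50 is about
#' ten times the parental value.
#'
#' @param fit_tolerant,fit_parental [fit_median_effect()] results.
#' @param threshold fold-change defining resistance (default 10).
#' @return a list with `ratio` and `is_resistant`.
#' @export
resistance_factor <- function(fit_tolerant, fit_parental, threshold = 10) {
  ratio <- ic50(fit_tolerant) / ic50(fit_parental)
  list(ratio = ratio, is_resistant = ratio >= threshold)
}
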