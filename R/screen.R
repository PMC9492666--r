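#' Synergy Index of a compound-inducer pair
#'
#' The screening statistic `SI = (fa_comb - fa_cpd) / fa_inducer`: the
#' incremental kill attributable to the combination, scaled by the
#' inducer's own effect. SI > 1 indicates synergism, SI < 1 antagonism; the
#' value may be negative when the combination is weaker than the compound
#' alone. When the inducer-alone effect falls below `epsilon` the ratio is
#' numerically meaningless and the SI is reported as missing (`NA`), never
#' as 0.
#'
#' @param fa_comb fraction affected of the combination.
#' @param fa_cpd fraction affected of the compound alone.
#' @param fa_inducer fraction affected of the inducer alone.
#' @param epsilon minimum inducer effect for a defined SI (default 0.01).
#' @return numeric SI values (vectorized); `NA` where undefined.
#' @examples
#' synergy_index(0.9, 0.1, 0.3)  # 2.667
#' @export
synergy_index <- function(fa_comb, fa_cpd, fa_inducer, epsilon = 0.01) {
  vals <- c(fa_comb, fa_cpd, fa_inducer)
  if (any(!is.na(vals) & (vals < 0 | vals > 1))) {
    ss_stop("invalid_argument", "all fraction-affected inputs must lie in [0, 1]")
  }
  si <- (fa_comb - fa_cpd) / fa_inducer
  undef <- !is.na(fa_inducer) & fa_inducer < epsilon
  if (any(undef)) {
    warning(sprintf("%d SI value(s) undefined: inducer effect below epsilon = %g",
                    sum(undef), epsilon), call. = FALSE)
    si[undef] <- NA_real_
  }
  si
}

#' Score a screen: Synergy Index per compound against both inducers
#'
#' Reshapes an fa table (output of [normalize_plate()]) into one row per
#' compound, computes the Synergy Index against each inducer, applies the
#' hit rule via [call_hits()], and ranks compounds by `min(si_E, si_R)`
#' descending (ties broken by mean combination kill descending, then
#' compound id). Compounds missing an arm get a missing SI and are excluded
#' from hit calling; a missing inducer-alone record aborts the whole screen
#' since the SI denominator is then undefined for every compound.
#'
#' @param fa_table tibble with columns `compound_id`, `arm`, `fa` (and
#'   optionally `sd`); arms `cpd`, `combo_E`, `combo_R` per compound plus
#'   inducer-alone arms `inducer_E` and `inducer_R`.
#' @param epsilon minimum inducer-alone effect for a defined SI.
#' @param death_threshold combination fraction affected required of a hit
#'   (default 0.5, i.e. at least 50% death under both combinations).
#' @return a tibble with one row per compound: fa values, `si_E`, `si_R`,
#'   propagated `si_sd` columns when replicate sds are present, `is_hit`,
#'   and `rank`.
#' @export
score_screen <- function(fa_table, epsilon = 0.01, death_threshold = 0.5) {
  needed <- c("compound_id", "arm", "fa")
  if (length(setdiff(needed, names(fa_table)))) {
    ss_stop("missing_column", "fa table needs columns compound_id, arm, fa")
  }
  get_inducer <- function(arm) {
    row <- fa_table[fa_table$arm == arm, ]
    if (nrow(row) != 1) {
      ss_stop("missing_inducer",
              "inducer-alone record `%s` absent or duplicated: SI undefined for all compounds",
              arm)
    }
    row
  }
  ind_E <- get_inducer("inducer_E")
  ind_R <- get_inducer("inducer_R")

  cpd_tab <- fa_table[fa_table$arm %in% c("cpd", "combo_E", "combo_R") &
                        !is.na(fa_table$compound_id), ]
  has_sd <- "sd" %in% names(cpd_tab)
  wide <- tidyr::pivot_wider(
    cpd_tab[, c("compound_id", "arm", "fa", if (has_sd) "sd")],
    names_from = "arm",
    values_from = c("fa", if (has_sd) "sd")
  )
  for (col in c("fa_cpd", "fa_combo_E", "fa_combo_R")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  res <- tibble::tibble(
    compound_id = wide$compound_id,
    fa_cpd = wide$fa_cpd,
    fa_inducer_E = ind_E$fa,
    fa_inducer_R = ind_R$fa,
    fa_comb_E = wide$fa_combo_E,
    fa_comb_R = wide$fa_combo_R
  )
  res$si_E <- synergy_index(res$fa_comb_E, res$fa_cpd, ind_E$fa, epsilon)
  res$si_R <- synergy_index(res$fa_comb_R, res$fa_cpd, ind_R$fa, epsilon)

  if (has_sd) {
    # descriptive uncertainty: replicate sds propagated in quadrature
    res$si_sd_E <- sqrt(wide$sd_combo_E^2 + wide$sd_cpd^2) / ind_E$fa
    res$si_sd_R <- sqrt(wide$sd_combo_R^2 + wide$sd_cpd^2) / ind_R$fa
  }

  res$is_hit <- with(res, !is.na(si_E) & !is.na(si_R) &
                       si_E > 1 & si_R > 1 &
                       fa_comb_E >= death_threshold & fa_comb_R >= death_threshold)
  score <- pmin(res$si_E, res$si_R)
  tie <- (res$fa_comb_E + res$fa_comb_R) / 2
  res$rank <- rank_screen(score, tie, res$compound_id)
  res[order(res$rank), ]
}

# ordinal rank: min(si) desc, mean combo kill desc, compound id asc;
# undefined scores sink to the bottom
rank_screen <- function(score, tie, id) {
  score[is.na(score)] <- -Inf
  tie[is.na(tie)] <- -Inf
  ord <- order(-score, -tie, id)
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  r
}

#' Apply the two-inducer hit rule
#'
#' A compound is a hit when both combinations kill at least
#' `death_threshold` of cells (inclusive) and both Synergy Index values
#' strictly exceed 1.
#'
#' @param results a [score_screen()] table.
#' @param death_threshold minimum combination fraction affected (default
#'   0.5).
#' @return the subset of `results` that are hits (with `is_hit`
#'   recomputed).
#' @export
call_hits <- function(results, death_threshold = 0.5) {
  results$is_hit <- with(results, !is.na(si_E) & !is.na(si_R) &
                           si_E > 1 & si_R > 1 &
                           fa_comb_E >= death_threshold &
                           fa_comb_R >= death_threshold)
  results[results$is_hit, ]
}

#' Intersect hit calls across cell lines
#'
#' A multi-line screen is scored per line; by default a compound counts as
#' a screen-wide hit only when every line calls it (intersection rule).
#'
#' @param results_list list of [score_screen()] tables, one per cell line.
#' @param rule `"intersection"` (default) or `"union"`.
#' @return character vector of compound ids.
#' @export
combine_screen_hits <- function(results_list, rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  hit_sets <- lapply(results_list, function(r) r$compound_id[r$is_hit])
  Reduce(if (rule == "intersection") intersect else union, hit_sets)
}
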