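#' Fraction affected from raw replicate signals
#'
#' Normalizes treated well signals against vehicle and blank controls:
#' per-replicate viability is `(signal - blank_mean) / (vehicle_mean -
#' blank_mean)`, fraction affected is `1 - viability`, and each replicate's
#' fa is clamped to `[0, 1]` before averaging so the replicate dispersion
#' stays meaningful and downstream Synergy Index denominators stay bounded.
#'
#' @param treated_signals one or more raw signals for the condition.
#' @param vehicle_signals raw signals of vehicle-control wells (mean is
#'   taken).
#' @param blank_signals raw signals of medium-only blank wells; defaults to
#'   0 for assays run without a blank.
#' @return a one-row tibble with `fa` (mean clamped fraction affected),
#'   `n` (replicate count) and `sd` (dispersion of per-replicate fa).
#' @examples
#' compute_fa(c(0.55, 0.45, 0.50), vehicle_signals = c(1.0, 1.1), blank_signals = 0.05)
#' @export
compute_fa <- function(treated_signals, vehicle_signals, blank_signals = 0) {
  if (length(treated_signals) < 1) {
    ss_stop("invalid_argument", "at least one treated replicate is required")
  }
  if (any(c(treated_signals, vehicle_signals, blank_signals) < 0)) {
    ss_stop("invalid_argument", "signals must be nonnegative")
  }
  v <- mean(vehicle_signals)
  b <- mean(blank_signals)
  if (v <= b) {
    ss_stop("normalization_impossible",
            "vehicle mean (%g) does not exceed blank mean (%g): failed plate", v, b)
  }
  fa_rep <- pmin(1, pmax(0, 1 - (treated_signals - b) / (v - b)))
  tibble::tibble(
    fa = mean(fa_rep),
    n = length(fa_rep),
    sd = if (length(fa_rep) > 1) stats::sd(fa_rep) else 0
  )
}

#' Normalize a wells table to fraction-affected records
#'
#' Applies [compute_fa()] to every non-control well using its own plate's
#' vehicle and blank wells (normalization is plate-local), then aggregates
#' per condition `(compound_id, arm, dose)` across plates. Plates missing
#' the required controls are rejected with a warning and their conditions
#' dropped.
#'
#' @param wells a wells table with columns `plate`, `well`, `compound_id`,
#'   `arm`, `dose`, `replicate`, `signal`; arms `vehicle` and `blank` mark
#'   the controls.
#' @param require_blank reject plates lacking blank wells (default). With
#'   `FALSE`, blank-free plates are normalized against a zero blank.
#' @param min_controls minimum vehicle (and, if required, blank) wells per
#'   plate (default 2).
#' @return an fa table: one row per condition with `compound_id`, `arm`,
#'   `dose`, `fa`, `n`, `sd`.
#' @export
normalize_plate <- function(wells, require_blank = TRUE, min_controls = 2L) {
  needed <- c("plate", "compound_id", "arm", "dose", "replicate", "signal")
  missing_cols <- setdiff(needed, names(wells))
  if (length(missing_cols)) {
    ss_stop("missing_column", "wells table lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  out <- vector("list", 0L)
  for (p in unique(wells$plate)) {
    pw <- wells[wells$plate == p, ]
    veh <- pw$signal[pw$arm == "vehicle"]
    blk <- pw$signal[pw$arm == "blank"]
    if (length(veh) < min_controls) {
      warning(sprintf("plate %s rejected: %d vehicle wells (need >= %d)",
                      p, length(veh), min_controls), call. = FALSE)
      next
    }
    if (length(blk) < min_controls) {
      if (require_blank) {
        warning(sprintf("plate %s rejected: %d blank wells (need >= %d)",
                        p, length(blk), min_controls), call. = FALSE)
        next
      }
      blk <- 0
    }
    v <- mean(veh); b <- mean(blk)
    if (v <= b) {
      warning(sprintf("plate %s rejected: vehicle mean <= blank mean", p),
              call. = FALSE)
      next
    }
    trt <- pw[!pw$arm %in% c("vehicle", "blank"), ]
    trt$fa_rep <- pmin(1, pmax(0, 1 - (trt$signal - b) / (v - b)))
    out[[length(out) + 1L]] <- trt
  }
  if (!length(out)) {
    ss_stop("no_usable_plates", "no plate passed control-well validation")
  }
  trt <- dplyr::bind_rows(out)
  res <- dplyr::summarise(
    dplyr::group_by(trt, compound_id, arm, dose),
    fa = mean(fa_rep),
    n = dplyr::n(),
    sd = ifelse(dplyr::n() > 1, stats::sd(fa_rep), 0),
    .groups = "drop"
  )
  tibble::as_tibble(res[order(res$arm, res$compound_id), ])
}
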