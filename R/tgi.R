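#' Tumor volume from caliper diameters
#'
#' `V = L * S^2 / 2` (mm3) from the longest (`L`) and shortest (`S`)
#' diameters in mm — the standard ellipsoid approximation for
#' subcutaneous xenografts.
#'
#' @param L,S longest and shortest diameters (mm), vectorized.
#' @param fix_swapped with `TRUE`, pairs recorded in the wrong order
#'   (`S > L`) are swapped instead of raising an error.
#' @return volumes in mm3.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(L, S, fix_swapped = FALSE) {
  if (any(L <= 0 | S <= 0)) {
    ss_stop("invalid_argument", "diameters must be positive")
  }
  swapped <- S > L
  if (any(swapped)) {
    if (!fix_swapped) {
      ss_stop("measurement_order",
              "%d pair(s) have S > L (diameters swapped?); use fix_swapped = TRUE to auto-correct",
              sum(swapped))
    }
    tmp <- L[swapped]
    L[swapped] <- S[swapped]
    S[swapped] <- tmp
  }
  L * S^2 / 2
}

#' Tumor growth inhibition percentage
#'
#' `TGI = (Vc - Vt) / (Vc - V0) * 100`, where `Vc` and `Vt` are the median
#' volumes of the control and treated groups at the end of the study and
#' `V0` is the control median at the start. Values above 100 (regression
#' below baseline) and below 0 (treated grew faster than control) are legal
#' and reported as-is.
#'
#' @param Vc,Vt,V0 median volumes (mm3); `Vc` must exceed `V0`.
#' @return TGI in percent.
#' @examples
#' tgi(Vc = 1000, Vt = 300, V0 = 100)  # 77.78
#' @export
tgi <- function(Vc, Vt, V0) {
  if (any(Vc <= V0)) {
    ss_stop("undefined_tgi", "control did not grow (Vc <= V0): TGI undefined")
  }
  (Vc - Vt) / (Vc - V0) * 100
}

#' Tumor growth inhibition from caliper trajectories
#'
#' Computes volumes with [tumor_volume()], takes group medians, and applies
#' [tgi()] per treated group. The endpoint is the last measurement day
#' common to the control and all treated groups that does not exceed
#' `endpoint_day`; animals without an endpoint measurement contribute their
#' last earlier observation (last observation carried forward, with a
#' message counting affected animals). The baseline is the first
#' measurement day, and `V0` is by default the control group's baseline
#' median; `baseline = "per_group"` uses each treated group's own baseline
#' instead.
#'
#' @param trajectories tibble with columns `animal_id`, `group`, `day`,
#'   `L_mm`, `S_mm` (e.g. from [simulate_xenograft()]).
#' @param control_group label of the control group.
#' @param endpoint_day latest study day considered (default: last day
#'   observed in the control group).
#' @param baseline `"control"` (default) or `"per_group"`.
#' @param fix_swapped passed to [tumor_volume()].
#' @return a tibble with one row per treated group: `group`, `Vc`, `Vt`,
#'   `V0`, `tgi_percent`.
#' @export
tgi_from_trajectories <- function(trajectories, control_group,
                                  endpoint_day = NULL,
                                  baseline = c("control", "per_group"),
                                  fix_swapped = FALSE) {
  baseline <- match.arg(baseline)
  needed <- c("animal_id", "group", "day", "L_mm", "S_mm")
  if (length(setdiff(needed, names(trajectories)))) {
    ss_stop("missing_column", "trajectories need columns: %s",
            paste(needed, collapse = ", "))
  }
  if (!control_group %in% trajectories$group) {
    ss_stop("invalid_argument", "control group `%s` not present", control_group)
  }
  tr <- trajectories
  tr$volume <- tumor_volume(tr$L_mm, tr$S_mm, fix_swapped = fix_swapped)

  if (is.null(endpoint_day)) {
    endpoint_day <- max(tr$day[tr$group == control_group])
  }
  # endpoint: last day <= endpoint_day measured in every group
  common_days <- Reduce(intersect, tapply(tr$day, tr$group, unique))
  common_days <- common_days[common_days <= endpoint_day]
  if (!length(common_days)) {
    ss_stop("undefined_tgi", "no common measurement day at or before day %g",
            endpoint_day)
  }
  end_day <- max(common_days)
  base_day <- min(tr$day)

  vol_at <- function(rows, day) {
    # per-animal volume at `day`, LOCF for animals measured only earlier
    locf <- 0L
    v <- vapply(split(rows, rows$animal_id), function(a) {
      a <- a[a$day <= day, ]
      if (!nrow(a)) return(NA_real_)
      if (max(a$day) < day) locf <<- locf + 1L
      a$volume[which.max(a$day)]
    }, numeric(1))
    if (locf > 0) {
      message(sprintf("day %g: last observation carried forward for %d animal(s)",
                      day, locf))
    }
    v[!is.na(v)]
  }

  ctrl_rows <- tr[tr$group == control_group, ]
  Vc <- stats::median(vol_at(ctrl_rows, end_day))
  V0_ctrl <- stats::median(vol_at(ctrl_rows, base_day))

  treated <- setdiff(unique(tr$group), control_group)
  rows <- lapply(treated, function(g) {
    grows <- tr[tr$group == g, ]
    if (!nrow(grows)) {
      warning(sprintf("group %s empty: skipped", g), call. = FALSE)
      return(NULL)
    }
    Vt <- stats::median(vol_at(grows, end_day))
    V0 <- if (baseline == "control") V0_ctrl else stats::median(vol_at(grows, base_day))
    tibble::tibble(group = g, Vc = Vc, Vt = Vt, V0 = V0,
                   tgi_percent = tgi(Vc, Vt, V0))
  })
  dplyr::bind_rows(rows)
}
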