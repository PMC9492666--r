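#' Configuration for a simulated combination screen
#'
#' Describes a single-dose combination screen of a compound library against
#' two ferroptosis inducers (labelled `E` for an erastin-like system-xc
#' inhibitor and `R` for an RSL3-like GPX4 inhibitor) in 96-well format.
#' Non-hit combinations follow Bliss independence,
#' `fa_comb = fa_cpd + fa_inducer - fa_cpd * fa_inducer`; compounds listed in
#' `hit_indices` additionally receive a Bliss-excess boost `bliss_excess`
#' (clamped so the true fraction affected stays at most 1).
#'
#' The defaults encode the reference screen used throughout the package:
#' 303 library compounds, 10 planted synergistic hits, both inducers dosed to
#' a 0.3 fraction affected, a Bliss excess of 0.35, additive plate-reader
#' noise of 0.02 absorbance units, and triplicate wells.
#'
#' @param n_compounds number of library compounds (default 303).
#' @param hit_indices integer indices of planted synergistic compounds;
#'   default: 10 evenly spaced indices across the library.
#' @param fa_cpd_range range of single-compound fractions affected, drawn
#'   uniformly per compound. The default `[0, 0.5]` reflects screening doses
#'   chosen to be sub-lethal as single agents.
#' @param fa_inducer named numeric of length 2 (`E`, `R`): fraction affected
#'   of each inducer alone, each strictly positive (Synergy Index
#'   denominator).
#' @param bliss_excess additive boost applied to the combination fraction
#'   affected of planted hits (the planted synergy signal), in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian viability noise
#'   (one viability unit spans the vehicle-blank signal window); noisy
#'   signals are floored at half the blank level.
#' @param n_replicates wells per condition (default 3).
#' @param seed integer random seed; identical seeds give bit-identical
#'   output.
#' @param vehicle_signal,blank_signal nominal raw signals of vehicle and
#'   medium-only blank wells (absorbance-like units).
#' @param compound_dose,inducer_dose metadata doses recorded in the wells
#'   table (uM); they do not enter the generative model.
#'
#' @return an object of class `screen_sim_config`.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_compounds = 303,
                              hit_indices = NULL,
                              fa_cpd_range = c(0, 0.5),
                              fa_inducer = c(E = 0.3, R = 0.3),
                              bliss_excess = 0.35,
                              noise_sd = 0.02,
                              n_replicates = 3,
                              seed = 1,
                              vehicle_signal = 1.0,
                              blank_signal = 0.05,
                              compound_dose = 10,
                              inducer_dose = c(E = 10, R = 1)) {
  n_compounds <- check_count(n_compounds, "n_compounds")
  if (is.null(hit_indices)) {
    hit_indices <- unique(round(seq(1, n_compounds, length.out = min(10, n_compounds))))
  }
  hit_indices <- sort(unique(as.integer(hit_indices)))
  if (length(hit_indices) && (min(hit_indices) < 1 || max(hit_indices) > n_compounds)) {
    ss_stop("invalid_argument", "hit_indices must lie in 1..n_compounds")
  }
  if (length(fa_cpd_range) != 2 || any(fa_cpd_range < 0) || any(fa_cpd_range > 1) ||
      fa_cpd_range[1] > fa_cpd_range[2]) {
    ss_stop("invalid_argument", "fa_cpd_range must be an ordered interval within [0, 1]")
  }
  if (length(fa_inducer) != 2 || is.null(names(fa_inducer)) ||
      !setequal(names(fa_inducer), c("E", "R"))) {
    ss_stop("invalid_argument", "fa_inducer must be a named numeric with names E and R")
  }
  fa_inducer <- fa_inducer[c("E", "R")]
  if (any(fa_inducer <= 0) || any(fa_inducer >= 1)) {
    ss_stop("invalid_argument", "each fa_inducer must lie strictly in (0, 1)")
  }
  check_number(bliss_excess, "bliss_excess", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  seed <- check_count(seed, "seed", min = 0L)
  check_number(vehicle_signal, "vehicle_signal", lower = 0, strict_lower = TRUE)
  check_number(blank_signal, "blank_signal", lower = 0)
  if (vehicle_signal <= blank_signal) {
    ss_stop("invalid_argument", "vehicle_signal must exceed blank_signal")
  }
  structure(
    list(
      n_compounds = n_compounds, hit_indices = hit_indices,
      fa_cpd_range = as.numeric(fa_cpd_range), fa_inducer = fa_inducer,
      bliss_excess = bliss_excess, noise_sd = noise_sd,
      n_replicates = n_replicates, seed = seed,
      vehicle_signal = vehicle_signal, blank_signal = blank_signal,
      compound_dose = compound_dose, inducer_dose = inducer_dose[c("E", "R")]
    ),
    class = "screen_sim_config"
  )
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat("<screen_sim_config>\n")
  cat(sprintf("  %d compounds, %d planted hits, %d replicates, seed %d\n",
              x$n_compounds, length(x$hit_indices), x$n_replicates, x$seed))
  cat(sprintf("  fa_inducer E = %.3g, R = %.3g; Bliss excess = %.3g; noise sd = %.3g\n",
              x$fa_inducer[["E"]], x$fa_inducer[["R"]], x$bliss_excess, x$noise_sd))
  invisible(x)
}

# 96-well layout constants: controls occupy columns 1 (vehicle) and 12
# (blank), leaving 80 sample wells per plate.
PLATE_ROWS <- LETTERS[1:8]
N_SAMPLE_WELLS <- 80L
N_CONTROL_WELLS <- 8L

sample_well_ids <- function() {
  as.vector(outer(PLATE_ROWS, 2:11, function(r, c) sprintf("%s%02d", r, c)))
}

#' Simulate a combination screen with planted synergistic hits
#'
#' Emits one raw well per condition and replicate: vehicle and blank control
#' wells on every plate, each compound alone, each inducer alone, and each
#' compound + inducer pair. The raw signal of a well with true fraction
#' affected `fa` is `(1 - fa) * (vehicle_signal - blank_signal) +
#' blank_signal` plus Gaussian viability-scale noise, floored at half the
#' blank signal.
#' Condition wells are laid out 80 to a plate with 8 vehicle and 8 blank
#' wells on each plate (control columns 1 and 12).
#'
#' A ground-truth sidecar records, per compound, the noiseless fractions
#' affected, both true Synergy Index values
#' (`SI = (fa_comb - fa_cpd) / fa_inducer`; under Bliss independence with no
#' excess this is `1 - fa_cpd`), and whether the compound truly satisfies the
#' hit rule. The truth object is a separate artifact that no downstream
#' pipeline stage reads.
#'
#' @param config a [screen_sim_config()].
#' @param death_threshold fraction-affected level defining "at least 50%
#'   death" in the truth hit flags (default 0.5).
#'
#' @return a list with elements `wells` (tibble: plate, well, compound_id,
#'   arm, dose, replicate, signal) and `truth` (list with `compounds` tibble,
#'   `inducers`, and the config).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_compounds = 20, seed = 7))
#' head(sim$wells)
#' sim$truth$compounds[sim$truth$compounds$is_hit, ]
#' @export
simulate_screen <- function(config, death_threshold = 0.5) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  compound_id <- sprintf("CPD_%03d", seq_len(n))

  fa_cpd <- stats::runif(n, config$fa_cpd_range[1], config$fa_cpd_range[2])
  fa_E <- config$fa_inducer[["E"]]
  fa_R <- config$fa_inducer[["R"]]
  is_planted <- seq_len(n) %in% config$hit_indices
  delta <- ifelse(is_planted, config$bliss_excess, 0)

  bliss <- function(fc, fi) fc + fi - fc * fi
  fa_comb_E <- pmin(1, bliss(fa_cpd, fa_E) + delta)
  fa_comb_R <- pmin(1, bliss(fa_cpd, fa_R) + delta)
  si_E <- (fa_comb_E - fa_cpd) / fa_E
  si_R <- (fa_comb_R - fa_cpd) / fa_R

  if (any(is_planted & (si_E <= 1 | si_R <= 1))) {
    ss_stop("unusable_ground_truth",
            "bliss_excess too small: a planted hit has true SI <= 1")
  }

  truth_compounds <- tibble::tibble(
    compound_id = compound_id, fa_cpd = fa_cpd,
    fa_comb_E = fa_comb_E, fa_comb_R = fa_comb_R,
    si_E = si_E, si_R = si_R,
    is_planted = is_planted,
    is_hit = si_E > 1 & si_R > 1 &
      fa_comb_E >= death_threshold & fa_comb_R >= death_threshold
  )

  # one condition row per (compound x arm) plus the two inducer-alone arms
  conditions <- tibble::tibble(
    compound_id = c(rep(compound_id, 3L), NA_character_, NA_character_),
    arm = c(rep(c("cpd", "combo_E", "combo_R"), each = n), "inducer_E", "inducer_R"),
    dose = c(rep(config$compound_dose, n),
             rep(config$compound_dose, 2L * n),
             config$inducer_dose[["E"]], config$inducer_dose[["R"]]),
    fa_true = c(fa_cpd, fa_comb_E, fa_comb_R, fa_E, fa_R)
  )
  reps <- config$n_replicates
  cond_wells <- conditions[rep(seq_len(nrow(conditions)), each = reps), ]
  cond_wells$replicate <- rep(seq_len(reps), nrow(conditions))

  n_cond <- nrow(cond_wells)
  n_plates <- ceiling(n_cond / N_SAMPLE_WELLS)
  cond_wells$plate <- sprintf("P%02d", ceiling(seq_len(n_cond) / N_SAMPLE_WELLS))
  cond_wells$well <- sample_well_ids()[(seq_len(n_cond) - 1L) %% N_SAMPLE_WELLS + 1L]

  ctrl <- tibble::tibble(
    plate = rep(sprintf("P%02d", seq_len(n_plates)), each = 2L * N_CONTROL_WELLS),
    well = rep(c(sprintf("%s01", PLATE_ROWS), sprintf("%s12", PLATE_ROWS)), n_plates),
    compound_id = NA_character_,
    arm = rep(rep(c("vehicle", "blank"), each = N_CONTROL_WELLS), n_plates),
    dose = NA_real_,
    replicate = rep(rep(seq_len(N_CONTROL_WELLS), 2L), n_plates),
    fa_true = NA_real_
  )

  wells <- dplyr::bind_rows(
    cond_wells[, c("plate", "well", "compound_id", "arm", "dose", "replicate", "fa_true")],
    ctrl
  )
  wells <- wells[order(wells$plate, wells$well), ]

  span <- config$vehicle_signal - config$blank_signal
  mu <- ifelse(
    wells$arm == "blank", config$blank_signal,
    ifelse(wells$arm == "vehicle", config$vehicle_signal,
           (1 - wells$fa_true) * span + config$blank_signal)
  )
  # noise_sd is on the viability scale; one viability unit spans
  # (vehicle - blank) signal units
  noise <- if (config$noise_sd > 0) {
    stats::rnorm(nrow(wells), 0, config$noise_sd * span)
  } else 0
  wells$signal <- pmax(mu + noise, config$blank_signal * 0.5)
  wells$fa_true <- NULL

  list(
    wells = wells,
    truth = list(
      compounds = truth_compounds,
      inducers = c(E = fa_E, R = fa_R),
      config = config
    )
  )
}
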