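# Tab-separated interchange tables with schema validation. Plate data has
# no dominant standard format; plain delimited text with a one-line header
# keeps every stage output diffable.

TABLE_SCHEMAS <- list(
  wells = list(
    columns = c(plate = "character", well = "character",
                compound_id = "character", arm = "character",
                dose = "numeric", replicate = "numeric", signal = "numeric"),
    nonneg = c("dose", "signal"), na_ok = c("compound_id", "dose")
  ),
  fa = list(
    columns = c(compound_id = "character", arm = "character", dose = "numeric",
                fa = "numeric", n = "numeric", sd = "numeric"),
    nonneg = c("dose", "fa", "n", "sd"), na_ok = c("compound_id", "dose")
  ),
  series = list(
    columns = c(drug_id = "character", dose = "numeric", fa = "numeric"),
    nonneg = c("dose", "fa"), na_ok = character(0)
  ),
  trajectories = list(
    columns = c(animal_id = "character", group = "character", day = "numeric",
                L_mm = "numeric", S_mm = "numeric"),
    nonneg = c("day", "L_mm", "S_mm"), na_ok = character(0)
  )
)

#' Read a validated pipeline table
#'
#' Reads a tab-separated stage file and validates it against a named
#' schema: required columns must be present, numeric columns must parse,
#' and nonnegative columns must be nonnegative. Offending rows are reported
#' with their line numbers. Distinct failure modes raise distinct condition
#' classes (`file_not_found`, `empty_file`, `missing_column`,
#' `bad_numeric`, `negative_value`).
#'
#' @param path file path.
#' @param schema one of `"wells"`, `"fa"`, `"series"`, `"trajectories"`.
#' @return a validated tibble.
#' @export
read_table <- function(path, schema = names(TABLE_SCHEMAS)) {
  schema <- match.arg(schema)
  sch <- TABLE_SCHEMAS[[schema]]
  if (!file.exists(path)) {
    ss_stop("file_not_found", "no such file: %s", path)
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) {
    ss_stop("empty_file", "%s contains a header but no rows", path)
  }
  missing_cols <- setdiff(names(sch$columns), names(raw))
  if (length(missing_cols)) {
    ss_stop("missing_column", "%s lacks column(s): %s", path,
            paste(missing_cols, collapse = ", "))
  }
  out <- raw[names(sch$columns)]
  for (col in names(sch$columns)) {
    if (sch$columns[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(out[[col]]))
      blank <- is.na(out[[col]]) | out[[col]] == ""
      bad <- is.na(v) & !blank
      if (any(bad)) {
        ss_stop("bad_numeric", "%s: non-numeric `%s` at line(s) %s", path, col,
                paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
      }
      if (any(blank) && !col %in% sch$na_ok) {
        ss_stop("bad_numeric", "%s: missing `%s` at line(s) %s", path, col,
                paste(utils::head(which(blank) + 1L, 5), collapse = ", "))
      }
      if (col %in% sch$nonneg && any(v < 0, na.rm = TRUE)) {
        ss_stop("negative_value", "%s: negative `%s` at line(s) %s", path, col,
                paste(utils::head(which(v < 0) + 1L, 5), collapse = ", "))
      }
      out[[col]] <- v
    } else {
      out[[col]][!is.na(out[[col]]) & out[[col]] == ""] <- NA_character_
    }
  }
  tibble::as_tibble(out)
}

#' Write a pipeline table
#'
#' Tab-separated, unquoted, no row names — the interchange format used by
#' every stage. Writing then reading any stage output reproduces the table.
#'
#' @param x data frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full screening pipeline from one configuration
#'
#' Executes simulate, normalize and screen stages (plus optional
#' combination-index and xenograft TGI stages) from a single configuration,
#' writing every stage output and a manifest that records the package
#' version, seed, parameters, and an MD5 checksum of every file. Rerunning
#' the same configuration reproduces identical checksums.
#'
#' @param config a named list, or path to a YAML file, with optional
#'   entries: `out_dir` (required), `seed`, `stages` (subset of
#'   `c("simulate", "normalize", "screen", "ci", "tgi")`), `screen_sim`
#'   (arguments to [screen_sim_config()]), `screen` (`epsilon`,
#'   `death_threshold`), `ci` (`Dm_a`, `m_a`, `Dm_b`, `m_b`, `ratio`,
#'   `potency_shift`, `noise_sd`, `fa_levels`), `xeno` (arguments to
#'   [xeno_sim_config()]), `tgi` (`endpoint_day`).
#' @return the manifest (a list), invisibly; written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) {
    ss_stop("invalid_config", "config requires `out_dir`")
  }
  stages <- config$stages %||% c("simulate", "normalize", "screen", "ci", "tgi")
  known <- c("simulate", "normalize", "screen", "ci", "tgi")
  if (length(setdiff(stages, known))) {
    ss_stop("invalid_config", "unknown stage(s): %s",
            paste(setdiff(stages, known), collapse = ", "))
  }
  seed <- check_count(config$seed %||% 1, "seed", min = 0L)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  emit <- function(x, name) {
    write_table(x, outfile(name))
    written <<- c(written, name)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      ss_stop("stage_failure", "stage `%s` failed: %s", stage,
              conditionMessage(e))
    })
  }

  wells <- truth <- fa_tab <- results <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", {
      sim_args <- config$screen_sim %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_screen(do.call(screen_sim_config, sim_args))
      wells <- sim$wells
      truth <- sim$truth
      emit(wells, "wells.tsv")
      emit(truth$compounds, "screen_truth.tsv")
    })
  }
  if ("normalize" %in% stages) {
    run_stage("normalize", {
      if (is.null(wells)) wells <- read_table(outfile("wells.tsv"), "wells")
      fa_tab <- normalize_plate(wells)
      emit(fa_tab, "fa.tsv")
    })
  }
  if ("screen" %in% stages) {
    run_stage("screen", {
      if (is.null(fa_tab)) fa_tab <- read_table(outfile("fa.tsv"), "fa")
      scr <- config$screen %||% list()
      results <- score_screen(fa_tab,
                              epsilon = scr$epsilon %||% 0.01,
                              death_threshold = scr$death_threshold %||% 0.5)
      emit(results, "screen_results.tsv")
      emit(call_hits(results, scr$death_threshold %||% 0.5), "hits.tsv")
    })
  }
  if ("ci" %in% stages) {
    run_stage("ci", {
      ci_cfg <- config$ci %||% list()
      pa <- median_effect_params(ci_cfg$Dm_a %||% 2, ci_cfg$m_a %||% 1.5)
      pb <- median_effect_params(ci_cfg$Dm_b %||% 8, ci_cfg$m_b %||% 1.5)
      sim <- simulate_combo_matrix(
        pa, pb,
        ratio = ci_cfg$ratio %||% c(0.5, 0.5),
        potency_shift = ci_cfg$potency_shift %||% 0.5,
        noise_sd = ci_cfg$noise_sd %||% 0.02, seed = seed
      )
      emit(dplyr::bind_rows(sim$drug_a, sim$drug_b, sim$combo), "series.tsv")
      ci_tab <- combination_index(
        fit_median_effect(sim$drug_a), fit_median_effect(sim$drug_b),
        fit_median_effect(sim$combo),
        ratio = ci_cfg$ratio %||% c(0.5, 0.5),
        fa_levels = ci_cfg$fa_levels %||% c(0.5, 0.75, 0.9)
      )
      emit(ci_tab, "ci.tsv")
    })
  }
  if ("tgi" %in% stages) {
    run_stage("tgi", {
      xeno_args <- config$xeno %||% list()
      xeno_args$seed <- xeno_args$seed %||% seed
      xcfg <- do.call(xeno_sim_config, xeno_args)
      xsim <- simulate_xenograft(xcfg)
      emit(xsim$trajectories, "trajectories.tsv")
      emit(xsim$truth$groups, "xeno_truth.tsv")
      tgi_cfg <- config$tgi %||% list()
      tgi_tab <- tgi_from_trajectories(
        xsim$trajectories, control_group = xcfg$control,
        endpoint_day = tgi_cfg$endpoint_day %||% xcfg$horizon
      )
      emit(tgi_tab, "tgi.tsv")
    })
  }

  manifest <- list(
    package = "synergyscreen",
    version = as.character(utils::packageVersion("synergyscreen")),
    seed = seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("out_dir", "stages", "seed"))],
    checksums = as.list(tools::md5sum(file.path(config$out_dir, sort(written))))
  )
  names(manifest$checksums) <- sort(written)
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
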