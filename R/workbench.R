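## Config-driven workbench entry points chaining the stages, with schema
## validation, plain-text logging and provenance (config hash in every
## report).

wb_log <- function(level, ..., min_level = getOption("nirsim.log_level", "info")) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[min_level]]) {
    message("[", toupper(level), "] ", ...)
  }
}

config_schema <- list(
  sensitivity = list(
    required = character(0),
    optional = c("model", "layout", "wavelength_nm", "landmark",
                 "cube_edge_mm", "sweep", "sweep_distances_mm", "out_dir",
                 "keep_fields", "seed")),
  session = list(
    required = c("out_dir"),
    optional = c("simulate", "seed", "absorbance_csv", "events_csv",
                 "path_lengths_csv", "n_trials", "restraint",
                 "filter_order", "cutoff_hz", "detrend", "window_s",
                 "alpha", "noise", "drift")))

#' Validate a workbench run configuration
#'
#' Checks the configuration (a named list, or a path to a JSON file)
#' against the stage's schema before anything runs: unknown keys are
#' rejected by name, required keys must be present.
#'
#' @param config Named list or JSON file path.
#' @param stage `"sensitivity"` or `"session"`.
#' @return The validated config list, invisibly enriched with defaults.
#' @export
validate_run_config <- function(config, stage = c("sensitivity", "session")) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config))
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a named list or JSON path")
  sch <- config_schema[[stage]]
  unknown <- setdiff(names(config), c(sch$required, sch$optional))
  if (length(unknown)) {
    abort(paste0("unknown config key(s) for stage '", stage, "': ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(sch$required, names(config))
  if (length(missing)) {
    abort(paste0("missing required config key(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(config)
}

#' Run the sensitivity stage: per-channel calibration products
#'
#' Builds (or loads) the head model and optode layout, computes the
#' per-channel SSP/partial-path summary and the voxel-wise maximum
#' sensitivity map, optionally runs the source-detector distance sweep,
#' and writes CSV summaries plus a JSON report carrying the config hash.
#'
#' @param config See [validate_run_config()]; keys: `model` (`"phantom"`
#'   or a [read_voxel_model()] path), `layout` (`"packaged"` or a CSV
#'   path; adjacency JSON is looked up as `<path>.adjacency.json`),
#'   `wavelength_nm`, `landmark`, `cube_edge_mm`, `sweep`,
#'   `sweep_distances_mm`, `out_dir`, `keep_fields`.
#' @return List with `summary`, `sweep` (or NULL), `max_map`, and the
#'   output paths; files land in `out_dir`.
#' @export
run_sensitivity <- function(config = list()) {
  config <- validate_run_config(config, "sensitivity")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model_spec <- config$model %||% "phantom"
  # the full 15-optode array spans ~105 mm; the default phantom is wide
  # enough to host it with margin
  model <- if (identical(model_spec, "phantom")) {
    macaque_phantom(grid_shape = c(126, 40, 30))
  } else {
    if (!file.exists(model_spec)) {
      abort(paste0("model file not found: ", model_spec))
    }
    read_voxel_model(model_spec)
  }
  layout_spec <- config$layout %||% "packaged"
  layout <- if (identical(layout_spec, "packaged")) paper_layout() else {
    if (!file.exists(layout_spec)) {
      abort(paste0("layout file not found: ", layout_spec))
    }
    read_optode_layout(layout_spec, paste0(layout_spec, ".adjacency.json"),
                       edge_length = 15)
  }
  wl <- config$wavelength_nm %||% 805
  chans <- enumerate_channels(layout)
  # center the lattice on the projected landmark
  lm <- config$landmark %||% "hand_knob"
  proj <- project_to_surface(model, model$landmarks[[lm]])
  for (cc in c("x", "ax", "bx")) chans[[cc]] <- chans[[cc]] -
      mean(range(layout$optodes$x)) + proj[1]
  for (cc in c("y", "ay", "by")) chans[[cc]] <- chans[[cc]] -
      mean(range(layout$optodes$y)) + proj[2]
  wb_log("info", "computing sensitivities for ", nrow(chans),
         " channels at ", wl, " nm")
  sens <- channel_sensitivities(model, chans, wavelengths = wl,
                                landmark = lm,
                                cube_edge = config$cube_edge_mm %||% 5.4,
                                keep_fields = TRUE)
  max_map <- max_sensitivity_map(sens$fields)
  sweep <- NULL
  if (isTRUE(config$sweep)) {
    wb_log("info", "running source-detector distance sweep")
    sweep <- sweep_sd_distance(
      model, landmark = lm,
      distances = config$sweep_distances_mm %||% c(5, 10, 15, 20, 25),
      wavelength = wl)
  }
  hash <- rlang::hash(config)
  paths <- list(summary = file.path(out_dir, "channel_summary.csv"),
                max_map = file.path(out_dir, "max_sensitivity_map.bin"),
                report = file.path(out_dir, "sensitivity_report.json"))
  readr::write_csv(sens$summary, paths$summary)
  write_voxel_field(max_map, model$voxel_size, paths$max_map,
                    meta = list(config_hash = hash))
  if (!is.null(sweep)) {
    paths$sweep <- file.path(out_dir, "sd_sweep.csv")
    readr::write_csv(as_tibble(sweep), paths$sweep)
  }
  jsonlite::write_json(
    list(stage = "sensitivity", config = config, config_hash = hash,
         n_channels = nrow(chans), wavelength_nm = wl),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wb_log("info", "sensitivity products written to ", out_dir)
  invisible(list(summary = sens$summary, sweep = sweep, max_map = max_map,
                 paths = paths))
}

#' Run the session stage: processing and event-related statistics
#'
#' Loads (or simulates) a session, runs the canonical processing chain and
#' the event-related statistics, and writes tidy CSVs plus a JSON report
#' echoing all parameters and the config hash.
#'
#' @param config See [validate_run_config()]; keys: `simulate` + `seed`
#'   (or `absorbance_csv` + `events_csv` + `path_lengths_csv`),
#'   `filter_order`, `cutoff_hz`, `detrend`, `window_s`, `alpha`,
#'   `n_trials`, `restraint`, `noise`, `drift`, `out_dir` (required).
#' @return List with the result tables and output paths.
#' @export
run_session <- function(config) {
  config <- validate_run_config(config, "session")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  filter_order <- config$filter_order %||% 4
  cutoff_hz <- config$cutoff_hz %||% 0.7
  window <- config$window_s %||% c(-2, 15)
  alpha <- config$alpha %||% 0.05
  if (isTRUE(config$simulate)) {
    if (is.null(config$seed)) abort("simulate = true requires a seed")
    sc_args <- list()
    if (!is.null(config$n_trials)) sc_args$n_trials <- config$n_trials
    if (!is.null(config$restraint)) sc_args$restraint <- config$restraint
    sc <- do.call(sim_config, sc_args)
    wb_log("info", "simulating session (seed ", config$seed, ")")
    ses <- simulate_session(sc, config$seed,
                            noise = config$noise %||% TRUE,
                            drift = config$drift %||% TRUE)
    absorbance <- ses$absorbance
    events <- ses$events
    path_lengths <- ses$path_lengths
    channels <- ses$channels
  } else {
    for (key in c("absorbance_csv", "events_csv", "path_lengths_csv")) {
      if (is.null(config[[key]])) {
        abort(paste0("without simulate = true, config needs '", key, "'"))
      }
      if (!file.exists(config[[key]])) {
        abort(paste0("input file not found: ", config[[key]]))
      }
    }
    absorbance <- readr::read_csv(config$absorbance_csv,
                                  show_col_types = FALSE)
    events <- readr::read_csv(config$events_csv, show_col_types = FALSE)
    path_lengths <- readr::read_csv(config$path_lengths_csv,
                                    show_col_types = FALSE)
    channels <- assign_regions(enumerate_channels(paper_layout()),
                               paper_region_table())
  }
  need <- distinct(absorbance, .data$channel, .data$wavelength_nm)
  miss <- dplyr::anti_join(need, path_lengths,
                           by = c("channel", "wavelength_nm"))
  if (nrow(miss) > 0) {
    abort(paste0("path lengths missing for channel(s): ",
                 paste(unique(miss$channel), collapse = ", ")))
  }
  wb_log("info", "processing absorbance (order ", filter_order,
         " Butterworth at ", cutoff_hz, " Hz)")
  hb <- process_absorbance(absorbance, path_lengths,
                           filter_order = filter_order,
                           cutoff_hz = cutoff_hz,
                           detrend = config$detrend %||% TRUE)
  block <- epoch_and_average(hb, events, window = window)
  results <- list(hb = hb, block = block)
  if (length(unique(events$hand)) == 2) {
    tc <- paired_t_curve(hb, events, window = window)
    results$t_curves <- tc
    results$peaks <- peak_metrics(block, tc, alpha = alpha)
  }
  results$hbo_hbr <- hbo_hbr_correlation(block)
  hash <- rlang::hash(config)
  paths <- list(block = file.path(out_dir, "block_averages.csv"),
                events = file.path(out_dir, "events.csv"),
                hbo_hbr = file.path(out_dir, "hbo_hbr_correlation.csv"),
                report = file.path(out_dir, "session_report.json"))
  readr::write_csv(block, paths$block)
  readr::write_csv(events, paths$events)
  readr::write_csv(results$hbo_hbr, paths$hbo_hbr)
  if (!is.null(results$t_curves)) {
    paths$t_curves <- file.path(out_dir, "t_curves.csv")
    paths$peaks <- file.path(out_dir, "peak_metrics.csv")
    readr::write_csv(results$t_curves, paths$t_curves)
    readr::write_csv(results$peaks, paths$peaks)
  }
  report <- list(stage = "session", config = config, config_hash = hash,
                 parameters = list(filter_order = filter_order,
                                   cutoff_hz = cutoff_hz,
                                   detrend = config$detrend %||% TRUE,
                                   window_s = window, alpha = alpha),
                 n_trials = nrow(events),
                 n_channels = length(unique(absorbance$channel)))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  wb_log("info", "session results written to ", out_dir)
  invisible(c(results, list(paths = paths, report = report)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
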