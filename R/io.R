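#' Write / read a trajectory as a delimited text table
#'
#' Plain-text comma-separated table with header
#' `t,PY,IN1,IN2,TC,RE,mean`, one row per integration step. The reader
#' restores an `swd_trajectory` (round trip up to the printed precision).
#'
#' @param traj an `swd_trajectory`.
#' @param path output file.
#' @param digits significant digits written.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns an `swd_trajectory`.
#' @export
write_trajectory <- function(traj, path, digits = 10) {
  stopifnot(inherits(traj, "swd_trajectory"))
  df <- as.data.frame(traj)
  df[] <- lapply(df, signif, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "PY", "IN1", "IN2", "TC", "RE", "mean")
  if (!all(need %in% names(df)))
    stop("not a trajectory table: expected columns ", paste(need, collapse = ","))
  st <- as.matrix(df[, c("PY", "IN1", "IN2", "TC", "RE")])
  dt <- if (nrow(df) > 1) df$t[2] - df$t[1] else NA_real_
  structure(list(time = df$t, state = st, mean = df$mean, dt = dt,
                 transient = NA_real_, config = NULL),
            class = "swd_trajectory")
}

#' Write a scan or map table
#'
#' One row per cell (parameter values, label, frequency, amplitude, ...),
#' as a plain CSV.
#'
#' @param x a data frame (`swd_scan`, `swd_map`, or similar).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

preset_file <- function(path = NULL) {
  if (!is.null(path)) return(path)
  system.file("extdata", "presets.yaml", package = "swdfield", mustWork = TRUE)
}

#' Names of shipped parameter presets
#'
#' @param path optional presets file (defaults to the shipped one).
#' @return Character vector of preset names.
#' @export
preset_names <- function(path = NULL) {
  names(yaml::read_yaml(preset_file(path))$presets)
}

#' Load a parameter preset
#'
#' Reads a named preset from the shipped configuration document (nested
#' key-value sections `model` / `stimulus` / `simulation`) and returns the
#' ready-to-use objects. The preset `"taylor2016-default"` carries the
#' published reference constants.
#'
#' @param name preset name.
#' @param path optional presets file.
#' @return List: `params` ([field_params()]), `config` ([sim_config()]),
#'   `stimulus` (list of reference stimulation settings).
#' @export
load_preset <- function(name = "taylor2016-default", path = NULL) {
  doc <- yaml::read_yaml(preset_file(path))$presets
  if (!name %in% names(doc))
    stop("unknown preset '", name, "'; available: ",
         paste(names(doc), collapse = ", "))
  pr <- doc[[name]]
  params <- do.call(set_params, c(list(field_params()), pr$model))
  cfg <- sim_config(dt = pr$simulation$dt, duration = pr$simulation$duration,
                    transient = pr$simulation$transient,
                    initial_state = unlist(pr$simulation$initial_state))
  list(params = params, config = cfg, stimulus = pr$stimulus,
       version = pr$version)
}

#' Write a run directory with manifest
#'
#' Serialises a set of named outputs (trajectories, scans/maps as data
#' frames) together with a config sidecar, a log, and a manifest listing
#' every file with its MD5 checksum. The pipeline is fully deterministic
#' (no random numbers anywhere), so re-running a job from its sidecar
#' reproduces byte-identical tables.
#'
#' @param outputs named list of `swd_trajectory` and/or data-frame objects
#'   (may be empty).
#' @param dir output directory (created if needed).
#' @param config list serialised as the YAML sidecar (grids, timings,
#'   thresholds, preset name, ...).
#' @param log character lines appended to the run log.
#' @return Data frame manifest (`file`, `md5`), invisibly written to
#'   `manifest.csv` as well.
#' @export
write_run <- function(outputs = list(), dir, config = list(), log = character()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  files <- character(0)
  for (nm in names(outputs)) {
    obj <- outputs[[nm]]
    f <- file.path(dir, paste0(nm, ".csv"))
    if (inherits(obj, "swd_trajectory")) write_trajectory(obj, f)
    else if (is.data.frame(obj)) write_scan(obj, f)
    else stop("unsupported output object '", nm, "'")
    files <- c(files, f)
  }
  cfg_file <- file.path(dir, "config.yaml")
  yaml::write_yaml(c(list(tool = "swdfield",
                          version = as.character(utils::packageVersion("swdfield")),
                          deterministic = TRUE),
                     config), cfg_file)
  log_file <- file.path(dir, "run.log")
  writeLines(c(paste("swdfield", utils::packageVersion("swdfield")),
               paste("outputs:", length(outputs)), log), log_file)
  files <- c(files, cfg_file, log_file)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
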