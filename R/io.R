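# Readers and writers for the delimited-text interchange formats, JSON
# configs, and run manifests. All files are comma-separated UTF-8 with a
# mandatory header row; times are seconds, concentrations micromolar.

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty file: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  num <- setdiff(required, c("worm_id", "neuron"))
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric or missing values in column `", col, "` of ", path,
           " at row(s) ", paste(utils::head(bad, 10), collapse = ", "))
    df[[col]] <- v
  }
  df
}

#' Read calcium traces from a delimited table
#'
#' Expects columns `worm_id`, `neuron`, `time_s`, `value`; rows are grouped
#' by (worm, neuron) and time-sorted into [calcium_trace()] objects.
#' Non-uniform sampling is resampled with a warning; missing or non-numeric
#' values are an error naming the offending rows.
#'
#' @param path CSV file path.
#' @return Named list of [calcium_trace()] objects (`worm_id.neuron`).
#' @export
read_traces <- function(path) {
  df <- read_table_checked(path, c("worm_id", "neuron", "time_s", "value"))
  key <- paste(df$worm_id, df$neuron, sep = ".")
  out <- lapply(split(df, key), function(g)
    calcium_trace(g$worm_id[1], g$neuron[1], g$time_s, g$value))
  out[order(names(out))]
}

#' Write calcium traces to a delimited table
#'
#' @param traces A [calcium_trace()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "calcium_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(worm_id = tr$worm_id, neuron = tr$neuron,
               time_s = tr$times, value = tr$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a stimulus profile
#'
#' Column layout `time_s`, `conc_uM` and optionally `d1`, `d2`.
#'
#' @param path CSV file path.
#' @return A [stimulus_profile()].
#' @export
read_profile <- function(path) {
  df <- read_table_checked(path, c("time_s", "conc_uM"))
  stimulus_profile(df$time_s, df$conc_uM, d1 = df$d1, d2 = df$d2)
}

#' @rdname read_profile
#' @param profile A [stimulus_profile()].
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a trajectory (positions plus a JSON sidecar for the target)
#'
#' The CSV holds `time_s`, `x_mm`, `y_mm`; the target coordinate lives in a
#' JSON sidecar `<path>.json` (`{"target": [x, y]}`).
#'
#' @param path CSV file path.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  df <- read_table_checked(path, c("time_s", "x_mm", "y_mm"))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing target sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  trajectory(df$time_s, df$x_mm, df$y_mm, meta$target)
}

#' @rdname read_trajectory
#' @param traj A [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(time_s = traj$times, x_mm = traj$x,
                              y_mm = traj$y),
                   path, row.names = FALSE)
  jsonlite::write_json(list(target = traj$target), paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read or write a JSON configuration
#'
#' @param path JSON file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run manifest for reproducible analyses
#'
#' Records the package version, a hash of the configuration, the master
#' seed, and the declared input/output paths; rerunning with an identical
#' manifest reproduces deterministic outputs bitwise and stochastic outputs
#' distributionally.
#'
#' @param config Named list of run parameters.
#' @param seed Master integer seed.
#' @param inputs,outputs Character vectors of file paths.
#' @param path Optional path; when given the manifest is written there as
#'   JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, seed, inputs = character(0),
                         outputs = character(0), path = NULL) {
  m <- list(tool = "pulsetaxis",
            version = as.character(utils::packageVersion("pulsetaxis")),
            config_hash = config_hash(config),
            seed = seed,
            inputs = inputs, outputs = outputs,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(m))
  }
  m
}

# Order-insensitive hash of a config list (names sorted recursively).
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  json <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash; stable across sessions, no extra dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
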