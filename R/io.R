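#' Write/read an inertial recording as CSV plus JSON sidecar
#'
#' CSV columns are `time,gx,gy,gz,ax,ay,az`; the sidecar (same path with
#' `.json` appended) records the sampling rate, placement and axis
#' convention.
#'
#' @param rec an [imu_recording()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  d <- data.frame(time = rec$t, gx = rec$gyro[, 1], gy = rec$gyro[, 2],
                  gz = rec$gyro[, 3], ax = rec$accel[, 1],
                  ay = rec$accel[, 2], az = rec$accel[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, placement = rec$placement,
                            axis_convention = rec$axis_convention),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @param path CSV path written by [write_imu_csv()].
#' @export
read_imu_csv <- function(path) {
  d <- read_checked(path, c("time", "gx", "gy", "gz", "ax", "ay", "az"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  imu_recording(meta$fs, d$time,
                as.matrix(d[, c("gx", "gy", "gz")]),
                as.matrix(d[, c("ax", "ay", "az")]),
                meta$placement, meta$axis_convention)
}

#' Write/read a skeleton recording as long-format CSV
#'
#' Columns: `time,body_id,joint,x,y,z`.
#'
#' @param rec a `skeleton_recording`.
#' @param path CSV path.
#' @export
write_skeleton_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec)[, c("time", "body_id", "joint",
                                          "x", "y", "z")],
                   path, row.names = FALSE)
  jsonlite::write_json(list(fps = attr(rec, "fps")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_skeleton_csv
#' @export
read_skeleton_csv <- function(path) {
  d <- read_checked(path, c("time", "body_id", "joint", "x", "y", "z"))
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json")) else list(fps = 30)
  structure(d, class = c("skeleton_recording", "data.frame"),
            fps = meta$fps)
}

#' Write/read ground-truth or detected events as CSV
#'
#' Ground-truth columns: `time,foot,kind,pass,step_length,position`;
#' detected event-series CSVs use `modality,foot,kind,time`.
#'
#' @param events a `gait_events` data frame.
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- read_checked(path, c("time", "foot", "kind", "pass"))
  class(d) <- c("gait_events", "data.frame")
  pw <- do.call(rbind, lapply(split(d, d$pass), function(g)
    data.frame(pass = g$pass[1], start = min(g$time), end = max(g$time))))
  rownames(pw) <- NULL
  attr(d, "pass_windows") <- pw
  d
}

#' Write an event series list as CSV (`modality,foot,kind,time`)
#' @param series a list of [event_series()] objects.
#' @param path CSV path.
#' @export
write_event_series_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) rbind(
    if (length(s$hs)) data.frame(modality = s$modality, foot = s$foot,
                                 kind = "HS", time = s$hs),
    if (length(s$to)) data.frame(modality = s$modality, foot = s$foot,
                                 kind = "TO", time = s$to))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write/read a trigger channel as CSV (`time,level`)
#' @param sync a `sync_signal`.
#' @param path CSV path.
#' @export
write_trigger_csv <- function(sync, path) {
  utils::write.csv(data.frame(time = (seq_along(sync$level) - 1) / sync$fs,
                              level = sync$level),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trigger_csv
#' @export
read_trigger_csv <- function(path) {
  d <- read_checked(path, c("time", "level"))
  fs <- 1 / stats::median(diff(d$time))
  structure(list(fs = round(fs), level = d$level), class = "sync_signal")
}

read_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")))
  d
}

#' Deterministic hash of a configuration object
#'
#' MD5 of the canonical (sorted-key) JSON serialisation; used to name run
#' directories and assert rerun determinism.
#'
#' @param config a JSON-serialisable list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(sort_names(config),
                                           auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

sort_names <- function(x) {
  if (is.list(x) && !is.null(names(x)))
    lapply(x[order(names(x))], sort_names)
  else x
}
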