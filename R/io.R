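# Plain-text interchange formats. Behavior, events and labels travel as
# CSV (data.table); a NeuronMatrix is a directory bundle of CSV matrices
# plus a JSON header, so every artifact stays human-inspectable and
# diff-able.

#' Write / read a behavior table
#'
#' Columns: `t_s`, `speed_mm_s`, `left_eye_rad`, `right_eye_rad`, and
#' optionally `heading_rad`, `roll_rad`, `pitch_rad`.
#'
#' @param behavior a `synth_behavior` or a data.frame with those columns
#' @param path CSV path
#' @return `read_behavior_csv` returns a list with `trace`
#'   (`eye_angle_trace`), `speed` data.frame and any extra columns
#' @export
write_behavior_csv <- function(behavior, path) {
  df <- if (inherits(behavior, "synth_behavior")) {
    data.frame(t_s = behavior$trace$t_s,
               speed_mm_s = behavior$speed$speed_mm_s,
               left_eye_rad = behavior$trace$left_rad,
               right_eye_rad = behavior$trace$right_rad)
  } else as.data.frame(behavior)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("t_s", "speed_mm_s", "left_eye_rad", "right_eye_rad")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("behavior CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  fs <- 1 / median(diff(df$t_s))
  list(trace = eye_angle_trace(df$t_s, df$left_eye_rad, df$right_eye_rad,
                               round(fs, 6)),
       speed = df[, c("t_s", "speed_mm_s")],
       extra = df[, setdiff(names(df), need), drop = FALSE])
}

#' Write / read a neuron matrix bundle
#'
#' A directory holding `F.csv` (neurons x time, empty cells where
#' unobserved), `centroids_um.csv`, `regions.csv` and `meta.json`.
#'
#' @param nm a `neuron_matrix`
#' @param dir bundle directory (created if needed)
#' @return `read_neuron_bundle` returns a `neuron_matrix`
#' @export
write_neuron_bundle <- function(nm, dir) {
  stopifnot(inherits(nm, "neuron_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  F <- nm$F; F[!nm$mask] <- NA_real_
  data.table::fwrite(as.data.frame(F), file.path(dir, "F.csv"),
                     col.names = FALSE)
  data.table::fwrite(as.data.frame(nm$centroids_um),
                     file.path(dir, "centroids_um.csv"))
  data.table::fwrite(data.frame(region = nm$regions),
                     file.path(dir, "regions.csv"))
  jsonlite::write_json(list(fs_hz = nm$fs_hz, n_neurons = nrow(F),
                            n_time = ncol(F)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_neuron_bundle
#' @export
read_neuron_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  F <- as.matrix(data.table::fread(file.path(dir, "F.csv"), header = FALSE,
                                   data.table = FALSE))
  dimnames(F) <- NULL
  cen <- as.matrix(data.table::fread(file.path(dir, "centroids_um.csv"),
                                     data.table = FALSE))
  reg <- data.table::fread(file.path(dir, "regions.csv"),
                           data.table = FALSE)$region
  neuron_matrix(F, mask = !is.na(F), fs_hz = meta$fs_hz,
                centroids_um = cen, regions = reg)
}

#' Write a scored saccade-event table
#' @param events data.frame from [score_kinematics()]
#' @param path CSV path
#' @export
write_events_csv <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' Write a state label series
#' @param labels data.frame from [label_series()]
#' @param path CSV path
#' @export
write_labels_csv <- function(labels, path) {
  data.table::fwrite(labels, path)
  invisible(path)
}

#' @rdname write_labels_csv
#' @param path CSV path
#' @export
read_labels_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("start_s", "end_s", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("label CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}
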