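# Per-substate saccade kinematics. The QEM presets carry the published
# per-state values for saccade rate, fixation duration, decay slope and peak
# speed; see the methods vignette for the provenance of the free parameters
# (amplitude, regularity, inter-saccade timing model).

#' Construct a substate kinematics preset
#'
#' Describes the saccade process of one quiescent substate: how often
#' conjugate saccades occur, how fast they are, and how the post-saccadic
#' fixation evolves. Means and SDs are on the printed (degree/second) scales.
#'
#' @param rate_per_min mean saccades per minute (0 for QNEM: no saccades)
#' @param fixation_s mean/sd of fixation duration in seconds
#' @param decay_slope_deg_s mean/sd of the post-saccadic decay slope (deg/s)
#' @param peak_speed_deg_s mean/sd of saccade peak angular speed (deg/s)
#' @param amplitude_deg mean/sd of the saccadic flight amplitude (deg)
#' @param regularity in `[0, 1]`: 0 gives Poisson-like (exponential) saccade
#'   timing, 1 clock-like (fixed) intervals
#' @return object of class `substate_kinematics`
#' @export
substate_kinematics <- function(rate_per_min,
                                fixation_s = c(5, 2),
                                decay_slope_deg_s = c(0.3, 0.2),
                                peak_speed_deg_s = c(849.1, 158.7),
                                amplitude_deg = c(45, 5),
                                regularity = 0.5) {
  stopifnot(rate_per_min >= 0, regularity >= 0, regularity <= 1)
  as2 <- function(v) if (length(v) == 1L) c(v, 0) else v[1:2]
  k <- list(rate_per_min = rate_per_min,
            fixation_s = as2(fixation_s),
            decay_slope_deg_s = as2(decay_slope_deg_s),
            peak_speed_deg_s = as2(peak_speed_deg_s),
            amplitude_deg = as2(amplitude_deg),
            regularity = regularity)
  if (any(vapply(k[2:5], function(v) v[1] < 0, logical(1))))
    stop("kinematic means must be >= 0")
  structure(k, class = "substate_kinematics")
}

#' Default per-substate kinematic presets
#'
#' Returns the shipped presets for the four quiescent substates (and a Wake
#' placeholder). QEM-1 has frequent, temporally regular saccades with short
#' fixations and shallow decay; QEM-2 sparse saccades with steep decay;
#' QEM-3 sparse saccades with long, static fixations; QNEM no saccades.
#' Values are loaded from the JSON preset file shipped with the package
#' (`inst/extdata/kinematic_presets.json`).
#'
#' @param path optional path to an alternative JSON preset file
#' @return named list of `substate_kinematics` (QNEM entry has rate 0)
#' @export
default_kinematics <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "kinematic_presets.json", package = "sleepscope")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(p) {
    substate_kinematics(rate_per_min = p$rate_per_min,
                        fixation_s = unlist(p$fixation_s),
                        decay_slope_deg_s = unlist(p$decay_slope_deg_s),
                        peak_speed_deg_s = unlist(p$peak_speed_deg_s),
                        amplitude_deg = unlist(p$amplitude_deg),
                        regularity = p$regularity)
  })
  out
}

STATE_LEVELS <- c("Wake", "QEM1", "QEM2", "QEM3", "QNEM", "Unlabeled")
SLEEP_STATES <- c("QEM1", "QEM2", "QEM3", "QNEM")
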