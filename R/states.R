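# Sleep-period detection, 1-min binning, bin features, substate labeling,
# occupancy and startle-response statistics.

#' Detect sleep periods from a speed trace
#'
#' Sleep is locomotor quiescence: the 5-s rolling-average speed stays below
#' 0.5 mm/s for at least one minute.
#'
#' @param speed_mm_s numeric speed series in mm/s (uniform sampling)
#' @param fs_hz sample rate of the speed series
#' @param threshold_mm_s speed threshold (default 0.5)
#' @param roll_win_s rolling-average window (default 5 s)
#' @param min_dur_s minimum period duration (default 60 s)
#' @return data.frame with `start_s`, `end_s` (one row per sleep period)
#' @export
detect_sleep <- function(speed_mm_s, fs_hz, threshold_mm_s = 0.5,
                         roll_win_s = 5, min_dur_s = 60) {
  roll <- running_mean(speed_mm_s, round(roll_win_s * fs_hz))
  runs <- true_runs(roll < threshold_mm_s)
  if (!nrow(runs)) return(data.frame(start_s = numeric(), end_s = numeric()))
  dur <- (runs$end - runs$start + 1L) / fs_hz
  keep <- dur >= min_dur_s
  data.frame(start_s = (runs$start[keep] - 1L) / fs_hz,
             end_s = runs$end[keep] / fs_hz)
}

#' Divide a sleep period into 1-minute bins
#'
#' Consecutive 60-s bins; a terminal remainder of at most 30 s is merged
#' into the preceding bin, a remainder in (30, 60) s becomes its own bin.
#'
#' @param start_s,end_s period bounds in seconds (end - start >= 60)
#' @param bin_s nominal bin length (default 60)
#' @param merge_max_s maximal terminal remainder that is merged (default 30)
#' @return data.frame with `start_s`, `end_s` per bin
#' @export
bin_period <- function(start_s, end_s, bin_s = 60, merge_max_s = 30) {
  dur <- end_s - start_s
  stopifnot(dur >= bin_s)
  n_full <- floor(dur / bin_s)
  rem <- dur - n_full * bin_s
  starts <- start_s + bin_s * seq_len(n_full) - bin_s
  ends <- starts + bin_s
  if (rem > 1e-9) {
    if (rem <= merge_max_s) ends[n_full] <- end_s
    else { starts <- c(starts, ends[n_full]); ends <- c(ends, end_s) }
  }
  data.frame(start_s = starts, end_s = ends)
}

#' Per-bin saccade features
#'
#' Saccade count, mean decay slope and mean fixation duration of the
#' accepted saccades whose onset falls in each bin. Censored fixations
#' enter at their censored value. Bins without saccades carry NA kinematic
#' means (they are QNEM-eligible).
#'
#' @param bins data.frame with `start_s`, `end_s` (from [bin_period()])
#' @param events scored saccades (from [score_kinematics()])
#' @return data.frame: bin bounds plus `count`, `mean_slope_deg_s`,
#'   `mean_fixation_s`
#' @export
featurize <- function(bins, events) {
  out <- bins
  out$count <- 0L
  out$mean_slope_deg_s <- NA_real_
  out$mean_fixation_s <- NA_real_
  for (i in seq_len(nrow(bins))) {
    in_bin <- events$onset_s >= bins$start_s[i] & events$onset_s < bins$end_s[i]
    k <- sum(in_bin)
    out$count[i] <- k
    if (k > 0L) {
      out$mean_slope_deg_s[i] <- mean(events$decay_slope_deg_s[in_bin])
      out$mean_fixation_s[i] <- mean(events$fixation_s[in_bin])
    }
  }
  out
}

#' Occupancy fractions of a label series
#'
#' Per window, the fraction of time in each state, both of total time and
#' of sleep time (excluding Wake and Unlabeled).
#'
#' @param labels data.frame with `start_s`, `end_s`, `label` per bin
#'   (a `state_label_series`, see [classify_bins()])
#' @param windows data.frame with `start_s`, `end_s` (default: one window
#'   spanning the labels)
#' @return data.frame: one row per window and state with `frac_total`,
#'   `frac_sleep`
#' @export
compute_occupancy <- function(labels, windows = NULL) {
  if (is.null(windows))
    windows <- data.frame(start_s = min(labels$start_s),
                          end_s = max(labels$end_s))
  res <- list()
  for (w in seq_len(nrow(windows))) {
    lo <- windows$start_s[w]; hi <- windows$end_s[w]
    s <- pmax(labels$start_s, lo); e <- pmin(labels$end_s, hi)
    dur <- pmax(e - s, 0)
    if (sum(dur) <= 0) {
      res[[w]] <- data.frame(window = w, state = STATE_LEVELS,
                             frac_total = NA_real_, frac_sleep = NA_real_)
      next
    }
    tot <- tapply(dur, factor(labels$label, STATE_LEVELS), sum, default = 0)
    tot[is.na(tot)] <- 0
    sleep_t <- sum(tot[SLEEP_STATES])
    res[[w]] <- data.frame(
      window = w, state = STATE_LEVELS,
      frac_total = as.numeric(tot / sum(tot)),
      frac_sleep = ifelse(STATE_LEVELS %in% SLEEP_STATES,
                          if (sleep_t > 0) as.numeric(tot / sleep_t) else NA_real_,
                          NA_real_))
  }
  do.call(rbind, res)
}

#' Startle-response probability per pre-stimulus state
#'
#' A trial is responsive if the response series crosses the rule's
#' threshold within 1 s after the stimulus: relative tail angle amplitude
#' above 180 degrees (dark-flash assay) or instantaneous speed above
#' 150 mm/s (mechano-acoustic tap assay). Trials are grouped by the state
#' label at stimulus time; trials during Unlabeled bins (or outside the
#' recording) are dropped.
#'
#' @param stim_t_s stimulus times in seconds
#' @param response numeric response series (tail angle in degrees, or speed
#'   in mm/s)
#' @param fs_hz sample rate of `response`
#' @param rule `"tail_angle_gt_180deg"` or `"speed_gt_150mm_s"`
#' @param labels a label series (`start_s`, `end_s`, `label`)
#' @param window_s response window after the stimulus (default 1 s)
#' @return data.frame per state: `n_trials`, `n_responsive`, `probability`
#' @export
startle_response_probability <- function(stim_t_s, response, fs_hz,
                                         rule = c("tail_angle_gt_180deg",
                                                  "speed_gt_150mm_s"),
                                         labels, window_s = 1) {
  rule <- match.arg(rule)
  thr <- if (rule == "tail_angle_gt_180deg") 180 else 150
  n <- length(response)
  states <- setdiff(STATE_LEVELS, "Unlabeled")
  tally <- matrix(0L, length(states), 2L,
                  dimnames = list(states, c("n_trials", "n_responsive")))
  for (t0 in stim_t_s) {
    i0 <- floor(t0 * fs_hz) + 1L
    i1 <- floor((t0 + window_s) * fs_hz) + 1L
    if (i0 < 1L || i1 > n) { warning("stimulus outside recording dropped"); next }
    lab <- labels$label[labels$start_s <= t0 & labels$end_s > t0]
    if (!length(lab) || lab[1] == "Unlabeled") next
    responsive <- any(abs(response[i0:i1]) > thr)
    tally[lab[1], 1L] <- tally[lab[1], 1L] + 1L
    tally[lab[1], 2L] <- tally[lab[1], 2L] + responsive
  }
  data.frame(state = states, n_trials = tally[, 1L],
             n_responsive = tally[, 2L],
             probability = ifelse(tally[, 1L] > 0,
                                  tally[, 2L] / tally[, 1L], NA_real_))
}
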