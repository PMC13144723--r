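# Conjugate-saccade detection and kinematic scoring.
#
# Chain: detrend (200-s running mean subtracted) -> 1.5-s running median ->
# fused-lasso (exact 1-D total-variation) denoising, lambda = 0.25 ->
# candidate peaks in the product of left/right eye velocities ->
# interocular-correlation and residual-noise selection -> kinematic scoring
# (decay slope, fixation duration, peak speed) on the raw trace.

#' Construct a paired eye-angle trace
#'
#' @param t_s time grid in seconds (must be uniform)
#' @param left_rad,right_rad eye angles in radians (NAs are linearly
#'   interpolated on ingest)
#' @param fs_hz sample rate in Hz
#' @return object of class `eye_angle_trace`
#' @export
eye_angle_trace <- function(t_s, left_rad, right_rad, fs_hz) {
  stopifnot(length(t_s) == length(left_rad),
            length(t_s) == length(right_rad), fs_hz > 0)
  if (length(t_s) > 1L) {
    dts <- diff(t_s)
    if (max(abs(dts - 1 / fs_hz)) > 1e-6 / fs_hz)
      stop("t_s must be a uniform grid at fs_hz")
  }
  structure(list(t_s = t_s, left_rad = interp_na(left_rad),
                 right_rad = interp_na(right_rad), fs_hz = fs_hz),
            class = "eye_angle_trace")
}

#' Preprocess an eye-angle trace for saccade detection
#'
#' Subtracts a 200-s running mean (slow-drift baseline), smooths with a
#' 1.5-s running median, then applies exact fused-lasso (total-variation)
#' denoising to obtain a piecewise-constant signal. The residual series
#' (detrended minus denoised) is retained for the noise-based selection
#' criterion.
#'
#' @param trace an `eye_angle_trace`
#' @param lambda fused-lasso penalty per sample (default 0.25; 0 disables)
#' @param mean_win_s running-mean window in seconds (default 200)
#' @param median_win_s running-median window in seconds (default 1.5)
#' @return object of class `filtered_trace` with per-eye `detrended`,
#'   `denoised` and `residual` series; `residual + denoised == detrended`
#'   exactly
#' @export
preprocess <- function(trace, lambda = 0.25, mean_win_s = 200,
                       median_win_s = 1.5) {
  stopifnot(inherits(trace, "eye_angle_trace"))
  fs <- trace$fs_hz
  k_med <- odd_window(median_win_s * fs)
  if (length(trace$t_s) <= k_med)
    stop("trace shorter than the median-filter window")
  one_eye <- function(x) {
    det <- x - running_mean(x, round(mean_win_s * fs))
    med <- as.numeric(runmed(det, k_med, endrule = "median"))
    den <- tv1d_denoise(med, lambda)
    list(detrended = det, denoised = den, residual = det - den)
  }
  L <- one_eye(trace$left_rad)
  R <- one_eye(trace$right_rad)
  structure(list(t_s = trace$t_s, fs_hz = fs,
                 left = L, right = R, lambda = lambda),
            class = "filtered_trace")
}

#' Exact 1-D total-variation (fused lasso) denoising
#'
#' Returns the exact minimizer of
#' \deqn{\tfrac12 \sum_i (y_i - \beta_i)^2 + \lambda \sum_i |\beta_{i+1} - \beta_i|}
#' computed with a direct (non-iterative) algorithm.
#'
#' @param y numeric vector
#' @param lambda penalty, >= 0
#' @return numeric vector of the same length
#' @export
tv1d_denoise <- function(y, lambda) {
  stopifnot(lambda >= 0, is.numeric(y))
  if (lambda == 0 || length(y) < 2L) return(as.numeric(y))
  tv1d_denoise_cpp(as.numeric(y), lambda)
}

#' Detect conjugate-saccade candidates
#'
#' Local maxima of the product of left and right denoised eye velocities
#' exceeding a threshold, greedily pruned so surviving peaks are at least
#' `min_isi_s` apart (larger peak kept).
#'
#' @param filtered a `filtered_trace`
#' @param threshold_rad2_s2 velocity-product threshold; 0.60 for the
#'   multi-animal rig, 0.32 for the single-animal rig
#' @param min_isi_s minimum inter-saccade interval in seconds (default 1.5)
#' @return data.frame with `idx`, `t_s`, `peak_product`
#' @export
detect_candidates <- function(filtered, threshold_rad2_s2 = 0.60,
                              min_isi_s = 1.5) {
  stopifnot(inherits(filtered, "filtered_trace"))
  if (threshold_rad2_s2 <= 0) stop("threshold must be > 0")
  fs <- filtered$fs_hz
  vL <- central_diff(filtered$left$denoised, fs)
  vR <- central_diff(filtered$right$denoised, fs)
  p <- vL * vR
  n <- length(p)
  if (n < 3L) return(data.frame(idx = integer(), t_s = numeric(),
                                peak_product = numeric()))
  is_max <- c(FALSE, p[2:(n - 1L)] >= p[1:(n - 2L)] &
                p[2:(n - 1L)] >= p[3:n], FALSE) & p > threshold_rad2_s2
  idx <- which(is_max)
  if (!length(idx)) return(data.frame(idx = integer(), t_s = numeric(),
                                      peak_product = numeric()))
  # greedy pruning: strongest first, suppress within min_isi
  ord <- idx[order(p[idx], decreasing = TRUE)]
  min_gap <- round(min_isi_s * fs)
  kept <- integer()
  for (i in ord) if (!length(kept) || all(abs(kept - i) >= min_gap))
    kept <- c(kept, i)
  kept <- sort(kept)
  data.frame(idx = kept, t_s = filtered$t_s[kept], peak_product = p[kept])
}

#' Select saccades by interocular correlation and residual noise
#'
#' A candidate is accepted iff the rolling interocular Pearson correlation
#' of the denoised traces in a `corr_win_s` window centered on the peak
#' exceeds `corr_min`, and the rolling mean absolute fused-lasso residual
#' (both eyes pooled) over `resid_win_s` is below `resid_max_rad`.
#'
#' @param candidates output of [detect_candidates()]
#' @param filtered the `filtered_trace`
#' @param corr_win_s correlation window (default 5 s)
#' @param corr_min correlation threshold (default 0.5)
#' @param resid_win_s residual window (default 15 s)
#' @param resid_max_rad residual threshold in radians (default 0.45)
#' @return data.frame of all candidates with `accepted`, `reason`
#'   (`"correlation"` or `"residual"` for rejects), `interocular_corr`,
#'   `resid_mean_rad`
#' @export
select_saccades <- function(candidates, filtered, corr_win_s = 5,
                            corr_min = 0.5, resid_win_s = 15,
                            resid_max_rad = 0.45) {
  stopifnot(inherits(filtered, "filtered_trace"))
  fs <- filtered$fs_hz
  n <- length(filtered$t_s)
  if (round(corr_win_s * fs) > n || round(resid_win_s * fs) > n)
    stop("selection window longer than trace")
  if (!nrow(candidates)) {
    out <- candidates
    out$interocular_corr <- numeric(0)
    out$resid_mean_rad <- numeric(0)
    out$accepted <- logical(0)
    out$reason <- character(0)
    return(out)
  }
  resid_roll <- running_abs_mean(
    (abs(filtered$left$residual) + abs(filtered$right$residual)) / 2,
    round(resid_win_s * fs))
  half_c <- round(corr_win_s * fs / 2)
  out <- candidates
  out$interocular_corr <- NA_real_
  out$resid_mean_rad <- NA_real_
  out$accepted <- logical(nrow(out))
  out$reason <- NA_character_
  for (j in seq_len(nrow(out))) {
    i <- out$idx[j]
    lo <- max(1L, i - half_c); hi <- min(n, i + half_c)
    a <- filtered$left$denoised[lo:hi]; b <- filtered$right$denoised[lo:hi]
    r <- if (sd(a) < 1e-12 || sd(b) < 1e-12) 0 else cor(a, b)
    out$interocular_corr[j] <- r
    out$resid_mean_rad[j] <- resid_roll[i]
    if (r <= corr_min) {
      out$reason[j] <- "correlation"
    } else if (resid_roll[i] >= resid_max_rad) {
      out$reason[j] <- "residual"
    } else out$accepted[j] <- TRUE
  }
  out
}

#' Score saccade kinematics on the raw trace
#'
#' For each accepted candidate: the velocity peak is located on the raw
#' binocular velocity within +/- `search_s` of the candidate; onset is the
#' last sample before the peak with |v| below `vel_frac` of the peak
#' velocity, offset the first such sample after it. Per eye, the baseline is
#' the median angle over 1 s pre-onset, the post-saccadic amplitude A is the
#' offset angle minus baseline, the decay slope is the absolute OLS slope of
#' the raw angle from offset to the first crossing of baseline + 0.33 A, and
#' the fixation duration is the time from offset to that crossing. Events
#' whose crossing is not reached before the next accepted saccade (or the
#' quiescent-period/trace end) are censored there. Binocular values are the
#' mean of the two eyes; peak speed is reported in deg/s.
#'
#' @param selected output of [select_saccades()]
#' @param trace the raw `eye_angle_trace`
#' @param search_s half-width of the raw-peak search window (default 0.5 s)
#' @param vel_frac onset/offset velocity fraction (default 0.1)
#' @param amp_frac fixation crossing fraction (default 0.33)
#' @param period_ends_s optional vector of quiescent-period end times used
#'   as censoring limits
#' @return data.frame of accepted events with onset/offset times, direction,
#'   per-eye and binocular amplitude (rad), `peak_speed_deg_s`,
#'   `decay_slope_deg_s`, `fixation_s`, `censored`
#' @export
score_kinematics <- function(selected, trace, search_s = 0.5,
                             vel_frac = 0.1, amp_frac = 0.33,
                             period_ends_s = NULL) {
  stopifnot(inherits(trace, "eye_angle_trace"))
  acc <- selected[selected$accepted, , drop = FALSE]
  fs <- trace$fs_hz
  n <- length(trace$t_s)
  vL <- central_diff(trace$left_rad, fs)
  vR <- central_diff(trace$right_rad, fs)
  vB <- (abs(vL) + abs(vR)) / 2
  half_s <- round(search_s * fs)
  base_w <- round(1 * fs)

  rows <- vector("list", nrow(acc))
  for (j in seq_len(nrow(acc))) {
    i <- acc$idx[j]
    lo <- max(1L, i - half_s); hi <- min(n, i + half_s)
    pk <- lo + which.max(vB[lo:hi]) - 1L
    vpk <- vB[pk]
    pre <- which(vB[lo:pk] < vel_frac * vpk)
    onset <- if (length(pre)) lo + max(pre) - 1L else lo
    post <- which(vB[pk:hi] < vel_frac * vpk)
    offset <- if (length(post)) pk + min(post) - 1L else hi

    # censoring limit: next accepted saccade onset, period end, trace end
    lim <- n
    if (j < nrow(acc)) lim <- min(lim, acc$idx[j + 1L] - half_s)
    if (!is.null(period_ends_s)) {
      pe <- period_ends_s[period_ends_s > trace$t_s[offset]]
      if (length(pe)) lim <- min(lim, floor(min(pe) * fs) + 1L)
    }
    lim <- max(lim, offset)

    eye <- function(x) {
      b_lo <- max(1L, onset - base_w)
      baseline <- median(x[b_lo:max(b_lo, onset - 1L)])
      A <- x[offset] - baseline
      thr <- amp_frac * abs(A)
      seg <- sign(A) * (x[offset:lim] - baseline)
      crossed <- which(seg < thr)
      if (length(crossed)) {
        ci <- offset + min(crossed) - 1L
        censored <- FALSE
      } else {
        ci <- lim
        censored <- TRUE
      }
      # regression runs up to, not including, the first below-threshold
      # sample (the decay itself, not the crossing movement)
      win <- offset:max(offset, if (censored) ci else ci - 1L)
      slope <- if (length(win) >= 2L) {
        tt <- (win - offset) / fs
        abs(coef(lm.fit(cbind(1, tt), x[win]))[2L])
      } else 0
      list(A = A, slope_deg_s = slope * RAD2DEG,
           fixation_s = (ci - offset) / fs, censored = censored)
    }
    L <- eye(trace$left_rad); R <- eye(trace$right_rad)
    rows[[j]] <- data.frame(
      onset_s = trace$t_s[onset], offset_s = trace$t_s[offset],
      peak_s = trace$t_s[pk],
      direction = sign(L$A + R$A),
      amplitude_left_rad = L$A, amplitude_right_rad = R$A,
      amplitude_rad = (abs(L$A) + abs(R$A)) / 2,
      peak_speed_deg_s = max(vB[onset:offset]) * RAD2DEG,
      decay_slope_deg_s = (L$slope_deg_s + R$slope_deg_s) / 2,
      fixation_s = (L$fixation_s + R$fixation_s) / 2,
      censored = L$censored || R$censored)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(), offset_s = numeric(), peak_s = numeric(),
               direction = numeric(), amplitude_left_rad = numeric(),
               amplitude_right_rad = numeric(), amplitude_rad = numeric(),
               peak_speed_deg_s = numeric(), decay_slope_deg_s = numeric(),
               fixation_s = numeric(), censored = logical())
  out
}

#' Run the full saccade chain on a trace
#'
#' Convenience wrapper: [preprocess()] -> [detect_candidates()] ->
#' [select_saccades()] -> [score_kinematics()].
#'
#' @param trace an `eye_angle_trace`
#' @param variant `"multi"` (threshold 0.60 rad^2/s^2) or `"single"` (0.32)
#' @param period_ends_s optional quiescent-period end times for censoring
#' @param ... passed to [preprocess()]
#' @return data.frame of scored accepted saccades
#' @export
detect_saccades <- function(trace, variant = c("multi", "single"),
                            period_ends_s = NULL, ...) {
  variant <- match.arg(variant)
  thr <- if (variant == "multi") 0.60 else 0.32
  filt <- preprocess(trace, ...)
  cand <- detect_candidates(filt, threshold_rad2_s2 = thr)
  sel <- select_saccades(cand, filt)
  score_kinematics(sel, trace, period_ends_s = period_ends_s)
}
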