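# Synthetic eye-angle and speed traces. Within each quiescent segment,
# conjugate saccades are injected according to the segment state's
# kinematics preset; wake segments get swim bouts with bout-coupled eye
# movements. Every injected event is logged with its commanded kinematics so
# downstream recovery tests compare against the log, never against
# re-derived values.
#
# Event waveform (both eyes move identically; independent Gaussian noise is
# added per eye afterwards):
#   1. flight: 4-sample overshoot rise whose middle two increments realize
#      the commanded peak speed as a central-difference velocity;
#   2. glissade: 8-sample descent to the post-saccadic position;
#   3. fixation drift: linear decay at the commanded slope for the
#      commanded fixation duration;
#   4. a 3-sample sub-saccadic dip that carries the angle across the 33%
#      post-saccadic amplitude threshold exactly at the commanded fixation
#      time, after which the eye holds until the next saccade.
# The overshoot and the dip are much shorter than the 1.5-s median window of
# the preprocessing chain, so detection sees only the post-saccadic step,
# while kinematic scoring on the raw trace recovers peak speed, decay slope
# and fixation duration essentially unbiased (see the methods vignette).

GLISS_S <- 0.16   # glissade duration (s)
DIP_S <- 0.04     # crossing-dip duration (s)
CROSS_MARGIN_RAD <- 2.3 * DEG2RAD   # drift stays this far above threshold
DIP_BELOW_RAD <- 1.2 * DEG2RAD      # dip lands this far below threshold
A_POST_FLOOR_RAD <- 7 * DEG2RAD     # post-saccadic step floor (detectability)

#' Synthesize behavior traces for a state schedule
#'
#' @param schedule a `state_schedule`
#' @param kinematics named list of `substate_kinematics`, one per quiescent
#'   state appearing in the schedule (default: shipped presets)
#' @param fs_hz sample rate, >= 10 Hz (default 50)
#' @param noise_sd_rad SD of per-eye Gaussian angle noise (default 0.01)
#' @param seed integer seed
#' @return list of class `synth_behavior`:
#'   \describe{
#'     \item{trace}{`eye_angle_trace` (t_s, left_rad, right_rad, fs_hz)}
#'     \item{speed}{data.frame t_s, speed_mm_s}
#'     \item{events}{generator log: one row per injected saccade with
#'       onset time, state, direction and commanded kinematics}
#'     \item{schedule}{the input schedule}
#'   }
#' @export
synth_behavior <- function(schedule, kinematics = default_kinematics(),
                           fs_hz = 50, noise_sd_rad = 0.01, seed = 1L) {
  if (fs_hz < 10) stop("fs_hz must be >= 10")
  set.seed(seed)
  dt <- 1 / fs_hz
  n <- floor(schedule$duration_s * fs_hz)
  t_s <- (seq_len(n) - 1L) * dt
  angle <- numeric(n)          # clean conjugate angle (rad)
  speed <- abs(rnorm(n, 0.08, 0.04))  # quiescent locomotor baseline < 0.5

  pos <- 0                      # current holding position of both eyes
  logs <- list(); li <- 0L

  for (si in seq_len(nrow(schedule$segments))) {
    seg <- schedule$segments[si, ]
    i0 <- floor(seg$start_s * fs_hz) + 1L
    i1 <- min(floor(seg$end_s * fs_hz), n)
    if (i1 < i0) next
    if (seg$state == "Wake") {
      res <- synth_wake_segment(i0, i1, fs_hz, pos)
      angle[i0:i1] <- res$angle
      speed[i0:i1] <- res$speed
      pos <- res$pos
    } else {
      kin <- kinematics[[seg$state]]
      if (is.null(kin)) stop("no kinematics preset for state ", seg$state)
      angle[i0:i1] <- pos
      if (kin$rate_per_min > 0) {
        res <- synth_quiescent_segment(i0, i1, fs_hz, pos, kin, seg$state)
        angle[i0:i1] <- res$angle
        pos <- res$pos
        if (nrow(res$log)) { li <- li + 1L; logs[[li]] <- res$log }
      }
    }
  }

  events <- if (li) do.call(rbind, logs) else empty_event_log()
  left <- angle + rnorm(n, 0, noise_sd_rad)
  right <- angle + rnorm(n, 0, noise_sd_rad)
  trace <- eye_angle_trace(t_s, left, right, fs_hz)
  structure(list(trace = trace,
                 speed = data.frame(t_s = t_s, speed_mm_s = speed),
                 events = events, schedule = schedule,
                 noise_sd_rad = noise_sd_rad, seed = seed),
            class = "synth_behavior")
}

empty_event_log <- function() {
  data.frame(onset_s = numeric(), state = character(), direction = numeric(),
             peak_speed_deg_s = numeric(), realized_peak_deg_s = numeric(),
             amplitude_deg = numeric(),
             post_amp_deg = numeric(), slope_deg_s = numeric(),
             fixation_s = numeric(), censored = logical())
}

# Saccade timing within a segment: inter-saccade interval =
# event overhead + fixation + rest, with the rest drawn so the mean interval
# equals 60 / rate. `regularity` interpolates between a fixed rest (1) and
# an exponential rest (0).
synth_quiescent_segment <- function(i0, i1, fs, pos, kin, state) {
  dt <- 1 / fs
  n_seg <- i1 - i0 + 1L
  n_gliss <- max(2L, round(GLISS_S * fs))
  mean_isi <- 60 / kin$rate_per_min
  # event overhead (flight + glissade + dip) is ~0.3 s; the rest interval
  # is drawn per event so that the mean inter-saccade interval is exactly
  # 60 / rate
  if (mean_isi - kin$fixation_s[1] - 0.35 <= 0.05)
    stop("kinematics preset incompatible: rate too high for fixation length")

  draw_rest <- function(mean_rest) {
    r <- kin$regularity * mean_rest +
      (1 - kin$regularity) * rexp(1L, 1 / mean_rest)
    max(r, 0.05)
  }

  angle <- rep(pos, n_seg)
  log <- empty_event_log()
  cur <- 1L + round(draw_rest(mean_isi - kin$fixation_s[1] - 0.3) * fs)

  while (cur + 8L < n_seg) {
    f <- rlnorm_mean_sd(1L, kin$fixation_s[1], kin$fixation_s[2])
    s_deg <- rlnorm_mean_sd(1L, kin$decay_slope_deg_s[1], kin$decay_slope_deg_s[2])
    v_deg <- rlnorm_mean_sd(1L, kin$peak_speed_deg_s[1], kin$peak_speed_deg_s[2])
    a_deg <- rlnorm_mean_sd(1L, kin$amplitude_deg[1], kin$amplitude_deg[2])

    v <- v_deg * DEG2RAD; s <- s_deg * DEG2RAD
    # rise increment realizing the commanded peak speed as a central
    # difference at this sample rate, capped so low-rate traces stay sane;
    # the attainable peak is logged alongside the commanded one
    h <- min(v * dt, 25 * DEG2RAD)
    a_big <- max(a_deg * DEG2RAD, 2.2 * h)    # raised so peak speed is attainable
    a_post <- max((s * f + CROSS_MARGIN_RAD) / 0.67, A_POST_FLOOR_RAD)
    dirn <- if (abs(pos) > 8 * DEG2RAD) -sign(pos) else sample(c(-1, 1), 1L)

    # flight: equal increments of h = v * dt, so the peak central-difference
    # velocity equals the commanded peak speed exactly; the apex sample
    # flows straight into the glissade so no sample has near-zero velocity
    n_h <- max(2L, round(a_big / h))
    a_big <- n_h * h
    n_f <- max(1L, round(f * fs))
    n_dip <- max(1L, round(DIP_S * fs))
    len <- n_h + n_gliss + n_f + n_dip + 1L
    censored <- cur + len > n_seg
    rise <- pos + dirn * cumsum(rep(h, n_h))
    gliss <- pos + dirn * seq(a_big, a_post, length.out = n_gliss + 1L)[-1L]
    drift_len <- if (censored) n_seg - (cur + n_h + n_gliss) else n_f
    drift_len <- max(drift_len, 0L)
    drift <- pos + dirn * (a_post - s * dt * seq_len(drift_len))
    wave <- c(rise, gliss, drift)
    if (!censored) {
      # dip decisively across the 33% threshold, then hold just above it
      p_f <- a_post - s * dt * drift_len
      dip <- pos + dirn * rep(0.33 * a_post - DIP_BELOW_RAD, n_dip)
      hold_val <- pos + dirn * p_f
      wave <- c(wave, dip, hold_val)
    }
    idx <- cur + seq_along(wave) - 1L
    keep <- idx <= n_seg
    angle[idx[keep]] <- wave[keep]
    end_idx <- max(idx[keep])
    hold_pos <- angle[end_idx]
    if (end_idx < n_seg) angle[(end_idx + 1L):n_seg] <- hold_pos

    onset_s <- (i0 - 1L + cur - 1L) * dt
    log <- rbind(log, data.frame(
      onset_s = onset_s, state = state, direction = dirn,
      peak_speed_deg_s = v_deg,
      realized_peak_deg_s = h * fs * RAD2DEG,
      amplitude_deg = a_big * RAD2DEG,
      post_amp_deg = a_post * RAD2DEG, slope_deg_s = s_deg,
      fixation_s = f, censored = censored))
    pos <- hold_pos
    overhead_i <- (len - n_f) * dt
    m_i <- max(mean_isi - kin$fixation_s[1] - overhead_i, 0.05)
    cur <- end_idx + 1L + round(draw_rest(m_i) * fs)
  }
  list(angle = angle, pos = pos, log = log)
}

# Wake: swim bouts (~1 s interbout) as short speed bursts; a fraction of
# bouts carries a coupled eye repositioning. Quiescent floor elsewhere.
synth_wake_segment <- function(i0, i1, fs, pos) {
  dt <- 1 / fs
  n_seg <- i1 - i0 + 1L
  angle <- rep(pos, n_seg)
  speed <- abs(rnorm(n_seg, 0.08, 0.04))
  n_bout <- max(2L, round(0.45 * fs))
  cur <- 1L + round((0.15 + rexp(1L, 1 / 0.55)) * fs)
  while (cur + n_bout < n_seg) {
    burst <- rlnorm_mean_sd(1L, 8, 4) *
      sin(seq(0, pi, length.out = n_bout + 2L))[2:(n_bout + 1L)]
    speed[cur:(cur + n_bout - 1L)] <- pmax(speed[cur:(cur + n_bout - 1L)], burst)
    if (runif(1L) < 0.4) {   # bout-coupled eye movement
      new_pos <- runif(1L, -20, 20) * DEG2RAD
      jump <- seq(pos, new_pos, length.out = 4L)[-1L]
      jidx <- cur + seq_along(jump) - 1L
      angle[jidx] <- jump
      if (max(jidx) < n_seg) angle[(max(jidx) + 1L):n_seg] <- new_pos
      pos <- new_pos
    }
    cur <- cur + n_bout + round((0.15 + rexp(1L, 1 / 0.55)) * fs)
  }
  list(angle = angle, speed = speed, pos = pos)
}
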