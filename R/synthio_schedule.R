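# State schedules: contiguous labeled segments over [0, T] with a lights
# step function, a first-day indicator and a clock offset. The schedule is
# the ground truth that behavior and neural generators, and all downstream
# recovery tests, refer back to.

#' Build a semi-Markov state schedule
#'
#' Draws a sequence of contiguous behavioral-state segments whose per-phase
#' time fractions approach `occupancy_targets` as the duration grows.
#' Consecutive draws of the same state are merged; quiescent segments are
#' at least 60 s long.
#'
#' @param duration_s total schedule length in seconds (> 0)
#' @param light_cycle_spec list: `mode` one of `"LD"`, `"LL"`, `"DD"`;
#'   for `"LD"`, `day_len_h` (default 14) and `day_start_h` (default 0)
#'   define the lights-on window within each 24-h cycle (clock hours)
#' @param occupancy_targets named numeric vector of target time fractions
#'   over states in `Wake, QEM1, QEM2, QEM3, QNEM` summing to <= 1
#'   (remainder is Wake), or a list with elements `day` and `night` for
#'   phase-dependent targets
#' @param seed integer seed; the schedule is deterministic given the seed
#' @param clock_offset_h clock time (hours from midnight) at t = 0
#' @param mean_segment_s mean segment duration for the semi-Markov draws
#' @return object of class `state_schedule`: `segments` (data.frame with
#'   `start_s`, `end_s`, `state`), plus `duration_s`, `lights_fun`,
#'   `day1_fun`, `clock_offset_h`
#' @export
make_schedule <- function(duration_s,
                          light_cycle_spec = list(mode = "LD", day_len_h = 14,
                                                  day_start_h = 0),
                          occupancy_targets = c(Wake = 0.5, QEM1 = 0.5),
                          seed = 1L,
                          clock_offset_h = 0,
                          mean_segment_s = 180) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  lights_fun <- make_lights_fun(light_cycle_spec, clock_offset_h)
  day1_fun <- function(t_s) as.numeric((t_s + clock_offset_h * 3600) < 24 * 3600)

  norm_targets <- function(tg) {
    tg <- tg[tg > 0]
    bad <- setdiff(names(tg), STATE_LEVELS[1:5])
    if (length(bad)) stop("unknown state in occupancy_targets: ", bad[1])
    s <- sum(tg)
    if (s > 1 + 1e-9) stop("occupancy_targets sum to more than 1")
    if (s < 1 - 1e-9) {
      tg["Wake"] <- (tg["Wake"] %||% 0) + (1 - s)
      tg <- tg[tg > 0]
    }
    tg
  }
  phase_targets <- if (is.list(occupancy_targets) &&
                       all(c("day", "night") %in% names(occupancy_targets))) {
    lapply(occupancy_targets, norm_targets)
  } else {
    tg <- norm_targets(unlist(occupancy_targets))
    list(day = tg, night = tg)
  }

  set.seed(seed)
  segs <- list(); t <- 0; i <- 0L
  while (t < duration_s) {
    tg <- if (lights_fun(t) > 0.5) phase_targets$day else phase_targets$night
    state <- sample(names(tg), 1L, prob = tg)
    dur <- if (length(tg) == 1L) duration_s - t else {
      d <- rexp(1L, 1 / mean_segment_s)
      if (state != "Wake") d <- max(d, 60) else d <- max(d, 10)
      d
    }
    dur <- min(dur, duration_s - t)
    i <- i + 1L
    segs[[i]] <- data.frame(start_s = t, end_s = t + dur, state = state)
    t <- t + dur
  }
  segments <- do.call(rbind, segs)
  # merge consecutive identical states
  keep <- c(TRUE, segments$state[-1] != segments$state[-nrow(segments)])
  grp <- cumsum(keep)
  segments <- data.frame(
    start_s = tapply(segments$start_s, grp, min),
    end_s = tapply(segments$end_s, grp, max),
    state = segments$state[keep], row.names = NULL)
  structure(list(segments = segments, duration_s = duration_s,
                 lights_fun = lights_fun, day1_fun = day1_fun,
                 clock_offset_h = clock_offset_h,
                 light_cycle_spec = light_cycle_spec, seed = seed),
            class = "state_schedule")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

make_lights_fun <- function(spec, clock_offset_h) {
  mode <- spec$mode %||% "LD"
  if (mode == "LL") return(function(t_s) rep(1, length(t_s)))
  if (mode == "DD") return(function(t_s) rep(0, length(t_s)))
  if (mode == "random") {
    # lights toggled at random times (mean block spec$block_h, default 2 h),
    # decorrelated from circadian phase; deterministic given spec$seed
    set.seed(spec$seed %||% 1L)
    n_blk <- ceiling((spec$duration_h %||% 48) / (spec$block_h %||% 2) * 4) + 4L
    edges <- cumsum(rexp(n_blk, 1 / ((spec$block_h %||% 2) * 3600)))
    state0 <- sample(0:1, 1L)
    return(function(t_s) (state0 + findInterval(t_s, edges)) %% 2)
  }
  day_len <- spec$day_len_h %||% 14
  day_start <- spec$day_start_h %||% 0
  function(t_s) {
    h <- ((t_s / 3600 + clock_offset_h) %% 24)
    as.numeric(h >= day_start & h < day_start + day_len)
  }
}

#' Build a fixed schedule from explicit segments
#'
#' Convenience constructor when the state sequence is known (tests,
#' single-state simulations).
#' @param states character vector of states
#' @param durations_s numeric vector of matching segment durations
#' @inheritParams make_schedule
#' @return `state_schedule`
#' @export
schedule_from_segments <- function(states, durations_s,
                                   light_cycle_spec = list(mode = "LL"),
                                   clock_offset_h = 0) {
  stopifnot(length(states) == length(durations_s), all(durations_s > 0))
  bad <- setdiff(states, STATE_LEVELS[1:5])
  if (length(bad)) stop("unknown state: ", bad[1])
  end <- cumsum(durations_s)
  segments <- data.frame(start_s = c(0, head(end, -1)), end_s = end,
                         state = states)
  lights_fun <- make_lights_fun(light_cycle_spec, clock_offset_h)
  structure(list(segments = segments, duration_s = end[length(end)],
                 lights_fun = lights_fun,
                 day1_fun = function(t_s)
                   as.numeric((t_s + clock_offset_h * 3600) < 24 * 3600),
                 clock_offset_h = clock_offset_h,
                 light_cycle_spec = light_cycle_spec, seed = NA),
            class = "state_schedule")
}

#' State label at given times
#' @param schedule a `state_schedule`
#' @param t_s numeric vector of times in seconds
#' @return character vector of states
#' @export
schedule_state_at <- function(schedule, t_s) {
  seg <- schedule$segments
  idx <- findInterval(pmin(t_s, schedule$duration_s - 1e-9), seg$start_s)
  idx[idx < 1L] <- 1L
  seg$state[idx]
}

#' Time fraction per state in a schedule (optionally within a window)
#' @param schedule a `state_schedule`
#' @param window_s optional c(start, end) in seconds
#' @return named numeric vector of fractions over the five states
#' @export
schedule_occupancy <- function(schedule, window_s = NULL) {
  seg <- schedule$segments
  if (!is.null(window_s)) {
    s <- pmax(seg$start_s, window_s[1]); e <- pmin(seg$end_s, window_s[2])
    keep <- e > s
    seg <- data.frame(start_s = s[keep], end_s = e[keep],
                      state = seg$state[keep])
  }
  dur <- tapply(seg$end_s - seg$start_s, factor(seg$state, STATE_LEVELS[1:5]),
                sum, default = 0)
  dur <- ifelse(is.na(dur), 0, dur)
  dur / sum(dur)
}
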