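# Synthetic neural populations with the response classes the downstream
# analyses assume: broad QEM-1 suppression, exponential ramp-down and
# ramp-up cells over relative time within each QEM-1 period, transient
# event cells, and pure-noise cells; plus additive slow bleaching and a
# missing-sample mask. Neuron class labels, time constants and injected
# event times are logged for recovery tests.

#' Specification of a synthetic neural population
#'
#' @param n_suppressed,n_ramp_down,n_ramp_up,n_event,n_noise class counts
#' @param tau_down,tau_up mean/sd of the ramp time constants in relative
#'   time units (defaults: 0.91 +/- 0.03 down, 0.21 +/- 0.01 up, matching
#'   the published raphe / hindbrain values)
#' @param noise_sd noise scale; per-sample SD is
#'   `noise_sd * (0.25 + signal)` (shot-noise-like)
#' @param bleach_amp,bleach_tau_s additive exponential bleach amplitude and
#'   time constant (0 amplitude disables)
#' @param missing_fraction fraction of samples masked as unobserved, in
#'   `[0, 0.5]`
#' @param event_rate_hz Poisson rate of boxcar transients for event cells
#' @return object of class `synth_neural_spec`
#' @export
synth_neural_spec <- function(n_suppressed = 20, n_ramp_down = 20,
                              n_ramp_up = 20, n_event = 10, n_noise = 10,
                              tau_down = c(0.91, 0.03),
                              tau_up = c(0.21, 0.01),
                              noise_sd = 0.05,
                              bleach_amp = 0, bleach_tau_s = 3600,
                              missing_fraction = 0,
                              event_rate_hz = 0.02) {
  counts <- c(n_suppressed, n_ramp_down, n_ramp_up, n_event, n_noise)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (sum(counts) == 0) stop("at least one neuron class must be non-empty")
  if (missing_fraction < 0 || missing_fraction > 0.5)
    stop("missing_fraction must be in [0, 0.5]")
  structure(list(n_suppressed = n_suppressed, n_ramp_down = n_ramp_down,
                 n_ramp_up = n_ramp_up, n_event = n_event, n_noise = n_noise,
                 tau_down = tau_down, tau_up = tau_up, noise_sd = noise_sd,
                 bleach_amp = bleach_amp, bleach_tau_s = bleach_tau_s,
                 missing_fraction = missing_fraction,
                 event_rate_hz = event_rate_hz),
            class = "synth_neural_spec")
}

#' Construct a neuron-by-time fluorescence container
#'
#' @param F neurons x time matrix
#' @param mask logical matrix, TRUE where observed
#' @param fs_hz sample rate (volumes per second)
#' @param centroids_um neurons x 3 matrix of x, y, z in micrometers
#' @param regions character vector of region labels per neuron
#' @return object of class `neuron_matrix`
#' @export
neuron_matrix <- function(F, mask = NULL, fs_hz = 2,
                          centroids_um = NULL, regions = NULL) {
  F <- as.matrix(F)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(F), ncol(F))
  stopifnot(all(dim(mask) == dim(F)))
  if (is.null(centroids_um))
    centroids_um <- matrix(0, nrow(F), 3,
                           dimnames = list(NULL, c("x", "y", "z")))
  if (is.null(regions)) regions <- rep("unassigned", nrow(F))
  stopifnot(nrow(centroids_um) == nrow(F), length(regions) == nrow(F))
  structure(list(F = F, mask = mask, fs_hz = fs_hz,
                 centroids_um = centroids_um, regions = regions),
            class = "neuron_matrix")
}

#' Generate a synthetic neural recording for a schedule
#'
#' Ramp cells follow `exp(-t./tau)` (down) or `1 - exp(-t./tau)` (up) in
#' relative time `t.` within each QEM-1 period and sit at baseline outside;
#' suppressed cells drop their mean during QEM-1; event cells emit boxcar
#' transients at Poisson times; all traces get signal-dependent Gaussian
#' noise (SD = `noise_sd * (0.25 + signal)`, emulating photon shot noise,
#' which is low when a cell is silent), an optional additive exponential
#' bleach, and a random missing mask.
#'
#' @param spec a `synth_neural_spec`
#' @param schedule a `state_schedule` (QEM-1 periods drive the ramps)
#' @param fs_hz sample rate (default 2, i.e. two volumes per second)
#' @param seed integer seed
#' @return list of class `synth_neural`: `matrix` (`neuron_matrix`),
#'   `cells` (log: class, tau, region per neuron), `events` (log of
#'   injected transients), `schedule`
#' @export
synth_neural <- function(spec, schedule, fs_hz = 2, seed = 1L) {
  stopifnot(inherits(spec, "synth_neural_spec"))
  set.seed(seed)
  n_t <- floor(schedule$duration_s * fs_hz)
  t_s <- (seq_len(n_t) - 1L) / fs_hz
  qem1 <- schedule$segments[schedule$segments$state == "QEM1", , drop = FALSE]
  classes <- rep(c("suppressed", "ramp_down", "ramp_up", "event", "noise"),
                 c(spec$n_suppressed, spec$n_ramp_down, spec$n_ramp_up,
                   spec$n_event, spec$n_noise))
  n <- length(classes)
  taus <- rep(NA_real_, n)
  region_of <- c(suppressed = "telencephalon", ramp_down = "dorsal_raphe",
                 ramp_up = "lateral_hindbrain", event = "tectum",
                 noise = "cerebellum")
  F <- matrix(0, n, n_t)
  ev_log <- list()

  rel_time <- rep(NA_real_, n_t)
  for (p in seq_len(nrow(qem1))) {
    idx <- which(t_s >= qem1$start_s[p] & t_s < qem1$end_s[p])
    if (length(idx) > 1L)
      rel_time[idx] <- (t_s[idx] - qem1$start_s[p]) /
        (qem1$end_s[p] - qem1$start_s[p])
  }
  in_qem1 <- !is.na(rel_time)

  for (i in seq_len(n)) {
    cl <- classes[i]
    tr <- numeric(n_t)
    if (cl == "suppressed") {
      tr <- rep(1, n_t)
      tr[in_qem1] <- 0.3
    } else if (cl == "ramp_down") {
      taus[i] <- max(rnorm(1, spec$tau_down[1], spec$tau_down[2]), 0.05)
      tr[in_qem1] <- exp(-rel_time[in_qem1] / taus[i])
    } else if (cl == "ramp_up") {
      taus[i] <- max(rnorm(1, spec$tau_up[1], spec$tau_up[2]), 0.05)
      tr[in_qem1] <- 1 - exp(-rel_time[in_qem1] / taus[i])
    } else if (cl == "event") {
      n_ev <- rpois(1, spec$event_rate_hz * schedule$duration_s)
      if (n_ev > 0) {
        starts <- sort(runif(n_ev, 0, schedule$duration_s - 4))
        starts <- starts[c(TRUE, diff(starts) > 10)]
        dur <- runif(length(starts), 2.5, 4)
        for (k in seq_along(starts)) {
          tr[t_s >= starts[k] & t_s < starts[k] + dur[k]] <- 1
          ev_log[[length(ev_log) + 1L]] <-
            data.frame(neuron = i, start_s = starts[k], dur_s = dur[k])
        }
      }
    }
    F[i, ] <- tr + rnorm(n_t, 0, spec$noise_sd * (0.25 + pmax(tr, 0)))
  }
  if (spec$bleach_amp > 0)
    F <- F + matrix(spec$bleach_amp * exp(-t_s / spec$bleach_tau_s),
                    n, n_t, byrow = TRUE)
  mask <- matrix(runif(n * n_t) >= spec$missing_fraction, n, n_t)
  F[!mask] <- NA_real_
  centroids <- cbind(x = runif(n, 0, 1000), y = runif(n, 0, 760),
                     z = runif(n, 0, 150))
  cells <- data.frame(neuron = seq_len(n), class = classes, tau = taus,
                      region = unname(region_of[classes]))
  structure(list(matrix = neuron_matrix(F, mask, fs_hz, centroids,
                                        cells$region),
                 cells = cells,
                 events = if (length(ev_log)) do.call(rbind, ev_log) else
                   data.frame(neuron = integer(), start_s = numeric(),
                              dur_s = numeric()),
                 schedule = schedule, seed = seed),
            class = "synth_neural")
}

#' @export
print.synth_neural <- function(x, ...) {
  cat("synthetic neural recording:", nrow(x$matrix$F), "neurons x",
      ncol(x$matrix$F), "samples at", x$matrix$fs_hz, "Hz\n")
  print(table(x$cells$class))
  invisible(x)
}
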