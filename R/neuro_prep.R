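# Post-processing of extracted fluorescence traces: duplicate-ROI merging,
# coverage filtering, bleach correction, interpolation, and transient-event
# detection.

#' Merge duplicate ROIs
#'
#' ROI pairs whose centroids are within 4 um in all three dimensions and
#' whose traces correlate above 0.8 on co-observed samples are treated as
#' repeated samplings of one neuron; within each transitive group only the
#' member with the highest coverage is kept.
#'
#' @param nm a `neuron_matrix`
#' @param dist_um per-axis distance threshold (default 4)
#' @param cor_min correlation threshold (default 0.8)
#' @param min_overlap minimum co-observed samples for the correlation
#'   (default 10)
#' @return the pruned `neuron_matrix`, with attribute `kept` (indices into
#'   the input)
#' @export
merge_duplicates <- function(nm, dist_um = 4, cor_min = 0.8,
                             min_overlap = 10L) {
  stopifnot(inherits(nm, "neuron_matrix"))
  n <- nrow(nm$F)
  if (n < 2L) return(nm)
  cov <- rowMeans(nm$mask)
  # candidate pairs by coordinate proximity (all three axes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    dx <- abs(nm$centroids_um[(i + 1L):n, 1] - nm$centroids_um[i, 1])
    dy <- abs(nm$centroids_um[(i + 1L):n, 2] - nm$centroids_um[i, 2])
    dz <- abs(nm$centroids_um[(i + 1L):n, 3] - nm$centroids_um[i, 3])
    for (j in i + which(dx <= dist_um & dy <= dist_um & dz <= dist_um)) {
      both <- nm$mask[i, ] & nm$mask[j, ]
      if (sum(both) < min_overlap) next
      a <- nm$F[i, both]; b <- nm$F[j, both]
      if (sd(a) < 1e-12 || sd(b) < 1e-12) next
      if (cor(a, b) > cor_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  kept <- vapply(split(seq_len(n), root), function(g)
    g[which.max(cov[g])], integer(1))
  kept <- sort(unname(kept))
  out <- neuron_matrix(nm$F[kept, , drop = FALSE],
                       nm$mask[kept, , drop = FALSE], nm$fs_hz,
                       nm$centroids_um[kept, , drop = FALSE],
                       nm$regions[kept])
  attr(out, "kept") <- kept
  out
}

#' Drop neurons with insufficient coverage
#'
#' @param nm a `neuron_matrix`
#' @param min_frac minimum observed fraction (default 0.5)
#' @return filtered `neuron_matrix` with attribute `kept`
#' @export
coverage_filter <- function(nm, min_frac = 0.5) {
  stopifnot(inherits(nm, "neuron_matrix"))
  kept <- which(rowMeans(nm$mask) >= min_frac)
  if (!length(kept)) stop("coverage filter removed every neuron")
  out <- neuron_matrix(nm$F[kept, , drop = FALSE],
                       nm$mask[kept, , drop = FALSE], nm$fs_hz,
                       nm$centroids_um[kept, , drop = FALSE],
                       nm$regions[kept])
  attr(out, "kept") <- kept
  out
}

#' Correct slow photobleaching
#'
#' Fits `f(t) = A exp(-t / tau) + C` (A >= 0, tau > 0) to each neuron's
#' observed samples by bounded least squares and subtracts the decaying
#' part, keeping the asymptote. Neurons whose fit fails are passed through
#' unchanged and flagged.
#'
#' @param nm a `neuron_matrix`
#' @param min_obs minimum observed samples required per neuron (default 100)
#' @return `neuron_matrix` with attributes `bleach_fits` (data.frame
#'   A, tau_s, C, failed) -- mask and dimensions are unchanged
#' @export
debleach <- function(nm, min_obs = 100L) {
  stopifnot(inherits(nm, "neuron_matrix"))
  n_t <- ncol(nm$F)
  t_s <- (seq_len(n_t) - 1L) / nm$fs_hz
  fits <- data.frame(A = numeric(nrow(nm$F)), tau_s = NA_real_,
                     C = NA_real_, failed = FALSE)
  F2 <- nm$F
  for (i in seq_len(nrow(nm$F))) {
    obs <- which(nm$mask[i, ])
    if (length(obs) < min_obs) { fits$failed[i] <- TRUE; next }
    y <- nm$F[i, obs]; tt <- t_s[obs]
    fit <- fit_exp_offset(tt, y)
    if (is.null(fit)) { fits$failed[i] <- TRUE; next }
    fits$A[i] <- fit["A"]; fits$tau_s[i] <- fit["tau"]; fits$C[i] <- fit["C"]
    F2[i, obs] <- y - fit["A"] * exp(-tt / fit["tau"])
  }
  out <- neuron_matrix(F2, nm$mask, nm$fs_hz, nm$centroids_um, nm$regions)
  attr(out, "bleach_fits") <- fits
  out
}

# bounded least squares for A exp(-t/tau) + C; profile C and A in closed
# form over a tau grid, then polish with optim
fit_exp_offset <- function(tt, y) {
  span <- diff(range(tt)); if (span <= 0) return(NULL)
  sse_at <- function(ltau) {
    b <- exp(-tt / exp(ltau))
    X <- cbind(1, b)
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(list(sse = Inf))
    A <- max(cf[2], 0)
    C <- if (A == 0) mean(y) else cf[1]
    r <- y - C - A * b
    list(sse = sum(r^2), A = A, C = C)
  }
  grid <- log(span * c(0.05, 0.1, 0.25, 0.5, 1, 2, 5))
  sses <- vapply(grid, function(g) sse_at(g)$sse, numeric(1))
  if (all(!is.finite(sses))) return(NULL)
  lt0 <- grid[which.min(sses)]
  op <- tryCatch(optim(lt0, function(g) sse_at(g)$sse, method = "Brent",
                       lower = lt0 - 3, upper = lt0 + 3),
                 error = function(e) NULL)
  if (is.null(op)) return(NULL)
  best <- sse_at(op$par)
  c(A = best$A, tau = exp(op$par), C = best$C)
}

#' Linearly interpolate missing samples
#'
#' @param nm a `neuron_matrix`
#' @return `neuron_matrix` with `F` fully observed (mask retained)
#' @export
interpolate_missing <- function(nm) {
  F2 <- nm$F
  for (i in seq_len(nrow(F2))) {
    F2[i, !nm$mask[i, ]] <- NA_real_
    F2[i, ] <- interp_na(F2[i, ])
  }
  neuron_matrix(F2, nm$mask, nm$fs_hz, nm$centroids_um, nm$regions)
}

#' Detect transient activity events
#'
#' Baseline per neuron: mean of samples below the rolling 10th percentile
#' (45-s centered window), subtracted from the trace. The noise SD is
#' estimated from the negative side of the signal -- the RMS deviation of
#' the samples below the quiescent level (the median of the
#' baseline-subtracted trace, which positive transients do not
#' contaminate). Supra-threshold runs (mean + 2 x noise SD) lasting at
#' least `min_dur_s` are events; surviving events closer than `min_gap_s`
#' are then merged, the merged event spanning both. Filtering before
#' merging keeps isolated single-sample noise crossings from chaining
#' into spurious events.
#'
#' @param nm a debleached, interpolated `neuron_matrix`
#' @param labels optional label series for per-state rates
#' @param min_dur_s minimum event duration (default 2 s)
#' @param min_gap_s minimum inter-event interval (default 6 s)
#' @param baseline_win_s rolling baseline window (default 45 s)
#' @param dual_rate_hz event-rate threshold for flagging neurons active in
#'   both wake and QEM-1 (default 0.014 events/s)
#' @return list of class `event_train`: `events` (neuron, start_s, end_s),
#'   `rates` (per neuron x state, events/s averaged over state instances),
#'   `dual_active` (logical per neuron), `noise_sd` per neuron
#' @export
detect_events <- function(nm, labels = NULL, min_dur_s = 2, min_gap_s = 6,
                          baseline_win_s = 45, dual_rate_hz = 0.014) {
  stopifnot(inherits(nm, "neuron_matrix"))
  fs <- nm$fs_hz
  n <- nrow(nm$F); n_t <- ncol(nm$F)
  win <- odd_window(baseline_win_s * fs)
  ev_rows <- list()
  noise_sd <- numeric(n)
  for (i in seq_len(n)) {
    x <- interp_na(ifelse(nm$mask[i, ], nm$F[i, ], NA_real_))
    bl <- rolling_low_mean(x, win, q = 0.10)
    d <- x - bl
    quiet <- median(d)
    neg <- d[d < quiet] - quiet
    nsd <- if (length(neg) >= 10) sqrt(mean(neg^2)) else sd(d)
    noise_sd[i] <- nsd
    thr <- mean(d) + 2 * nsd
    runs <- true_runs(d > thr)
    if (!nrow(runs)) next
    runs <- runs[(runs$end - runs$start + 1L) / fs >= min_dur_s, ,
                 drop = FALSE]
    if (!nrow(runs)) next
    # merge surviving events separated by less than min_gap_s
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (k in 2:nrow(runs)) {
      if ((runs$start[k] - merged$end[nrow(merged)]) / fs < min_gap_s)
        merged$end[nrow(merged)] <- runs$end[k]
      else merged <- rbind(merged, runs[k, ])
    }
    ev_rows[[length(ev_rows) + 1L]] <-
      data.frame(neuron = i, start_s = (merged$start - 1L) / fs,
                 end_s = merged$end / fs)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(neuron = integer(), start_s = numeric(), end_s = numeric())

  rates <- NULL; dual <- NULL
  if (!is.null(labels)) {
    states <- c("Wake", "QEM1")
    rates <- matrix(NA_real_, n, length(states),
                    dimnames = list(NULL, states))
    for (s in states) {
      seg <- labels[labels$label == s, , drop = FALSE]
      if (!nrow(seg)) next
      per_inst <- matrix(0, n, nrow(seg))
      for (g in seq_len(nrow(seg))) {
        dur <- seg$end_s[g] - seg$start_s[g]
        if (dur <= 0) next
        cnt <- tabulate(events$neuron[events$start_s >= seg$start_s[g] &
                                        events$start_s < seg$end_s[g]], n)
        per_inst[, g] <- cnt / dur
      }
      rates[, s] <- rowMeans(per_inst)
    }
    dual <- rates[, "Wake"] > dual_rate_hz & rates[, "QEM1"] > dual_rate_hz
  }
  structure(list(events = events, rates = rates, dual_active = dual,
                 noise_sd = noise_sd),
            class = "event_train")
}

# mean of samples below the rolling q-quantile in a centered window
rolling_low_mean <- function(x, win, q = 0.10) {
  n <- length(x)
  half <- win %/% 2L
  out <- numeric(n)
  # evaluate on a stride and interpolate: the baseline is slow by design
  stride <- max(1L, half %/% 2L)
  at <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(at, function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    qq <- quantile(w, q, names = FALSE)
    lw <- w[w <= qq]
    if (length(lw)) mean(lw) else qq
  }, numeric(1))
  approx(at, vals, xout = seq_len(n))$y
}

#' Standard post-processing chain
#'
#' [merge_duplicates()] -> [coverage_filter()] -> [debleach()] ->
#' [interpolate_missing()].
#' @param nm a raw `neuron_matrix`
#' @param min_frac coverage threshold (default 0.5)
#' @return cleaned `neuron_matrix`
#' @export
neuro_prep <- function(nm, min_frac = 0.5) {
  interpolate_missing(debleach(coverage_filter(merge_duplicates(nm),
                                               min_frac)))
}
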