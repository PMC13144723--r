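# Population dynamics within a behavioral state: state-restricted PCA,
# trajectory entanglement, and elastic-net decoding of relative time.

#' State-restricted PCA
#'
#' Each period of the state is summarized as a neurons x 10 matrix of
#' within-decile mean activity (z-scored traces); the matrices are averaged
#' across periods, PCA is computed over the 10 decile observations, and the
#' full recording is projected onto the top two components. PC signs are
#' fixed so that PC1 correlates positively with relative time.
#'
#' @param nm an interpolated `neuron_matrix` (traces are z-scored here)
#' @param labels label series
#' @param state state name (e.g. "QEM1" or "Wake")
#' @param n_bins deciles per period (default 10)
#' @return list of class `state_pca`: `loadings` (neurons x 2), `mean_mat`
#'   (neurons x n_bins), `projection` (T x 2), `explained` (variance
#'   fractions), `periods`
#' @export
state_pca <- function(nm, labels, state = "QEM1", n_bins = 10L) {
  Z <- zscore_rows(nm$F)
  t_s <- (seq_len(ncol(Z)) - 1L) / nm$fs_hz
  periods <- merge_label_periods(labels, state)
  mats <- list()
  for (p in seq_len(nrow(periods))) {
    idx <- which(t_s >= periods$start_s[p] & t_s < periods$end_s[p])
    if (length(idx) < n_bins) { warning("period ", p, " too short, skipped"); next }
    dec <- cut(seq_along(idx), n_bins, labels = FALSE)
    mats[[length(mats) + 1L]] <-
      t(vapply(seq_len(n_bins), function(b)
        rowMeans(Z[, idx[dec == b], drop = FALSE]), numeric(nrow(Z))))
  }
  if (!length(mats)) stop("no usable period of state ", state)
  M <- Reduce(`+`, mats) / length(mats)       # n_bins x neurons
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  # sign convention: PC1 score increases with time within the mean period
  for (j in 1:2) {
    sc <- M %*% load2[, j]
    if (cor(sc, seq_len(n_bins)) < 0) load2[, j] <- -load2[, j]
  }
  proj <- t(Z) %*% load2
  structure(list(loadings = load2, mean_mat = t(M),
                 projection = proj,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 periods = periods, state = state, fs_hz = nm$fs_hz),
            class = "state_pca")
}

zscore_rows <- function(F) {
  mu <- rowMeans(F)
  s <- apply(F, 1, sd)
  s[s < 1e-12] <- 1
  (F - mu) / s
}

#' Trajectory entanglement within a period
#'
#' The 2-D trajectory is Gaussian-smoothed (sigma 12.5 s), represented as
#' N - 1 linear segments, and the number of unique self-crossings (pairs of
#' intersecting segments, pairs sharing an endpoint excluded) is counted
#' and normalized by the period duration.
#'
#' @param projection T x 2 matrix of projected activity for one period
#' @param fs_hz sample rate
#' @param sigma_s smoothing kernel SD (default 12.5 s)
#' @return list: `crossings` (integer), `duration_s`,
#'   `entanglement` (crossings per second); `NA`s when under 3 samples
#' @export
entanglement <- function(projection, fs_hz, sigma_s = 12.5) {
  n <- nrow(projection)
  if (is.null(n) || n < 3L)
    return(list(crossings = NA_integer_, duration_s = NA_real_,
                entanglement = NA_real_))
  x <- gaussian_smooth(projection[, 1], sigma_s * fs_hz)
  y <- gaussian_smooth(projection[, 2], sigma_s * fs_hz)
  cr <- polyline_crossings_cpp(x, y)
  dur <- n / fs_hz
  list(crossings = cr, duration_s = dur, entanglement = cr / dur)
}

#' Entanglement of every period of a state
#'
#' @param pca a `state_pca`
#' @param min_period_s periods shorter than this are skipped (default 60)
#' @return data.frame per period: `start_s`, `end_s`, `crossings`,
#'   `duration_s`, `entanglement`
#' @export
state_entanglement <- function(pca, min_period_s = 60) {
  t_s <- (seq_len(nrow(pca$projection)) - 1L) / pca$fs_hz
  per <- pca$periods
  per <- per[per$end_s - per$start_s >= min_period_s, , drop = FALSE]
  rows <- lapply(seq_len(nrow(per)), function(p) {
    idx <- which(t_s >= per$start_s[p] & t_s < per$end_s[p])
    e <- entanglement(pca$projection[idx, , drop = FALSE], pca$fs_hz)
    data.frame(start_s = per$start_s[p], end_s = per$end_s[p],
               crossings = e$crossings, duration_s = e$duration_s,
               entanglement = e$entanglement)
  })
  do.call(rbind, rows)
}

#' Decode relative time within a state from population activity
#'
#' Traces are z-scored within the state; every period at least
#' `min_period_s` long is divided into 100 relative-time bins (bin-mean
#' activity); an elastic net is trained on all periods but one and
#' evaluated on the held-out period, rotating through periods. The truth
#' is a 0 to 1 ramp over each period's bins. Hyperparameters (mixing
#' `alpha` in {0.1, 0.5, 0.9}, penalty on a log grid) are chosen by inner
#' leave-one-period-out validation on the training periods when at least
#' three periods exist.
#'
#' @param nm interpolated `neuron_matrix`
#' @param labels label series
#' @param state decoded state (default "QEM1")
#' @param min_period_s period threshold (default 180)
#' @param n_bins relative-time bins (default 100)
#' @param alphas elastic-net mixing grid
#' @param seed integer seed
#' @return list of class `time_decoder`: `pred` (per period bins),
#'   `truth`, `r2` (pooled), `weights` (median over fits), `period_ids`
#' @export
decode_relative_time <- function(nm, labels, state = "QEM1",
                                 min_period_s = 180, n_bins = 100L,
                                 alphas = c(0.1, 0.5, 0.9), seed = 1L) {
  bins <- state_bins(nm, labels, state, min_period_s, n_bins)
  if (length(unique(bins$period)) < 2L)
    stop("need at least 2 eligible periods of ", state)
  X <- bins$X; period <- bins$period
  y <- rep(seq(0, 1, length.out = n_bins), length(unique(period)))
  set.seed(seed)
  periods <- unique(period)
  preds <- numeric(length(y))
  wts <- matrix(NA_real_, ncol(X), length(periods))
  for (k in seq_along(periods)) {
    te <- period == periods[k]
    Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
    hp <- pick_enet(Xtr, ytr, period[!te], alphas)
    fit <- glmnet::glmnet(Xtr, ytr, alpha = hp$alpha, lambda = hp$lambda,
                          standardize = FALSE)
    preds[te] <- as.numeric(predict(fit, X[te, , drop = FALSE]))
    wts[, k] <- as.numeric(coef(fit))[-1]
  }
  r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  structure(list(pred = preds, truth = y, period = period, r2 = r2,
                 weights = apply(wts, 1, median), state = state,
                 n_periods = length(periods)),
            class = "time_decoder")
}

# per-state z-scoring and relative-time binning
state_bins <- function(nm, labels, state, min_period_s, n_bins) {
  t_s <- (seq_len(ncol(nm$F)) - 1L) / nm$fs_hz
  per <- merge_label_periods(labels, state)
  per <- per[per$end_s - per$start_s >= min_period_s, , drop = FALSE]
  in_state <- rep(FALSE, length(t_s))
  for (p in seq_len(nrow(per)))
    in_state[t_s >= per$start_s[p] & t_s < per$end_s[p]] <- TRUE
  Zs <- nm$F
  mu <- rowMeans(Zs[, in_state, drop = FALSE])
  sdv <- apply(Zs[, in_state, drop = FALSE], 1, sd)
  sdv[sdv < 1e-12] <- 1
  Zs <- (Zs - mu) / sdv
  Xl <- list(); pid <- integer()
  for (p in seq_len(nrow(per))) {
    idx <- which(t_s >= per$start_s[p] & t_s < per$end_s[p])
    if (length(idx) < n_bins / 2) next
    bin <- cut(seq_along(idx), n_bins, labels = FALSE)
    Xl[[length(Xl) + 1L]] <-
      t(vapply(seq_len(n_bins), function(b)
        rowMeans(Zs[, idx[bin == b], drop = FALSE]), numeric(nrow(Zs))))
    pid <- c(pid, rep(p, n_bins))
  }
  list(X = do.call(rbind, Xl), period = pid, periods = per)
}

pick_enet <- function(X, y, period, alphas,
                      lambdas = 10^seq(-4, 0, length.out = 9)) {
  periods <- unique(period)
  if (length(periods) < 2L || length(alphas) == 1L && length(lambdas) == 1L) {
    return(list(alpha = alphas[ceiling(length(alphas) / 2)], lambda = 1e-3))
  }
  best <- NULL
  for (a in alphas) {
    err <- matrix(NA_real_, length(periods), length(lambdas))
    for (k in seq_along(periods)) {
      te <- period == periods[k]
      fit <- glmnet::glmnet(X[!te, , drop = FALSE], y[!te], alpha = a,
                            lambda = lambdas, standardize = FALSE)
      pr <- predict(fit, X[te, , drop = FALSE])
      # glmnet orders lambda decreasing; map columns back
      lam_used <- fit$lambda
      for (li in seq_along(lambdas)) {
        ci <- which.min(abs(lam_used - lambdas[li]))
        err[k, li] <- mean((y[te] - pr[, ci])^2)
      }
    }
    me <- colMeans(err, na.rm = TRUE)
    if (is.null(best) || min(me) < best$err) {
      best <- list(alpha = a, lambda = lambdas[which.min(me)],
                   err = min(me))
    }
  }
  best
}

#' Common gain correction across fish
#'
#' For each fish, a scalar gain is fit by least squares to the pooled
#' predictions of all other fish and applied to the held-out fish's
#' predictions.
#'
#' @param decoders list of `time_decoder`, one per fish
#' @return the list with `pred` gain-corrected and `r2` updated; gains in
#'   attribute `gains`
#' @export
gain_correct <- function(decoders) {
  n <- length(decoders)
  stopifnot(n >= 2L)
  gains <- numeric(n)
  for (i in seq_len(n)) {
    others <- do.call(rbind, lapply(decoders[-i], function(d)
      cbind(d$pred, d$truth)))
    g <- sum(others[, 1] * others[, 2]) / sum(others[, 1]^2)
    gains[i] <- g
    d <- decoders[[i]]
    d$pred <- d$pred * g
    d$r2 <- 1 - sum((d$truth - d$pred)^2) / sum((d$truth - mean(d$truth))^2)
    decoders[[i]] <- d
  }
  attr(decoders, "gains") <- gains
  decoders
}

#' Within-state circular-shift shuffle control
#'
#' Each neuron's activity inside each period of the state is circularly
#' shifted by an independent offset of at least `min_shift_s` (drawn from
#' the available range when the period is shorter), preserving local
#' autocorrelation but destroying cross-neuron temporal alignment.
#'
#' @param nm a `neuron_matrix`
#' @param labels label series
#' @param state shuffled state
#' @param min_shift_s minimum shift (default 30 s)
#' @param seed integer seed
#' @return shuffled `neuron_matrix`
#' @export
shuffle_control <- function(nm, labels, state = "QEM1", min_shift_s = 30,
                            seed = 1L) {
  set.seed(seed)
  t_s <- (seq_len(ncol(nm$F)) - 1L) / nm$fs_hz
  per <- merge_label_periods(labels, state)
  F2 <- nm$F
  for (p in seq_len(nrow(per))) {
    idx <- which(t_s >= per$start_s[p] & t_s < per$end_s[p])
    len <- length(idx)
    if (len < 4L) next
    min_off <- min(round(min_shift_s * nm$fs_hz), len - 1L)
    for (i in seq_len(nrow(F2))) {
      off <- sample(min_off:(len - 1L), 1L)
      F2[i, idx] <- F2[i, idx][(seq_len(len) - 1L + off) %% len + 1L]
    }
  }
  neuron_matrix(F2, nm$mask, nm$fs_hz, nm$centroids_um, nm$regions)
}

#' Behavior-only relative-time decoder (control)
#'
#' Same protocol as [decode_relative_time()] but on a small behavioral
#' feature matrix instead of neural activity.
#'
#' @param behavior T x k matrix of behavioral features on the neural grid
#' @inheritParams decode_relative_time
#' @return a `time_decoder`
#' @export
decode_relative_time_behavior <- function(behavior, fs_hz, labels,
                                          state = "QEM1",
                                          min_period_s = 180,
                                          n_bins = 100L, seed = 1L) {
  nm <- neuron_matrix(t(as.matrix(behavior)), fs_hz = fs_hz)
  decode_relative_time(nm, labels, state, min_period_s, n_bins, seed = seed)
}
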