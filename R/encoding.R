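# Per-neuron encoding analysis: multivariate regression of each neuron on
# six behavioral and three QEM-1 state regressors with cross-validated R^2
# and shuffle-based partial models; exponential ramp classification; and
# permutation-based anatomical enrichment.

#' Turn bias from a heading series
#'
#' Gaussian-smoothed heading change (kernel sigma 8 min): a slow signed
#' signal reflecting sustained turn-direction bias.
#'
#' @param heading_rad unwrapped heading series in radians
#' @param fs_hz sample rate
#' @param sigma_s kernel SD in seconds (default 480)
#' @return numeric series, same length
#' @export
turn_bias <- function(heading_rad, fs_hz, sigma_s = 480) {
  dh <- c(0, diff(heading_rad))
  gaussian_smooth(dh, sigma_s * fs_hz)
}

#' QEM-1 state regressors
#'
#' Three series on the neural time base: a binary QEM-1 indicator, its
#' running integral within each QEM-1 period (0 outside), and the period
#' onset impulse convolved with an exponential kernel whose time constant
#' is 1/15 of that period's duration.
#'
#' @param labels label series (`start_s`, `end_s`, `label`)
#' @param t_s neural time grid in seconds
#' @return matrix with columns `qem1`, `qem1_integral`, `qem1_onset`
#' @export
build_qem1_regressors <- function(labels, t_s) {
  ind <- numeric(length(t_s))
  integ <- numeric(length(t_s))
  onset <- numeric(length(t_s))
  qem1 <- merge_label_periods(labels, "QEM1")
  dt <- if (length(t_s) > 1) t_s[2] - t_s[1] else 1
  for (p in seq_len(nrow(qem1))) {
    idx <- which(t_s >= qem1$start_s[p] & t_s < qem1$end_s[p])
    if (!length(idx)) next
    ind[idx] <- 1
    integ[idx] <- cumsum(rep(dt, length(idx)))
    tau <- (qem1$end_s[p] - qem1$start_s[p]) / 15
    onset[idx] <- onset[idx] + exp(-(t_s[idx] - qem1$start_s[p]) / tau)
  }
  cbind(qem1 = ind, qem1_integral = integ, qem1_onset = onset)
}

# contiguous periods of one label (adjacent equal-label bins merged)
merge_label_periods <- function(labels, state) {
  seg <- labels[labels$label == state, , drop = FALSE]
  if (!nrow(seg)) return(data.frame(start_s = numeric(), end_s = numeric()))
  seg <- seg[order(seg$start_s), ]
  out <- seg[1, c("start_s", "end_s")]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    if (seg$start_s[i] - out$end_s[nrow(out)] < 1e-6)
      out$end_s[nrow(out)] <- seg$end_s[i]
    else out <- rbind(out, seg[i, c("start_s", "end_s")])
  }
  rownames(out) <- NULL
  out
}

#' Assemble the nine-regressor design
#'
#' @param behavior list with per-sample series on the neural time base:
#'   `speed`, `roll`, `pitch`, `left_eye`, `right_eye`, `heading`
#' @param labels label series (for the QEM-1 regressors)
#' @param t_s neural time grid
#' @param fs_hz neural sample rate
#' @return T x 9 design matrix
#' @export
build_regressors <- function(behavior, labels, t_s, fs_hz) {
  X <- cbind(speed = behavior$speed, roll = behavior$roll,
             pitch = behavior$pitch, left_eye = behavior$left_eye,
             right_eye = behavior$right_eye,
             turn_bias = turn_bias(behavior$heading, fs_hz),
             build_qem1_regressors(labels, t_s))
  stopifnot(ncol(X) == 9)
  X
}

REGRESSOR_GROUPS <- list(eyes = c("left_eye", "right_eye"),
                         turn_bias = "turn_bias",
                         qem1 = c("qem1", "qem1_integral", "qem1_onset"))

#' Cross-validated encoding model for one neuron
#'
#' Ten contiguous time folds; OLS fit on 9 folds, R^2 on the held-out
#' fold. Three partial models re-run the identical procedure with one
#' regressor group time-shuffled (eyes, turn bias, or the QEM-1 triple);
#' a group contributes significantly when the drop in mean fold R^2
#' exceeds twice the standard error of the full model's fold R^2.
#'
#' @param y neuron trace (interpolated, numeric)
#' @param X T x 9 design from [build_regressors()]
#' @param n_folds contiguous folds (default 10)
#' @param seed seed for the shuffles
#' @return list: `beta` (full-data coefficients), `r2` (cross-validated),
#'   `r2_folds`, `partial` (per group: shuffled r2, delta, significant)
#' @export
fit_encoding <- function(y, X, n_folds = 10L, seed = 1L) {
  stopifnot(length(y) == nrow(X))
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (n < 10L * n_folds) stop("need more co-observed samples")
  fold <- cut(seq_len(n), n_folds, labels = FALSE)

  cv_r2 <- function(Xm) {
    r2f <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      cf <- ols_coef(Xm[tr, , drop = FALSE], y[tr])
      pred <- cbind(1, Xm[te, , drop = FALSE]) %*% cf
      sst <- sum((y[te] - mean(y[tr]))^2)
      r2f[f] <- if (sst > 0) 1 - sum((y[te] - pred)^2) / sst else NA_real_
    }
    r2f
  }
  r2_full <- cv_r2(X)
  se_full <- sd(r2_full, na.rm = TRUE) / sqrt(sum(is.finite(r2_full)))
  set.seed(seed)
  partial <- lapply(names(REGRESSOR_GROUPS), function(g) {
    cols <- REGRESSOR_GROUPS[[g]]
    Xs <- X
    p <- sample.int(n)
    Xs[, cols] <- Xs[p, cols, drop = FALSE]
    r2s <- cv_r2(Xs)
    delta <- mean(r2_full, na.rm = TRUE) - mean(r2s, na.rm = TRUE)
    list(group = g, r2 = mean(r2s, na.rm = TRUE), delta = delta,
         significant = is.finite(delta) && delta > 2 * se_full)
  })
  names(partial) <- names(REGRESSOR_GROUPS)
  list(beta = ols_coef(X, y), r2 = mean(r2_full, na.rm = TRUE),
       r2_folds = r2_full, se = se_full, partial = partial)
}

# OLS with a tiny ridge fallback for rank-deficient designs
ols_coef <- function(X, y) {
  Xd <- cbind(1, X)
  cf <- tryCatch(qr.coef(qr(Xd), y), error = function(e) rep(NA_real_, ncol(Xd)))
  if (anyNA(cf)) {
    XtX <- crossprod(Xd) + diag(1e-6, ncol(Xd))
    cf <- solve(XtX, crossprod(Xd, y))
    attr(cf, "ridge") <- TRUE
  }
  cf
}

#' Exponential ramp fit over relative time in QEM-1
#'
#' Each QEM-1 period at least `min_period_s` long becomes a trial: the
#' neuron's activity is linearly resampled to 1000 relative-time points,
#' trials are averaged, the mean trace is peak-normalized (divided by its
#' maximum absolute value, so an exact exponential decay stays within the
#' amplitude bound), and two bounded models are fit by least squares: decay
#' `a exp(-t. / b) + c` and ramp-up `a (1 - exp(-t. / b)) + c`
#' (`0 < a < 1`, `0 < b < 2000`). The class is the better-fitting model.
#'
#' @param y neuron trace (interpolated)
#' @param t_s time grid
#' @param labels label series
#' @param min_period_s minimum period length (default 180)
#' @param n_resample relative-time points (default 1000)
#' @param literal_exponent if TRUE, use the exponent form `exp(-1/(b t.))`
#'   instead of `exp(-t. / b)` (comparison mode; see vignette)
#' @return list of class `ramp_fit`: `model` ("decay" or "ramp_up"),
#'   `a`, `b`, `c`, `r2`, `delta_r2` (decay minus ramp-up), `n_periods`,
#'   or flagged `undefined` when no eligible period exists
#' @export
fit_ramps <- function(y, t_s, labels, min_period_s = 180,
                      n_resample = 1000L, literal_exponent = FALSE) {
  qem1 <- merge_label_periods(labels, "QEM1")
  qem1 <- qem1[qem1$end_s - qem1$start_s >= min_period_s, , drop = FALSE]
  if (!nrow(qem1))
    return(structure(list(undefined = TRUE, n_periods = 0L),
                     class = "ramp_fit"))
  trials <- matrix(NA_real_, nrow(qem1), n_resample)
  for (p in seq_len(nrow(qem1))) {
    idx <- which(t_s >= qem1$start_s[p] & t_s < qem1$end_s[p])
    if (length(idx) < 10L) next
    rel <- (t_s[idx] - qem1$start_s[p]) / (qem1$end_s[p] - qem1$start_s[p])
    trials[p, ] <- approx(rel, y[idx],
                          xout = seq(0, 1, length.out = n_resample),
                          rule = 2)$y
  }
  trials <- trials[rowSums(is.finite(trials)) > 0, , drop = FALSE]
  if (!nrow(trials))
    return(structure(list(undefined = TRUE, n_periods = 0L),
                     class = "ramp_fit"))
  m <- colMeans(trials, na.rm = TRUE)
  pk <- max(abs(m))
  mn <- if (pk > 0) m / pk else m
  tt <- seq(0, 1, length.out = n_resample)
  basis <- function(b) if (literal_exponent)
    exp(-1 / pmax(b * tt, 1e-12)) else exp(-tt / b)
  fit_one <- function(up) {
    obj <- function(par) {
      a <- par[1]; b <- par[2]; cc <- par[3]
      e <- basis(b)
      pred <- if (up) a * (1 - e) + cc else a * e + cc
      sum((mn - pred)^2)
    }
    best <- NULL
    for (b0 in c(0.05, 0.2, 0.5, 1, 5, 50)) {
      op <- tryCatch(optim(c(0.8, b0, 0.1), obj, method = "L-BFGS-B",
                           lower = c(1e-6, 1e-6, -1),
                           upper = c(1 - 1e-6, 2000, 2)),
                     error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    sst <- sum((mn - mean(mn))^2)
    r2 <- if (sst > 0) 1 - best$value / sst else NA_real_
    list(par = best$par, r2 = r2)
  }
  dn <- fit_one(FALSE); up <- fit_one(TRUE)
  pick <- if (dn$r2 >= up$r2) "decay" else "ramp_up"
  sel <- if (pick == "decay") dn else up
  structure(list(undefined = FALSE, model = pick, a = sel$par[1],
                 b = sel$par[2], c = sel$par[3], r2 = sel$r2,
                 delta_r2 = dn$r2 - up$r2, n_periods = nrow(trials)),
            class = "ramp_fit")
}

#' Anatomical enrichment of flagged neurons
#'
#' For each region: `P(X)` is the fraction of flagged (positive) neurons in
#' the region; the null resamples `n_tot,region` neurons from the whole
#' recording without replacement 100 times, giving `P0(X)`; fold
#' enrichment is `E(X) = P(X) / mean(P0(X))`. A region is significant for
#' one fish when `P(X) > P0(X)` in at least 95 of the 100 draws.
#'
#' @param positive logical vector, one per neuron
#' @param regions character vector of region labels
#' @param n_draws null draws (default 100)
#' @param seed integer seed
#' @return data.frame per region: `n_pos`, `n_tot`, `p_x`, `e_x`,
#'   `n_null_below` (draws with `P(X) > P0`), `significant`
#' @export
enrichment <- function(positive, regions, n_draws = 100L, seed = 1L) {
  stopifnot(length(positive) == length(regions))
  set.seed(seed)
  n <- length(positive)
  out <- list()
  for (reg in sort(unique(regions))) {
    in_reg <- regions == reg
    n_tot <- sum(in_reg)
    if (n_tot == 0L) next
    n_pos <- sum(positive & in_reg)
    p_x <- n_pos / n_tot
    p0 <- vapply(seq_len(n_draws), function(d)
      sum(positive[sample.int(n, n_tot)]) / n_tot, numeric(1))
    out[[reg]] <- data.frame(
      region = reg, n_pos = n_pos, n_tot = n_tot, p_x = p_x,
      e_x = if (mean(p0) > 0) p_x / mean(p0) else NA_real_,
      n_null_below = sum(p_x > p0),
      significant = sum(p_x > p0) >= 0.95 * n_draws)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Across-fish enrichment verdict
#'
#' A region is significant across fish when at least `ceiling(frac * n)`
#' fish are individually significant (the published criterion corresponds
#' to 8 of 11 fish).
#'
#' @param per_fish list of per-fish [enrichment()] tables
#' @param frac required fraction (default 0.7)
#' @return data.frame per region: `n_fish`, `n_significant`, `significant`
#' @export
enrichment_across_fish <- function(per_fish, frac = 0.7) {
  all_reg <- sort(unique(unlist(lapply(per_fish, `[[`, "region"))))
  n_fish <- length(per_fish)
  need <- ceiling(frac * n_fish)
  do.call(rbind, lapply(all_reg, function(reg) {
    sig <- vapply(per_fish, function(tb) {
      i <- match(reg, tb$region)
      !is.na(i) && tb$significant[i]
    }, logical(1))
    data.frame(region = reg, n_fish = n_fish, n_significant = sum(sig),
               significant = sum(sig) >= need)
  }))
}
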