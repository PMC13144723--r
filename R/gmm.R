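# Diagonal-covariance Gaussian mixture for substate classification.
#
# The three bin features (saccade count, mean decay slope, mean fixation
# duration) are z-standardized; the 3-component mixture is initialized with
# a diagonally dominant mean matrix (component k at +1 SD on feature k),
# fitted by EM with a variance floor of 2e-5, and model order is selected
# with the sample-size-adjusted BIC, SABIC = -2 logL + p log((n + 2) / 24).

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' @param X numeric matrix (observations x features), already standardized
#'   if standardization is wanted
#' @param k number of components
#' @param var_floor variance floor applied per dimension (default 2e-5)
#' @param n_restarts number of EM starts; the first uses the diagonally
#'   dominant initialization when `k <= ncol(X)`, the rest draw component
#'   means from random observations
#' @param seed integer seed for the random restarts
#' @param max_iter,tol EM termination controls
#' @return list with `weights`, `means` (k x d), `vars` (k x d),
#'   `loglik`, `n`, `k`
#' @export
gmm_fit_diag <- function(X, k, var_floor = 2e-5, n_restarts = 10L,
                         seed = 0L, max_iter = 500L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= k)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1L && k <= d) {
      m <- matrix(0, k, d)
      for (j in seq_len(k)) m[j, j] <- 1
      m
    } else if (r == 2L && n > 5 * k) {
      stats::kmeans(X, k, nstart = 5)$centers
    } else X[sample.int(n, k), , drop = FALSE] +
      matrix(rnorm(k * d, 0, 0.01), k, d)
    fit <- try(gmm_em_once(X, k, mu0, var_floor, max_iter, tol), silent = TRUE)
    if (inherits(fit, "try-error")) next
    # degeneracy guard: a component supported by fewer points than
    # 2 (dimensions + 1) is a near-singular spike, not a cluster
    degenerate <- min(fit$weights) * n < 2 * (d + 1)
    if (degenerate && !is.null(best)) next
    if (is.null(best) || best$degenerate && !degenerate ||
        (fit$loglik > best$loglik && best$degenerate == degenerate)) {
      fit$degenerate <- degenerate
      best <- fit
    }
  }
  if (is.null(best)) stop("EM failed for all restarts")
  best
}

gmm_em_once <- function(X, k, mu, var_floor, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  w <- rep(1 / k, k)
  v <- matrix(rep(apply(X, 2, var), each = k), k, d)
  v <- pmax(v, var_floor)
  X2 <- X^2
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    # E step, vectorized over components:
    # logp_ij = log w_j - 0.5 sum_d [log(2 pi v_jd) + (x_id - mu_jd)^2/v_jd]
    cst <- log(w) - 0.5 * rowSums(log(2 * pi * v)) - 0.5 * rowSums(mu^2 / v)
    logp <- X2 %*% t(-0.5 / v) + X %*% t(mu / v) +
      matrix(cst, n, k, byrow = TRUE)
    m <- logp[cbind(seq_len(n), max.col(logp, "first"))]
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    # M step
    nk <- pmax(colSums(resp), 1e-8)
    w <- nk / n
    mu <- (t(resp) %*% X) / nk
    v <- pmax((t(resp) %*% X2) / nk - mu^2, var_floor)
    if (is.finite(prev) && abs(ll - prev) < tol * (1 + abs(ll))) break
    prev <- ll
  }
  list(weights = w, means = mu, vars = v, loglik = ll, n = n, k = k)
}

gmm_logdens <- function(fit, X) {
  n <- nrow(X); k <- fit$k
  logp <- matrix(0, n, k)
  for (j in seq_len(k)) {
    z <- sweep(X, 2, fit$means[j, ], "-")
    logp[, j] <- log(fit$weights[j]) - 0.5 * sum(log(2 * pi * fit$vars[j, ])) -
      0.5 * rowSums(sweep(z^2, 2, fit$vars[j, ], "/"))
  }
  logp
}

#' Sample-size-adjusted BIC of a diagonal mixture fit
#'
#' `SABIC = -2 logL + p log((n + 2) / 24)` with
#' `p = (k - 1) + 2 k d` free parameters.
#' @param fit result of [gmm_fit_diag()]
#' @return numeric scalar
#' @export
sabic <- function(fit) {
  d <- ncol(fit$means)
  p <- (fit$k - 1) + 2 * fit$k * d
  -2 * fit$loglik + p * log((fit$n + 2) / 24)
}

#' SABIC model-order sweep
#'
#' Fits mixtures with `k = 1..k_max` components and reports the SABIC of
#' each.
#' @inheritParams gmm_fit_diag
#' @param k_max largest model order (default 6)
#' @return data.frame with `k`, `loglik`, `sabic`; the selected order is
#'   `k[which.min(sabic)]`
#' @export
sabic_sweep <- function(X, k_max = 6L, var_floor = 2e-5, n_restarts = 10L,
                        seed = 0L) {
  res <- lapply(seq_len(k_max), function(k)
    gmm_fit_diag(X, k, var_floor, n_restarts, seed = seed + k))
  data.frame(k = seq_len(k_max),
             loglik = vapply(res, `[[`, numeric(1), "loglik"),
             sabic = vapply(res, sabic, numeric(1)))
}

#' Fit the substate mixture on bin features
#'
#' Standardizes the features of all saccade-containing bins, fits the
#' 3-component diagonal mixture (diagonally dominant initialization,
#' variance floor 2e-5), maps components to substates by their dominant
#' feature -- highest count mean is QEM-1, steepest decay-slope mean QEM-2,
#' longest fixation mean QEM-3 -- and reports the SABIC sweep for
#' `k = 1..6`.
#'
#' @param features data.frame from [featurize()] (only bins with
#'   `count >= 1` are used; at least 30 such bins are required)
#' @param seed integer seed
#' @param k number of components (default 3)
#' @param sweep logical: also compute the SABIC sweep (default TRUE)
#' @return object of class `substate_gmm`: standardization constants,
#'   mixture parameters, `component_map` (component index -> substate),
#'   optional `sabic_table`
#' @export
fit_substate_gmm <- function(features, seed = 0L, k = 3L, sweep = TRUE) {
  Xr <- as.matrix(features[features$count >= 1L,
                           c("count", "mean_slope_deg_s", "mean_fixation_s")])
  if (nrow(Xr) < 30L) stop("need at least 30 saccade-containing bins")
  ctr <- colMeans(Xr); scl <- apply(Xr, 2, sd)
  scl[scl < 1e-12] <- 1
  X <- sweep(sweep(Xr, 2, ctr, "-"), 2, scl, "/")
  fit <- gmm_fit_diag(X, k, seed = seed)
  # component -> substate by dominant (original-unit) feature
  mu_orig <- sweep(sweep(fit$means, 2, scl, "*"), 2, ctr, "+")
  claim <- c(count = which.max(mu_orig[, 1]),
             slope = which.max(mu_orig[, 2]),
             fixation = which.max(mu_orig[, 3]))
  if (length(unique(claim)) != k)
    stop("component labeling is ambiguous: a component dominates several ",
         "features while another dominates none")
  component_map <- character(k)
  component_map[claim["count"]] <- "QEM1"
  component_map[claim["slope"]] <- "QEM2"
  component_map[claim["fixation"]] <- "QEM3"
  out <- list(center = ctr, scale = scl, weights = fit$weights,
              means = fit$means, vars = fit$vars, loglik = fit$loglik,
              n = fit$n, k = k, component_map = component_map, seed = seed)
  if (sweep) out$sabic_table <- sabic_sweep(X, 6L, seed = seed)
  structure(out, class = "substate_gmm")
}

#' Classify sleep bins into substates
#'
#' Bins without saccades are QNEM; bins with saccades get the substate of
#' the maximum-posterior mixture component (ties broken in component
#' order QEM1 < QEM2 < QEM3).
#'
#' @param features data.frame from [featurize()]
#' @param gmm a fitted `substate_gmm`
#' @return the features with `label` and posterior columns
#'   `p_QEM1`, `p_QEM2`, `p_QEM3` added
#' @export
classify_bins <- function(features, gmm) {
  if (!inherits(gmm, "substate_gmm")) stop("gmm must be a fitted substate_gmm")
  out <- features
  out$label <- "QNEM"
  out$p_QEM1 <- out$p_QEM2 <- out$p_QEM3 <- 0
  has <- which(out$count >= 1L)
  if (length(has)) {
    Xr <- as.matrix(out[has, c("count", "mean_slope_deg_s", "mean_fixation_s")])
    X <- sweep(sweep(Xr, 2, gmm$center, "-"), 2, gmm$scale, "/")
    logp <- gmm_logdens(gmm, X)
    m <- apply(logp, 1, max)
    post <- exp(logp - m); post <- post / rowSums(post)
    # order posteriors as QEM1, QEM2, QEM3
    ord <- match(c("QEM1", "QEM2", "QEM3"), gmm$component_map)
    post <- post[, ord, drop = FALSE]
    out$p_QEM1[has] <- post[, 1]; out$p_QEM2[has] <- post[, 2]
    out$p_QEM3[has] <- post[, 3]
    out$label[has] <- c("QEM1", "QEM2", "QEM3")[max.col(post, "first")]
  }
  out
}

#' Assemble a full label series over a recording
#'
#' Sleep bins carry their substate label; the rest of the recording is
#' labeled Wake on a regular grid; optional tracking gaps become Unlabeled.
#'
#' @param classified output of [classify_bins()]
#' @param duration_s recording length
#' @param step_s grid step for non-sleep time (default 60)
#' @param gaps_s optional data.frame `start_s`, `end_s` of tracking gaps
#' @return data.frame `start_s`, `end_s`, `label` ordered in time
#'   (a *state label series*)
#' @export
label_series <- function(classified, duration_s, step_s = 60, gaps_s = NULL) {
  sleep <- classified[order(classified$start_s),
                      c("start_s", "end_s", "label")]
  pieces <- list(sleep)
  bounds <- c(0, as.vector(t(sleep[, 1:2])), duration_s)
  for (i in seq(1, length(bounds) - 1, by = 2)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    if (hi - lo <= 1e-9) next
    starts <- seq(lo, hi, by = step_s)
    starts <- starts[starts < hi]
    ends <- pmin(starts + step_s, hi)
    pieces[[length(pieces) + 1L]] <-
      data.frame(start_s = starts, end_s = ends, label = "Wake")
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$start_s), ]
  if (!is.null(gaps_s)) {
    for (g in seq_len(nrow(gaps_s))) {
      hit <- out$start_s < gaps_s$end_s[g] & out$end_s > gaps_s$start_s[g]
      out$label[hit] <- "Unlabeled"
    }
  }
  rownames(out) <- NULL
  out
}

#' Serialize / load a fitted substate mixture as JSON
#' @param gmm a `substate_gmm`
#' @param path file path
#' @return `read_substate_gmm` returns a `substate_gmm`
#' @export
write_substate_gmm <- function(gmm, path) {
  jsonlite::write_json(unclass(gmm), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_substate_gmm
#' @export
read_substate_gmm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feat <- c("count", "mean_slope_deg_s", "mean_fixation_s")
  x$means <- matrix(unlist(x$means), nrow = x$k,
                    dimnames = list(NULL, feat))
  x$vars <- matrix(unlist(x$vars), nrow = x$k, dimnames = list(NULL, feat))
  x$center <- setNames(as.numeric(x$center), feat)
  x$scale <- setNames(as.numeric(x$scale), feat)
  structure(x, class = "substate_gmm")
}
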