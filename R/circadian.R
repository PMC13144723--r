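# Latent-variable neural-network model of state gating.
#
# Five-state probabilities (Wake, QEM-1/2/3, QNEM) are modeled from three
# inputs -- luminosity (0/1), introduction day (1 on the loading day, else
# 0), and circadian time encoded as a 24-h cosine/sine pair -- through a
# bottleneck architecture: dense encoder (24 units) -> 1-D latent ->
# dense decoder (24 units) -> 5-unit softmax. The scalar latent forces the
# model to order the inputs along a single gating axis. Trained by Adam on
# the cross-entropy; summing the cross-entropy over fish is equivalent to
# a cross-entropy against the per-timestep empirical state distribution,
# which keeps training cost independent of the number of fish.

#' Build model inputs and targets from a label series
#'
#' @param labels a label series (`start_s`, `end_s`, `label`) at 1-min
#'   resolution (coarser labels are sampled at bin midpoints)
#' @param schedule the `state_schedule` of the recording (provides the
#'   lights and introduction-day step functions and the clock offset)
#' @param step_s time step (default 60 s)
#' @param condition optional condition tag (e.g. "LD"); defaults to the
#'   schedule's light mode
#' @return list: `inputs` (T x 4 matrix: lights, day1, cos, sin),
#'   `states` (factor over the five states), `t_s`; Unlabeled steps dropped
#' @export
build_inputs <- function(labels, schedule, step_s = 60, condition = NULL) {
  if (is.null(schedule$lights_fun)) stop("schedule must provide lights_fun")
  t_grid <- seq(0, schedule$duration_s - step_s, by = step_s) + step_s / 2
  lab <- rep("Unlabeled", length(t_grid))
  for (i in seq_len(nrow(labels))) {
    hit <- t_grid >= labels$start_s[i] & t_grid < labels$end_s[i]
    lab[hit] <- labels$label[i]
  }
  keep <- lab != "Unlabeled"
  t_grid <- t_grid[keep]; lab <- lab[keep]
  phase <- 2 * pi * (t_grid / 3600 + schedule$clock_offset_h) / 24
  inputs <- cbind(lights = schedule$lights_fun(t_grid),
                  day1 = schedule$day1_fun(t_grid),
                  cos = cos(phase), sin = sin(phase))
  list(inputs = inputs,
       states = factor(lab, STATE_LEVELS[1:5]),
       t_s = t_grid,
       condition = condition %||% (schedule$light_cycle_spec$mode %||% "LD"))
}

act_fun <- function(name) switch(name,
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 df = function(a) a * (1 - a)),
  relu = list(f = function(z) pmax(z, 0),
              df = function(a) (a > 0) * 1),
  stop("unknown activation: ", name))

mlp_init <- function(hidden, activation, seed) {
  set.seed(seed)
  glorot <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
  list(W1 = glorot(4, hidden), b1 = rep(0, hidden),
       W2 = glorot(hidden, 1), b2 = 0,
       W3 = glorot(1, hidden), b3 = rep(0, hidden),
       W4 = glorot(hidden, 5), b4 = rep(0, 5),
       activation = activation, hidden = hidden)
}

mlp_forward <- function(par, X) {
  a <- act_fun(par$activation)
  n <- nrow(X)
  A1 <- a$f(X %*% par$W1 + rep(par$b1, each = n))
  A2 <- a$f(A1 %*% par$W2 + par$b2)
  A3 <- a$f(A2 %*% par$W3 + rep(par$b3, each = n))
  Z4 <- A3 %*% par$W4 + rep(par$b4, each = n)
  m <- Z4[cbind(seq_len(n), max.col(Z4, "first"))]
  E <- exp(Z4 - m)
  P <- E / rowSums(E)
  list(A1 = A1, A2 = A2, A3 = A3, P = P)
}

# gradient of mean weighted cross-entropy wrt all parameters
# (forward and backward fused; sigmoid/relu derivatives inlined)
mlp_grad <- function(par, X, Tg, w, tX) {
  sig <- par$activation == "sigmoid"
  n <- nrow(X)
  A1 <- X %*% par$W1 + rep(par$b1, each = n)
  A1 <- if (sig) 1 / (1 + exp(-A1)) else pmax(A1, 0)
  A2 <- A1 %*% par$W2 + par$b2
  A2 <- if (sig) 1 / (1 + exp(-A2)) else pmax(A2, 0)
  A3 <- A2 %*% par$W3 + rep(par$b3, each = n)
  A3 <- if (sig) 1 / (1 + exp(-A3)) else pmax(A3, 0)
  Z4 <- A3 %*% par$W4 + rep(par$b4, each = n)
  m <- Z4[cbind(seq_len(n), max.col(Z4, "first"))]
  E <- exp(Z4 - m)
  P <- E / rowSums(E)
  nw <- sum(w)
  D4 <- (P - Tg) * (w / nw)
  D3 <- (D4 %*% t(par$W4)) * (if (sig) A3 * (1 - A3) else (A3 > 0))
  D2 <- (D3 %*% t(par$W3)) * (if (sig) A2 * (1 - A2) else (A2 > 0))
  D1 <- (D2 %*% t(par$W2)) * (if (sig) A1 * (1 - A1) else (A1 > 0))
  loss <- -sum(w * rowSums(Tg * log(pmax(P, 1e-12)))) / nw
  list(grads = list(W1 = tX %*% D1, b1 = colSums(D1),
                    W2 = crossprod(A1, D2), b2 = sum(D2),
                    W3 = crossprod(A2, D3), b3 = colSums(D3),
                    W4 = crossprod(A3, D4), b4 = colSums(D4)),
       loss = loss)
}

mlp_train <- function(par, X, Tg, w, lr = 1e-3, max_epochs = 2000,
                      patience = 200, tol = 1e-6) {
  keys <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  m <- lapply(par[keys], function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; since <- 0L
  tX <- t(X)
  for (ep in seq_len(max_epochs)) {
    g <- mlp_grad(par, X, Tg, w, tX)
    for (k in keys) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g$grads[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g$grads[[k]]^2
      mhat <- m[[k]] / (1 - b1^ep); vhat <- v[[k]] / (1 - b2^ep)
      par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    if (g$loss < best - tol) { best <- g$loss; since <- 0L }
    else { since <- since + 1L; if (since >= patience) break }
  }
  par$loss <- best
  par$converged <- best < Inf && is.finite(best)
  par
}

# Compress per-fish one-hot targets into per-unique-input-row empirical
# state distributions with multiplicity weights. The cross-entropy against
# these weighted distributions equals the summed per-fish cross-entropy.
compress_training_set <- function(fish_data, fish_idx) {
  Xs <- list(); Ts <- list()
  for (i in fish_idx) {
    fd <- fish_data[[i]]
    Tg <- matrix(0, nrow(fd$inputs), 5)
    Tg[cbind(seq_len(nrow(Tg)), as.integer(fd$states))] <- 1
    Xs[[length(Xs) + 1L]] <- fd$inputs
    Ts[[length(Ts) + 1L]] <- Tg
  }
  X <- do.call(rbind, Xs); Tg <- do.call(rbind, Ts)
  key <- apply(round(X, 9), 1, paste, collapse = "|")
  grp <- match(key, unique(key))
  Xu <- X[!duplicated(grp), , drop = FALSE]
  Tu <- rowsum(Tg, grp)
  w <- rowSums(Tu)
  list(X = Xu, Tg = Tu / w, w = w)
}

#' Fit the five-state gating model with a cross-validated ensemble
#'
#' Repeated k-fold cross-validation over fish: for each repetition x fold,
#' a model is trained on the training fish and evaluated on the held-out
#' fish (correlation between predicted and observed state probabilities).
#'
#' @param fish_data list, one element per fish, each from [build_inputs()]
#' @param n_folds folds over fish (default 5; requires >= 5 fish)
#' @param n_reps repetitions of the fold split (default 20)
#' @param seed integer seed
#' @param hidden encoder/decoder width (default 24)
#' @param activation `"sigmoid"` (default) or `"relu"`
#' @param lr,max_epochs,patience optimizer controls (Adam)
#' @param smooth_steps moving-average window (in steps) applied to the
#'   observed state probabilities before correlating (default 30)
#' @return object of class `state_prob_ensemble`: list of members, each
#'   with trained parameters, held-out fish indices, and per-state r
#' @export
fit_state_prob_model <- function(fish_data, n_folds = 5, n_reps = 20,
                                 seed = 1L, hidden = 24,
                                 activation = c("sigmoid", "relu"),
                                 lr = 1e-3, max_epochs = 2000,
                                 patience = 200, smooth_steps = 30) {
  activation <- match.arg(activation)
  n_fish <- length(fish_data)
  if (n_fish < n_folds) stop("need at least ", n_folds, " fish")
  set.seed(seed)
  members <- list()
  for (rep in seq_len(n_reps)) {
    fold_of <- sample(rep_len(seq_len(n_folds), n_fish))
    for (fold in seq_len(n_folds)) {
      test_idx <- which(fold_of == fold)
      train_idx <- setdiff(seq_len(n_fish), test_idx)
      tr <- compress_training_set(fish_data, train_idx)
      par <- mlp_init(hidden, activation,
                      seed = seed + 1000L * rep + fold)
      par <- mlp_train(par, tr$X, tr$Tg, tr$w, lr = lr,
                       max_epochs = max_epochs, patience = patience)
      r <- evaluate_state_prob(par, fish_data, test_idx, smooth_steps)
      members[[length(members) + 1L]] <-
        list(par = par, rep = rep, fold = fold, test_idx = test_idx,
             r_by_state = r)
    }
  }
  structure(list(members = members, n_fish = n_fish, seed = seed,
                 activation = activation, hidden = hidden,
                 smooth_steps = smooth_steps),
            class = "state_prob_ensemble")
}

#' Predict state probabilities for an input matrix
#' @param par trained member parameters (`member$par`)
#' @param inputs T x 4 input matrix
#' @return list: `prob` (T x 5, rows sum to 1), `latent` (T)
#' @export
predict_state_prob <- function(par, inputs) {
  fw <- mlp_forward(par, inputs)
  colnames(fw$P) <- STATE_LEVELS[1:5]
  list(prob = fw$P, latent = as.numeric(fw$A2))
}

#' Correlation between predicted and observed state probabilities
#'
#' Observed probability per time step is the fraction of held-out fish in
#' each state (within each condition), smoothed with a moving average; the
#' Pearson correlation with the model prediction is computed per state and
#' condition, then averaged over conditions.
#'
#' @param par trained parameters
#' @param fish_data the full fish list
#' @param test_idx indices of held-out fish
#' @param smooth_steps moving-average window in steps
#' @return named numeric vector of per-state r (NA where a state has no
#'   variance in the observations)
#' @export
evaluate_state_prob <- function(par, fish_data, test_idx, smooth_steps = 30) {
  conds <- unique(vapply(fish_data[test_idx], `[[`, character(1), "condition"))
  acc <- matrix(NA_real_, length(conds), 5,
                dimnames = list(conds, STATE_LEVELS[1:5]))
  for (ci in seq_along(conds)) {
    idx <- test_idx[vapply(fish_data[test_idx], `[[`, character(1),
                           "condition") == conds[ci]]
    # align on the common time grid of the condition
    t_ref <- fish_data[[idx[1]]]$t_s
    obs <- matrix(0, length(t_ref), 5)
    cnt <- numeric(length(t_ref))
    for (i in idx) {
      fd <- fish_data[[i]]
      pos <- match(round(fd$t_s, 6), round(t_ref, 6))
      ok <- !is.na(pos)
      oh <- matrix(0, length(t_ref), 5)
      oh[cbind(pos[ok], as.integer(fd$states)[ok])] <- 1
      obs <- obs + oh
      cnt[pos[ok]] <- cnt[pos[ok]] + 1L
    }
    ok <- cnt > 0
    obs <- obs[ok, , drop = FALSE] / cnt[ok]
    pred <- predict_state_prob(par, fish_data[[idx[1]]]$inputs)$prob
    pred <- pred[match(t_ref[ok], fish_data[[idx[1]]]$t_s), , drop = FALSE]
    for (s in 1:5) {
      o <- running_mean(obs[, s], smooth_steps)
      if (sd(o) < 1e-10 || sd(pred[, s]) < 1e-10) next
      acc[ci, s] <- cor(pred[, s], o)
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Input-ablation analysis
#'
#' Refits the full cross-validated ensemble with one input time-shuffled
#' (the cosine/sine pair is permuted jointly for `"circadian"`), using the
#' same seed and therefore the same fold assignments as the reference
#' ensemble, and reports the per-state drop in held-out correlation with a
#' paired Wilcoxon signed-rank test across ensemble members.
#'
#' @param fish_data list of per-fish inputs (as passed to the full fit)
#' @param full a fitted `state_prob_ensemble`
#' @param which one of `"circadian"`, `"luminosity"`, `"introduction"`
#' @param seed seed for the shuffles (default: ensemble seed + 1)
#' @param ... passed through to [fit_state_prob_model()]
#' @return list: `ablated` ensemble, `delta_r` (members x states),
#'   `summary` data.frame per state with mean full r, mean ablated r,
#'   mean delta and signed-rank p
#' @export
ablate_input <- function(fish_data, full,
                         which = c("circadian", "luminosity", "introduction"),
                         seed = NULL, ...) {
  which <- match.arg(which)
  cols <- switch(which, luminosity = 1L, introduction = 2L,
                 circadian = 3:4)
  seed <- seed %||% (full$seed + 1L)
  set.seed(seed)
  shuffled <- lapply(fish_data, function(fd) {
    p <- sample.int(nrow(fd$inputs))
    fd$inputs[, cols] <- fd$inputs[p, cols, drop = FALSE]
    fd
  })
  abl <- fit_state_prob_model(shuffled, seed = full$seed,
                              hidden = full$hidden,
                              activation = full$activation,
                              smooth_steps = full$smooth_steps, ...)
  r_full <- t(vapply(full$members, `[[`, numeric(5), "r_by_state"))
  r_abl <- t(vapply(abl$members, `[[`, numeric(5), "r_by_state"))
  delta <- r_full - r_abl
  summ <- data.frame(
    state = STATE_LEVELS[1:5],
    r_full = colMeans(r_full, na.rm = TRUE),
    r_ablated = colMeans(r_abl, na.rm = TRUE),
    delta_r = colMeans(delta, na.rm = TRUE),
    p_signed_rank = vapply(1:5, function(s) {
      d <- delta[, s]; d <- d[is.finite(d)]
      if (length(d) < 3 || all(d == 0)) return(NA_real_)
      suppressWarnings(wilcox.test(d)$p.value)
    }, numeric(1)))
  list(ablated = abl, delta_r = delta, summary = summ, which = which)
}

#' Serialize / load a fitted gating-model ensemble as JSON
#'
#' Stores every member's weights, fold assignment and held-out
#' correlations, plus the ensemble metadata (seed, activation, width,
#' smoothing window).
#'
#' @param ensemble a `state_prob_ensemble`
#' @param path file path
#' @return `read_state_prob_ensemble` returns a `state_prob_ensemble`
#' @export
write_state_prob_ensemble <- function(ensemble, path) {
  ser <- unclass(ensemble)
  ser$members <- lapply(ensemble$members, function(m) {
    m$par <- lapply(m$par, function(p) if (is.matrix(p)) list(
      dim = dim(p), data = as.numeric(p)) else p)
    m
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_prob_ensemble
#' @export
read_state_prob_ensemble <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  members <- lapply(x$members, function(m) {
    par <- m$par
    for (k in c("W1", "W2", "W3", "W4"))
      par[[k]] <- matrix(unlist(par[[k]]$data),
                         nrow = unlist(par[[k]]$dim)[1])
    for (k in c("b1", "b2", "b3", "b4", "loss"))
      par[[k]] <- as.numeric(unlist(par[[k]]))
    par$activation <- as.character(par$activation)
    par$hidden <- as.numeric(par$hidden)
    par$converged <- isTRUE(unlist(par$converged))
    list(par = par, rep = unlist(m$rep), fold = unlist(m$fold),
         test_idx = unlist(m$test_idx),
         r_by_state = setNames(
           vapply(m$r_by_state, function(v)
             if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)),
           STATE_LEVELS[1:5]))
  })
  structure(list(members = members, n_fish = unlist(x$n_fish),
                 seed = unlist(x$seed),
                 activation = unlist(x$activation),
                 hidden = unlist(x$hidden),
                 smooth_steps = unlist(x$smooth_steps)),
            class = "state_prob_ensemble")
}
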