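# Shared numeric helpers. All angle series are radians internally; degrees
# appear only at reporting boundaries.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Centered running mean with partial windows at the edges
#' @param x numeric vector
#' @param n window length in samples (coerced to >= 1)
#' @return numeric vector, same length as `x`
#' @keywords internal
running_mean <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  half <- n %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Centered running mean of |x| (used for the residual-noise criterion)
#' @keywords internal
running_abs_mean <- function(x, n) running_mean(abs(x), n)

#' Central-difference velocity of a uniformly sampled series
#'
#' One-sided differences at the two ends.
#' @param x numeric vector, fs sample rate in Hz
#' @return numeric vector of d x / d t, same length
#' @keywords internal
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  v[1L] <- (x[2L] - x[1L]) * fs
  v[n] <- (x[n] - x[n - 1L]) * fs
  v
}

#' Discrete Gaussian smoothing kernel
#' @param sigma_samples kernel SD in samples
#' @keywords internal
gaussian_kernel <- function(sigma_samples, radius = ceiling(4 * sigma_samples)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_samples^2))
  k / sum(k)
}

#' Gaussian-smooth a series (reflecting boundaries)
#' @keywords internal
gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  k <- gaussian_kernel(sigma_samples)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  pad <- c(x[pmin(r:1, n)], x, x[pmax(n - seq_len(r) + 1L, 1L)])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1L):(r + n)]
}

#' Sample from a lognormal matched to a target mean and sd
#'
#' Positive kinematic quantities (durations, slopes, speeds) are drawn from
#' moment-matched lognormals so the generative mean equals the preset mean
#' without truncation bias.
#' @keywords internal
rlnorm_mean_sd <- function(n, mean, sd) {
  if (mean <= 0) stop("lognormal sampler requires mean > 0")
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Linearly interpolate missing values (constant extrapolation at the ends)
#' @keywords internal
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(x)
  out <- approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  out
}

#' Maximal runs of TRUE in a logical vector
#' @return data.frame with columns start, end (sample indices, inclusive)
#' @keywords internal
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

odd_window <- function(n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n + 1L else n
}
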