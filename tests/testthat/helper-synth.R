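# Shared fixture builders. Tests run behavior at 10 Hz where the chain
# allows it, 50 Hz where peak-speed measurement matters.

qem_run <- function(state, minutes, seed, fs = 50,
                    kin = default_kinematics()) {
  sch <- schedule_from_segments(state, minutes * 60)
  beh <- synth_behavior(sch, kin, fs_hz = fs, seed = seed)
  ev <- detect_saccades(beh$trace, "multi", period_ends_s = minutes * 60)
  list(beh = beh, events = ev)
}

match_events <- function(detected, injected, tol_s = 0.5) {
  m <- vapply(injected$onset_s, function(t) {
    d <- abs(detected$onset_s - t)
    if (length(d) && min(d) < tol_s) which.min(d) else NA_integer_
  }, integer(1))
  m
}

label_series_of <- function(schedule) {
  data.frame(start_s = schedule$segments$start_s,
             end_s = schedule$segments$end_s,
             label = schedule$segments$state)
}

# independent oracle for 1-D total-variation denoising: box-constrained
# dual quadratic program solved with L-BFGS-B
tv_oracle <- function(y, lam) {
  n <- length(y)
  if (n == 1 || lam <= 0) return(y)
  Dy <- diff(y)
  fn <- function(u) {
    Dtu <- -(c(u, 0) - c(0, u))
    0.5 * sum(Dtu^2) - sum(u * Dy)
  }
  gr <- function(u) {
    Dtu <- -(c(u, 0) - c(0, u))
    (Dtu[2:n] - Dtu[1:(n - 1)]) - Dy
  }
  res <- optim(rep(0, n - 1), fn, gr, method = "L-BFGS-B",
               lower = -lam, upper = lam,
               control = list(maxit = 10000, factr = 1e1))
  u <- res$par
  y - (-(c(u, 0) - c(0, u)))
}

# brute-force O(N^2) segment-intersection count (shared-endpoint pairs
# excluded), independent of the compiled implementation
crossings_oracle <- function(x, y) {
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p1, p2, p3); d2 <- d(p1, p2, p4)
    d3 <- d(p3, p4, p1); d4 <- d(p3, p4, p2)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  m <- length(x) - 1
  cnt <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i + 1) next
    if (seg_int(c(x[i], y[i]), c(x[i + 1], y[i + 1]),
                c(x[j], y[j]), c(x[j + 1], y[j + 1]))) cnt <- cnt + 1
  }
  cnt
}

# union-find oracle for duplicate grouping
dup_groups_oracle <- function(centroids, F, mask, dist_um = 4, cor_min = 0.8) {
  n <- nrow(centroids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (all(abs(centroids[i, ] - centroids[j, ]) <= dist_um)) {
      both <- mask[i, ] & mask[j, ]
      if (sum(both) >= 10 && sd(F[i, both]) > 0 && sd(F[j, both]) > 0 &&
          cor(F[i, both], F[j, both]) > cor_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}
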