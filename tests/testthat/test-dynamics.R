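ramp_population <- function(n_neurons = 20, seed = 1, noise = 0,
                            periods = 3, period_s = 360, wake_s = 240) {
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), periods),
                                rep(c(wake_s, period_s), periods))
  spec <- synth_neural_spec(n_suppressed = 0, n_ramp_down = n_neurons / 2,
                            n_ramp_up = n_neurons / 2, n_event = 0,
                            n_noise = 0, noise_sd = noise)
  sn <- synth_neural(spec, sch, seed = seed)
  list(sn = sn, labels = label_series_of(sch))
}

test_that("state PCA finds the ramp axis with the time-locked sign", {
  d <- ramp_population(seed = 2)
  pca <- state_pca(d$sn$matrix, d$labels, "QEM1")
  expect_gt(pca$explained[1], 0.9)
  # loadings orthonormal, projection 2-D
  expect_equal(crossprod(pca$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ncol(pca$projection), 2L)
  # PC1 score increases with time within a period
  t_s <- (seq_len(nrow(pca$projection)) - 1) / 2
  p1 <- pca$periods[1, ]
  idx <- which(t_s >= p1$start_s & t_s < p1$end_s)
  expect_gt(cor(pca$projection[idx, 1], t_s[idx]), 0.9)
})

test_that("isotropic noise spreads variance evenly over components", {
  set.seed(3)
  sch <- schedule_from_segments(c("Wake", "QEM1"), c(120, 600))
  nm <- neuron_matrix(matrix(rnorm(30 * 1440), 30), fs_hz = 2)
  labs <- label_series_of(sch)
  pca <- state_pca(nm, labs, "QEM1")
  expect_lt(pca$explained[1] / pca$explained[2], 2)
})

test_that("entanglement counts unique crossings like the brute-force oracle", {
  # straight line: none
  line <- cbind(seq(0, 10, length.out = 50), seq(0, 5, length.out = 50))
  e <- entanglement(line, fs_hz = 2, sigma_s = 0)
  expect_equal(e$crossings, 0L)
  # figure-eight polyline: exactly one self-crossing
  fig8 <- cbind(c(0, 2, 2, 0, 1), c(0, 2, 0, 2, 1))
  expect_equal(entanglement(fig8, 2, sigma_s = 0)$crossings, 1L)
  # random walks match the O(N^2) oracle exactly
  set.seed(9)
  for (rep in 1:3) {
    n <- 150
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    got <- entanglement(cbind(x, y), fs_hz = 2, sigma_s = 0)
    expect_equal(got$crossings, crossings_oracle(x, y))
    expect_equal(got$entanglement, got$crossings / (n / 2))
  }
  # undefined under 3 samples
  expect_true(is.na(entanglement(cbind(1, 1), 2)$crossings))
})

test_that("entanglement is invariant to rigid rotation of the projection", {
  set.seed(4)
  tr <- cbind(cumsum(rnorm(200)), cumsum(rnorm(200)))
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e1 <- entanglement(tr, 2)
  e2 <- entanglement(tr %*% Rm, 2)
  expect_identical(e1$crossings, e2$crossings)
})

test_that("ramping sleep dynamics are less entangled than wake noise", {
  set.seed(5)
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), 3), rep(c(360, 360), 3))
  labs <- label_series_of(sch)
  n_t <- 2 * sum(rep(c(360, 360), 3))
  t_s <- (seq_len(n_t) - 1) / 2
  F <- matrix(0, 20, n_t)
  in_q <- rep(FALSE, n_t)
  for (p in which(sch$segments$state == "QEM1"))
    in_q[t_s >= sch$segments$start_s[p] & t_s < sch$segments$end_s[p]] <- TRUE
  for (i in 1:20) {
    F[i, in_q] <- seq(0, 1, length.out = sum(in_q)) * (i <= 10) -
      seq(0, 1, length.out = sum(in_q)) * (i > 10)
    F[i, !in_q] <- rnorm(sum(!in_q), 0, 0.8)   # tangled wake activity
    F[i, ] <- F[i, ] + rnorm(n_t, 0, 0.05)
  }
  nm <- neuron_matrix(F, fs_hz = 2)
  ent_q <- state_entanglement(state_pca(nm, labs, "QEM1"))
  ent_w <- state_entanglement(state_pca(nm, labs, "Wake"))
  expect_lt(median(ent_q$entanglement), median(ent_w$entanglement))
})

test_that("relative time decodes from ramp populations but not controls", {
  fishes <- lapply(1:3, function(f)
    ramp_population(seed = f, periods = 3, period_s = 300 + 40 * f))
  dec <- gain_correct(lapply(fishes, function(d)
    decode_relative_time(d$sn$matrix, d$labels, "QEM1", seed = 1)))
  r2 <- vapply(dec, `[[`, numeric(1), "r2")
  expect_true(all(r2 >= 0.95))
  # circular-shift shuffle control collapses decoding
  dec_sh <- vapply(fishes, function(d) {
    sh <- shuffle_control(d$sn$matrix, d$labels, "QEM1", seed = 3)
    decode_relative_time(sh, d$labels, "QEM1", seed = 1)$r2
  }, numeric(1))
  expect_true(all(dec_sh <= 0.1))
  # decoder weight signs follow the ramp direction; slow, spread time
  # constants keep both classes near-linear in relative time, and the
  # ridge-like mixing spreads weight across the correlated population
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), 3), rep(c(240, 340), 3))
  spec <- synth_neural_spec(n_suppressed = 0, n_ramp_down = 10,
                            n_ramp_up = 10, n_event = 0, n_noise = 0,
                            tau_up = c(3, 0.5), tau_down = c(3, 0.5),
                            noise_sd = 0.1)
  sn <- synth_neural(spec, sch, seed = 11)
  dd <- decode_relative_time(sn$matrix, label_series_of(sch), "QEM1",
                             seed = 2, alphas = 0.1)
  down <- sn$cells$class == "ramp_down"
  expect_lt(mean(dd$weights[down]), 0)
  expect_gt(mean(dd$weights[!down]), 0)
  expect_error(decode_relative_time(
    ramp_population(periods = 1)$sn$matrix,
    ramp_population(periods = 1)$labels, "QEM1"), "2 eligible")
})

test_that("the shuffle control preserves autocorrelation and reproducibility", {
  d <- ramp_population(seed = 6, noise = 0.05)
  sh1 <- shuffle_control(d$sn$matrix, d$labels, "QEM1", seed = 4)
  sh2 <- shuffle_control(d$sn$matrix, d$labels, "QEM1", seed = 4)
  expect_identical(sh1$F, sh2$F)
  ac <- function(x) cor(x[-1], x[-length(x)])
  t_s <- (seq_len(ncol(sh1$F)) - 1) / 2
  p <- sleepscope:::merge_label_periods(d$labels, "QEM1")[1, ]
  idx <- which(t_s >= p$start_s & t_s < p$end_s)
  a_orig <- mean(vapply(1:10, function(i) ac(d$sn$matrix$F[i, idx]), numeric(1)))
  a_sh <- mean(vapply(1:10, function(i) ac(sh1$F[i, idx]), numeric(1)))
  expect_lt(abs(a_orig - a_sh), 0.05 * max(abs(a_orig), 0.2))
  # alignment with the true ramp is destroyed
  ramp <- seq(0, 1, length.out = length(idx))
  cr <- vapply(1:20, function(i) cor(sh1$F[i, idx], ramp), numeric(1))
  expect_lt(abs(mean(cr)), 0.25)
})

test_that("behavior-only decoding of quiescent generator behavior fails", {
  set.seed(12)
  d <- ramp_population(seed = 12, periods = 3)
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), 3), rep(c(240, 360), 3))
  beh <- synth_behavior(sch, fs_hz = 10, seed = 12)
  n_t <- ncol(d$sn$matrix$F)
  pick <- round(seq(1, length(beh$trace$t_s), length.out = n_t))
  behavior <- cbind(speed = beh$speed$speed_mm_s[pick],
                    left = beh$trace$left_rad[pick],
                    right = beh$trace$right_rad[pick],
                    roll = rnorm(n_t, 0, 0.05), pitch = rnorm(n_t, 0, 0.05))
  db <- decode_relative_time_behavior(behavior, 2, d$labels, "QEM1", seed = 3)
  expect_lte(db$r2, 0.05)
})
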