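test_that("turn bias is a smoothed heading derivative", {
  fs <- 2
  expect_equal(turn_bias(rep(1.2, 500), fs), rep(0, 500), tolerance = 1e-12)
  # constant rotation: constant positive bias away from the edges
  n <- 16000                       # kernel radius is 4 * 960 samples
  h <- seq(0, 400, length.out = n)
  tb <- turn_bias(h, fs)
  expect_true(all(tb[5000:11000] > 0))
  expect_lt(sd(tb[6000:10000]), 1e-7)
  # alternating turns at a 20-min period give an oscillating sign,
  # matching a direct convolution oracle
  t_s <- (seq_len(n) - 1) / fs
  dh <- sin(2 * pi * t_s / 1200) * 0.01
  h2 <- cumsum(dh)
  tb2 <- turn_bias(h2, fs)
  k <- sleepscope:::gaussian_kernel(480 * fs)
  oracle <- as.numeric(stats::filter(c(0, diff(h2)), k, sides = 2))
  mid <- which(!is.na(oracle))
  expect_equal(tb2[mid], oracle[mid], tolerance = 1e-6)
  expect_gt(max(tb2), 0); expect_lt(min(tb2), 0)
})

test_that("QEM-1 regressors have the stated closed forms", {
  t_s <- seq(0, 600, by = 0.5)
  labs <- data.frame(start_s = c(0, 200, 350), end_s = c(200, 350, 600),
                     label = c("Wake", "QEM1", "Wake"))
  X <- build_qem1_regressors(labs, t_s)
  expect_true(all(X[t_s < 200, ] == 0))
  # indicator is binary, integral reaches the period duration
  in_p <- t_s >= 200 & t_s < 350
  expect_true(all(X[in_p, "qem1"] == 1))
  expect_equal(max(X[, "qem1_integral"]), 150, tolerance = 1)
  # onset kernel: tau = duration / 15 = 10 s; e-fold after 10 s
  i0 <- min(which(in_p))
  i10 <- which.min(abs(t_s - (200 + 10)))
  expect_equal(unname(X[i10, "qem1_onset"] / X[i0, "qem1_onset"]), exp(-1),
               tolerance = 0.01)
  # no QEM-1: all-zero regressors
  X0 <- build_qem1_regressors(data.frame(start_s = 0, end_s = 600,
                                         label = "Wake"), t_s)
  expect_true(all(X0 == 0))
})

test_that("encoding fits flag the truly contributing regressor groups", {
  set.seed(7)
  n <- 2400; fs <- 2
  t_s <- (seq_len(n) - 1) / fs
  labs <- data.frame(start_s = c(0, 400, 700, 1000),
                     end_s = c(400, 700, 1000, 1200),
                     label = c("Wake", "QEM1", "Wake", "QEM1"))
  behavior <- list(speed = abs(rnorm(n)), roll = rnorm(n), pitch = rnorm(n),
                   left_eye = rnorm(n), right_eye = rnorm(n),
                   heading = cumsum(rnorm(n, 0, 0.05)))
  X <- build_regressors(behavior, labs, t_s, fs)
  # neuron driven by speed: high R2, QEM-1 shuffle not significant
  y1 <- 2 * X[, "speed"] + rnorm(n, 0, 0.1)
  e1 <- fit_encoding(y1, X, seed = 1)
  expect_gt(e1$r2, 0.9)
  expect_false(e1$partial$qem1$significant)
  # neuron equal to the QEM-1 indicator: QEM-1 flag significant
  y2 <- X[, "qem1"] + rnorm(n, 0, 0.1)
  e2 <- fit_encoding(y2, X, seed = 2)
  expect_true(e2$partial$qem1$significant)
  # eye-driven neuron
  y3 <- X[, "left_eye"] + X[, "right_eye"] + rnorm(n, 0, 0.1)
  e3 <- fit_encoding(y3, X, seed = 3)
  expect_true(e3$partial$eyes$significant)
})

test_that("significance flags stay rare on pure-noise neurons", {
  set.seed(11)
  n <- 1500; fs <- 2
  t_s <- (seq_len(n) - 1) / fs
  labs <- data.frame(start_s = c(0, 250, 500), end_s = c(250, 500, 750),
                     label = c("Wake", "QEM1", "Wake"))
  behavior <- list(speed = abs(rnorm(n)), roll = rnorm(n), pitch = rnorm(n),
                   left_eye = rnorm(n), right_eye = rnorm(n),
                   heading = cumsum(rnorm(n, 0, 0.05)))
  X <- build_regressors(behavior, labs, t_s, fs)
  flags <- matrix(NA, 120, 3)
  for (i in seq_len(nrow(flags))) {
    e <- fit_encoding(rnorm(n), X, seed = 100 + i)
    flags[i, ] <- c(e$partial$eyes$significant,
                    e$partial$turn_bias$significant,
                    e$partial$qem1$significant)
  }
  expect_true(all(colMeans(flags) <= 0.15))
})

test_that("ramp fits classify and recover exponential time constants", {
  t_s <- seq(0, 1199.5, by = 0.5)
  labs <- data.frame(start_s = c(0, 300, 700), end_s = c(300, 600, 1000),
                     label = c("Wake", "QEM1", "QEM1"))
  rel <- function(t, s, e) (t - s) / (e - s)
  mk <- function(fun) {
    y <- numeric(length(t_s))
    for (p in 2:3) {
      idx <- t_s >= labs$start_s[p] & t_s < labs$end_s[p]
      y[idx] <- fun(rel(t_s[idx], labs$start_s[p], labs$end_s[p]))
    }
    y
  }
  f1 <- fit_ramps(mk(function(u) exp(-u / 0.5)), t_s, labs)
  expect_equal(f1$model, "decay")
  expect_equal(f1$b, 0.5, tolerance = 0.02)
  expect_gt(f1$r2, 0.99)
  f2 <- fit_ramps(mk(function(u) 1 - exp(-u / 0.2)), t_s, labs)
  expect_equal(f2$model, "ramp_up")
  expect_equal(f2$b, 0.2, tolerance = 0.05)
  # short periods only: undefined fit flagged
  labs3 <- data.frame(start_s = 0, end_s = 100, label = "QEM1")
  expect_true(fit_ramps(rnorm(length(t_s)), t_s, labs3)$undefined)
  # the literal printed exponent form stays available for comparison
  f4 <- fit_ramps(mk(function(u) exp(-1 / pmax(0.5 * u, 1e-12))), t_s, labs,
                  literal_exponent = TRUE)
  expect_equal(f4$model, "decay")
})

test_that("generator ramp cells are recovered from the neural matrix", {
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), 3), rep(c(240, 360), 3))
  labs <- label_series_of(sch)
  spec <- synth_neural_spec(n_suppressed = 0, n_ramp_down = 10,
                            n_ramp_up = 10, n_event = 0, n_noise = 0,
                            noise_sd = 0)
  sn <- synth_neural(spec, sch, seed = 8)
  t_s <- (seq_len(ncol(sn$matrix$F)) - 1) / 2
  fits <- lapply(seq_len(20), function(i) fit_ramps(sn$matrix$F[i, ], t_s, labs))
  cls <- vapply(fits, `[[`, character(1), "model")
  want <- ifelse(sn$cells$class == "ramp_down", "decay", "ramp_up")
  expect_equal(mean(cls == want), 1)
  b <- vapply(fits, `[[`, numeric(1), "b")
  down <- sn$cells$class == "ramp_down"
  expect_lt(median(abs(b[down] - sn$cells$tau[down]) / sn$cells$tau[down]),
            0.10)
})

test_that("enrichment matches its expectation oracle and edge cases", {
  # region of 10 with 5 positives among 100 neurons, 10 positives total:
  # E[P0] = 0.1, so E ~ 5
  regions <- c(rep("A", 10), rep("B", 90))
  positive <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 85))
  e <- enrichment(positive, regions, seed = 3)
  a <- e[e$region == "A", ]
  expect_equal(a$p_x, 0.5)
  expect_equal(a$e_x, 5, tolerance = 1)
  # a region containing every neuron has enrichment exactly 1
  e2 <- enrichment(positive, rep("all", 100), seed = 1)
  expect_equal(e2$e_x, 1)
  expect_false(e2$significant)
})

test_that("uniform labels give calibrated enrichment significance", {
  set.seed(21)
  sig_rate <- replicate(40, {
    regions <- rep(sprintf("r%02d", 1:10), each = 100)
    positive <- sample(c(TRUE, FALSE), 1000, TRUE, prob = c(.1, .9))
    mean(enrichment(positive, regions,
                    seed = sample.int(1e6, 1))$significant)
  })
  # per-fish false-positive rate is near (and conservatively below) 5%
  expect_lt(mean(sig_rate), 0.07)
  expect_gt(mean(sig_rate), 0.005)
})

test_that("across-fish verdict needs the configured quorum", {
  tb <- function(sig) data.frame(region = "A", n_pos = 1, n_tot = 10,
                                 p_x = .1, e_x = 1, n_null_below = 50,
                                 significant = sig)
  per_fish <- c(replicate(8, tb(TRUE), simplify = FALSE),
                replicate(3, tb(FALSE), simplify = FALSE))
  out <- enrichment_across_fish(per_fish)
  expect_true(out$significant)   # 8 of 11 meets ceiling(0.7 * 11) = 8
  per_fish2 <- c(replicate(7, tb(TRUE), simplify = FALSE),
                 replicate(4, tb(FALSE), simplify = FALSE))
  expect_false(enrichment_across_fish(per_fish2)$significant)
})
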