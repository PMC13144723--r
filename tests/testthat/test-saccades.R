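make_trace <- function(left, right, fs = 10) {
  n <- length(left)
  eye_angle_trace((seq_len(n) - 1) / fs, left, right, fs)
}

test_that("preprocess removes offsets and keeps the residual identity", {
  set.seed(1)
  n <- 3000; fs <- 10
  x <- rnorm(n, sd = 0.01) + 0.5    # constant offset plus noise
  tr <- make_trace(x, x, fs)
  f <- preprocess(tr)
  expect_lt(max(abs(f$left$detrended)), 0.06)
  expect_equal(f$left$residual + f$left$denoised, f$left$detrended,
               tolerance = 1e-12)
  # lambda = 0: denoised equals the median-filtered detrended series
  f0 <- preprocess(tr, lambda = 0)
  k <- 15L  # 1.5 s at 10 Hz
  med <- as.numeric(runmed(f0$left$detrended, k, endrule = "median"))
  expect_equal(f0$left$denoised, med)
  expect_error(preprocess(make_trace(rnorm(5), rnorm(5), 10)), "shorter")
})

test_that("constant input gives an all-zero detrended trace", {
  tr <- make_trace(rep(0.3, 500), rep(0.3, 500), 10)
  f <- preprocess(tr)
  expect_equal(max(abs(f$left$detrended)), 0)
  expect_equal(max(abs(f$left$denoised)), 0)
})

test_that("candidate detection fires on conjugate steps only", {
  fs <- 10
  step <- function(at, amp, n = 600) {
    x <- rep(0, n); x[at:n] <- amp; x
  }
  # conjugate 20 deg step: velocity product far above threshold
  L <- step(300, 20 * pi / 180); R <- L
  f <- preprocess(make_trace(L, R, fs))
  cand <- detect_candidates(f, 0.60)
  expect_equal(nrow(cand), 1L)
  expect_lt(abs(cand$t_s - 30), 1)
  # monocular step: product ~ 0
  f2 <- preprocess(make_trace(L, rep(0, 600), fs))
  expect_equal(nrow(detect_candidates(f2, 0.60)), 0L)
  # two equal steps 1 s apart are pruned to one
  L3 <- step(300, 0.35) + step(310, 0.35)
  f3 <- preprocess(make_trace(L3, L3, fs))
  expect_equal(nrow(detect_candidates(f3, 0.60, min_isi_s = 1.5)), 1L)
  expect_error(detect_candidates(f, 0))
})

test_that("selection separates conjugate, vergence and noisy events", {
  fs <- 10; n <- 900
  base <- rep(0, n); base[450:n] <- 0.35
  f <- preprocess(make_trace(base, base, fs))
  sel <- select_saccades(detect_candidates(f, 0.6), f)
  expect_true(all(sel$accepted))
  # anti-conjugate (vergence): correlation below threshold
  f2 <- preprocess(make_trace(base, -base, fs))
  cand2 <- detect_candidates(f2, 0.6)
  sel2 <- select_saccades(cand2, f2)
  expect_true(nrow(sel2) == 0 || all(!sel2$accepted))
  if (nrow(sel2)) expect_equal(sel2$reason[1], "correlation")
  # saccade inside a high-noise epoch: the noise is common to both eyes,
  # so the correlation criterion passes and the residual criterion rejects
  set.seed(2)
  common <- rnorm(n, sd = 0.6)
  f3 <- preprocess(make_trace(base + common, base + common, fs))
  cand3 <- detect_candidates(f3, 0.6)
  sel3 <- select_saccades(cand3, f3)
  if (nrow(sel3)) expect_true(all(sel3$reason[!sel3$accepted] == "residual"))
  expect_error(select_saccades(detect_candidates(f, .6), f, corr_win_s = 1e5),
               "window")
})

test_that("kinematic scoring recovers closed-form decays", {
  fs <- 50
  n <- 20 * fs
  # baseline 0; step to 10 deg at t=4 s over two samples; linear decay 1 deg/s
  amp <- 10 * pi / 180
  x <- rep(0, n)
  i0 <- 4 * fs
  x[i0] <- amp / 2
  decay <- amp - (seq_len(n - i0)) / fs * pi / 180
  x[(i0 + 1):n] <- pmax(decay, 0)
  tr <- make_trace(x, x, fs)
  f <- preprocess(tr)
  sel <- select_saccades(detect_candidates(f, 0.32), f)
  ev <- score_kinematics(sel, tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$decay_slope_deg_s, 1, tolerance = 0.05)
  # crossing of 0.33 * 10 deg after 6.7 s of 1 deg/s decay
  expect_equal(ev$fixation_s, 6.7, tolerance = 0.15)
  expect_false(ev$censored)

  # perfectly static fixation: censored at the trace end with slope ~ 0
  y <- rep(0, n); y[i0] <- amp / 2; y[(i0 + 1):n] <- amp
  tr2 <- make_trace(y, y, fs)
  f2 <- preprocess(tr2)
  ev2 <- score_kinematics(select_saccades(detect_candidates(f2, 0.32), f2), tr2)
  expect_equal(nrow(ev2), 1L)
  expect_true(ev2$censored)
  expect_lt(ev2$decay_slope_deg_s, 0.05)
})

test_that("the full chain recovers generator kinematics and event sets", {
  run <- qem_run("QEM1", 10, seed = 21, fs = 50)
  inj <- run$beh$events; det <- run$events
  m <- match_events(det, inj)
  recall <- mean(!is.na(m))
  precision <- mean(!is.na(match_events(inj, det)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # QEM-2 slope recovery within 3 SE of the preset mean
  run2 <- qem_run("QEM2", 30, seed = 22, fs = 50)
  kin <- default_kinematics()$QEM2
  se <- kin$decay_slope_deg_s[2] / sqrt(nrow(run2$events))
  expect_lt(abs(mean(run2$events$decay_slope_deg_s) -
                  kin$decay_slope_deg_s[1]), 3 * se + 0.05)
  # accepted events strictly increasing with >= 1.5 s gaps
  expect_true(all(diff(run$events$onset_s) >= 1.5 - 1e-9))
})

test_that("the chain is invariant to a constant added to both eyes", {
  sch <- schedule_from_segments("QEM1", 300)
  beh <- synth_behavior(sch, fs_hz = 50, seed = 31)
  tr <- beh$trace
  tr2 <- eye_angle_trace(tr$t_s, tr$left_rad + 0.5, tr$right_rad + 0.5,
                         tr$fs_hz)
  e1 <- detect_saccades(tr, "multi")
  e2 <- detect_saccades(tr2, "multi")
  expect_equal(e1$onset_s, e2$onset_s)
  expect_equal(e1$decay_slope_deg_s, e2$decay_slope_deg_s, tolerance = 1e-8)
})
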