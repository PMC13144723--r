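mk_nm <- function(F, centroids = NULL, mask = NULL) {
  neuron_matrix(F, mask = mask, fs_hz = 2, centroids_um = centroids)
}

test_that("duplicate merging follows distance, correlation and coverage", {
  set.seed(1)
  base <- rnorm(400)
  F <- rbind(base, base + rnorm(400, 0, 0.05), rnorm(400))
  cen <- rbind(c(0, 0, 0), c(2, 1, 1), c(100, 100, 100))
  nm <- mk_nm(F, cen)
  out <- merge_duplicates(nm)
  expect_equal(nrow(out$F), 2L)
  # near neighbors with low correlation both survive
  F2 <- rbind(rnorm(400), rnorm(400))
  nm2 <- mk_nm(F2, rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_equal(nrow(merge_duplicates(nm2)$F), 2L)
  # merging is idempotent
  out2 <- merge_duplicates(out)
  expect_equal(out2$F, out$F)
})

test_that("transitive duplicate chains keep one best-covered member", {
  set.seed(2)
  base <- rnorm(600)
  F <- rbind(base + rnorm(600, 0, 0.02),
             base + rnorm(600, 0, 0.02),
             base + rnorm(600, 0, 0.02))
  cen <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))  # A~B, B~C, not A~C
  mask <- matrix(TRUE, 3, 600)
  mask[1, 1:200] <- FALSE   # member 1 has the worst coverage
  nm <- neuron_matrix(F, mask, 2, cen)
  out <- merge_duplicates(nm)
  expect_equal(nrow(out$F), 1L)
  # agrees with an independent union-find grouping
  groups <- dup_groups_oracle(cen, F, mask)
  expect_equal(length(unique(groups)), 1L)
  expect_equal(attr(out, "kept"), which.max(rowMeans(mask)))
})

test_that("coverage filtering applies the 50% boundary", {
  F <- matrix(rnorm(300), 3, 100)
  mask <- rbind(c(rep(TRUE, 49), rep(FALSE, 51)),
                c(rep(TRUE, 51), rep(FALSE, 49)),
                rep(TRUE, 100))
  nm <- neuron_matrix(F, mask, 2)
  out <- coverage_filter(nm)
  expect_equal(attr(out, "kept"), c(2L, 3L))
  expect_equal(coverage_filter(mk_nm(F))$F, F)
  expect_error(coverage_filter(neuron_matrix(F, mask & FALSE, 2)), "every")
})

test_that("bleach correction recovers and removes the exponential", {
  t_s <- (0:2399) / 2
  # pure exponential: residual flat
  F <- rbind(2 * exp(-t_s / 300) + 1,
             rnorm(2400, 0, 0.05) + 1)
  nm <- mk_nm(F)
  out <- debleach(nm)
  fits <- attr(out, "bleach_fits")
  expect_lt(sd(out$F[1, ]), 1e-6 * 2 + 1e-8)
  expect_equal(fits$tau_s[1], 300, tolerance = 0.01)
  # bleach-free input: A ~ 0 and the trace survives unchanged
  expect_lt(fits$A[2], 0.05)
  expect_equal(out$F[2, ], F[2, ], tolerance = 0.05)
  expect_false(any(fits$failed))
  # generator bleach recovered within 10% on quiet populations
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), 2), rep(c(240, 300), 2))
  spec <- synth_neural_spec(n_suppressed = 0, n_ramp_down = 0, n_ramp_up = 0,
                            n_event = 3, n_noise = 5, noise_sd = 0.05,
                            bleach_amp = 0.8, bleach_tau_s = 800)
  sn <- synth_neural(spec, sch, seed = 6)
  bf <- attr(debleach(sn$matrix), "bleach_fits")
  noisy <- sn$cells$class == "noise"
  expect_lt(median(abs(bf$tau_s[noisy] - 800) / 800), 0.10)
  # mask and dimensions unchanged
  expect_identical(dim(out$F), dim(nm$F))
  expect_identical(out$mask, nm$mask)
})

test_that("event detection applies duration and merging rules", {
  fs <- 2
  flat <- rnorm(1200, 0, 0.02)
  nm <- mk_nm(rbind(flat))
  expect_equal(nrow(detect_events(mk_nm(rbind(rep(0, 1200))))$events), 0L)
  expect_equal(nrow(detect_events(nm)$events), 0L)
  # three 3-s boxcars 20 s apart at 5x noise
  x <- rnorm(1200, 0, 0.02)
  for (s in c(100, 140, 180)) x[(s * fs):((s + 3) * fs)] <- 0.5
  ev <- detect_events(mk_nm(rbind(x)))
  expect_equal(nrow(ev$events), 3L)
  # two boxcars 3 s apart merge into one event spanning both
  y <- rnorm(1200, 0, 0.02)
  y[(100 * fs):(103 * fs)] <- 0.5
  y[(106 * fs):(109 * fs)] <- 0.5
  ev2 <- detect_events(mk_nm(rbind(y)))
  expect_equal(nrow(ev2$events), 1L)
  expect_gt(ev2$events$end_s - ev2$events$start_s, 8)
})

test_that("generator transients are recovered with high precision and recall", {
  sch <- schedule_from_segments(rep(c("Wake", "QEM1"), 4), rep(c(300, 400), 4))
  labs <- label_series_of(sch)
  spec <- synth_neural_spec(n_suppressed = 0, n_ramp_down = 0, n_ramp_up = 0,
                            n_event = 8, n_noise = 0, noise_sd = 0.05,
                            missing_fraction = 0)
  sn <- synth_neural(spec, sch, seed = 5)
  ev <- detect_events(sn$matrix, labs)
  inj <- sn$events
  hit <- vapply(seq_len(nrow(inj)), function(k)
    any(ev$events$neuron == inj$neuron[k] &
          abs(ev$events$start_s - inj$start_s[k]) < 3), logical(1))
  prec <- vapply(seq_len(nrow(ev$events)), function(k)
    any(inj$neuron == ev$events$neuron[k] &
          abs(inj$start_s - ev$events$start_s[k]) < 3), logical(1))
  expect_gte(mean(hit), 0.95)
  expect_gte(mean(prec), 0.95)
  # per-state rates are populated and dual-activity is flagged coherently
  expect_true(all(is.finite(ev$rates)))
  expect_type(ev$dual_active, "logical")
})

test_that("interpolation fills masked samples linearly", {
  F <- matrix(c(0, NA, 2, NA, 4, 5), 1)
  mask <- !is.na(F)
  nm <- neuron_matrix(F, mask, 2)
  out <- interpolate_missing(nm)
  expect_equal(as.numeric(out$F), c(0, 1, 2, 3, 4, 5))
})
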