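test_that("model inputs encode lights, introduction day and circadian phase", {
  sch <- schedule_from_segments("Wake", 48 * 3600,
                                light_cycle_spec = list(mode = "LD"))
  labs <- data.frame(start_s = 0, end_s = 48 * 3600, label = "Wake")
  fd <- build_inputs(labs, sch)
  # start at midnight: cosine column begins at ~1
  expect_gt(fd$inputs[1, "cos"], 0.99)
  expect_equal(fd$inputs[, "cos"]^2 + fd$inputs[, "sin"]^2,
               rep(1, nrow(fd$inputs)), tolerance = 1e-12)
  # introduction indicator: first 24 h only
  expect_true(all(fd$inputs[fd$t_s < 24 * 3600, "day1"] == 1))
  expect_true(all(fd$inputs[fd$t_s > 24 * 3600, "day1"] == 0))
  # constant darkness: lights column all zero
  schd <- schedule_from_segments("Wake", 3600,
                                 light_cycle_spec = list(mode = "DD"))
  fdd <- build_inputs(data.frame(start_s = 0, end_s = 3600, label = "Wake"),
                      schd)
  expect_true(all(fdd$inputs[, "lights"] == 0))
  expect_error(build_inputs(labs, list()), "lights_fun")
})

test_that("predicted state probabilities always sum to one", {
  par <- sleepscope:::mlp_init(24, "sigmoid", 1)
  set.seed(2)
  X <- cbind(sample(0:1, 1000, TRUE), sample(0:1, 1000, TRUE),
             cos(runif(1000, 0, 2 * pi)), sin(runif(1000, 0, 2 * pi)))
  p <- predict_state_prob(par, X)
  expect_equal(rowSums(p$prob), rep(1, 1000), tolerance = 1e-6)
  expect_length(p$latent, 1000)
})

test_that("a degenerate single-state dataset is learned almost surely", {
  sch <- schedule_from_segments("Wake", 6 * 3600)
  labs <- data.frame(start_s = 0, end_s = 6 * 3600, label = "QNEM")
  fish <- lapply(1:5, function(i) build_inputs(labs, sch, condition = "LL"))
  ens <- fit_state_prob_model(fish, n_reps = 1, seed = 1, max_epochs = 800)
  pred <- predict_state_prob(ens$members[[1]]$par, fish[[1]]$inputs)$prob
  expect_true(all(pred[, "QNEM"] > 0.95))
})

test_that("lights-driven states are predicted on held-out fish", {
  # 4 random light schedules + complements, 2 fish each; states follow
  # the lights with 90% compliance
  make_fish <- function(i, seed = 50) {
    base_id <- ((i - 1) %/% 2) + 1
    sch <- make_schedule(12 * 3600,
                         list(mode = "random", seed = base_id, block_h = 2,
                              duration_h = 12), c(Wake = 1), seed = 1)
    if (i %% 2 == 0) { lf <- sch$lights_fun
      sch$lights_fun <- function(t) 1 - lf(t) }
    set.seed(seed + i)
    t_grid <- seq(0, sch$duration_s - 60, by = 60) + 30
    L <- sch$lights_fun(t_grid)
    st <- ifelse(runif(length(t_grid)) < ifelse(L > 0.5, 0.9, 0.1),
                 "Wake", "QNEM")
    labs <- data.frame(start_s = t_grid - 30, end_s = t_grid + 30,
                       label = st)
    build_inputs(labs, sch, condition = paste0("c", i))
  }
  fish <- lapply(1:8, make_fish)
  ens <- fit_state_prob_model(fish, n_folds = 4, n_reps = 1, seed = 2,
                              max_epochs = 800)
  r <- t(vapply(ens$members, `[[`, numeric(5), "r_by_state"))
  expect_gt(mean(r[, "Wake"], na.rm = TRUE), 0.7)
  # latent separates the two states (gating-axis diagnostic)
  par <- ens$members[[1]]$par
  p <- predict_state_prob(par, fish[[1]]$inputs)
  z_wake <- p$latent[fish[[1]]$states == "Wake"]
  z_qnem <- p$latent[fish[[1]]$states == "QNEM"]
  expect_gt(abs(median(z_wake) - median(z_qnem)), 1e-3)
})

test_that("shuffles are reproducible and leave fold structure intact", {
  sch <- schedule_from_segments("Wake", 2 * 3600)
  labs <- data.frame(start_s = 0, end_s = 2 * 3600, label = "Wake")
  fish <- lapply(1:5, function(i) build_inputs(labs, sch))
  ens <- fit_state_prob_model(fish, n_reps = 1, seed = 4, max_epochs = 50)
  a1 <- ablate_input(fish, ens, "circadian", seed = 9, n_reps = 1,
                     max_epochs = 50)
  a2 <- ablate_input(fish, ens, "circadian", seed = 9, n_reps = 1,
                     max_epochs = 50)
  expect_identical(a1$summary$r_ablated, a2$summary$r_ablated)
  expect_error(ablate_input(fish, ens, "nonsense"), "arg")
})

test_that("ensemble estimates tighten with more fish", {
  make_fish <- function(i, seed = 900) {
    sch <- schedule_from_segments("Wake", 6 * 3600,
                                  light_cycle_spec = list(mode = "LD",
                                                          day_len_h = 3))
    set.seed(seed + i)
    t_grid <- seq(0, sch$duration_s - 60, by = 60) + 30
    L <- sch$lights_fun(t_grid)
    st <- ifelse(runif(length(t_grid)) < ifelse(L > 0.5, 0.85, 0.15),
                 "Wake", "QNEM")
    build_inputs(data.frame(start_s = t_grid - 30, end_s = t_grid + 30,
                            label = st), sch, condition = "LD")
  }
  fit_spread <- function(n_fish) {
    fish <- lapply(seq_len(n_fish), make_fish)
    ens <- fit_state_prob_model(fish, n_reps = 2, seed = 7,
                                max_epochs = 400)
    r <- vapply(ens$members, function(m) m$r_by_state[["Wake"]], numeric(1))
    sd(r, na.rm = TRUE)
  }
  expect_lt(fit_spread(20), fit_spread(5))
})

test_that("ensembles round-trip through JSON with identical predictions", {
  sch <- schedule_from_segments("Wake", 3600)
  labs <- data.frame(start_s = 0, end_s = 3600, label = "Wake")
  fish <- lapply(1:5, function(i) build_inputs(labs, sch))
  ens <- fit_state_prob_model(fish, n_reps = 1, seed = 4, max_epochs = 30)
  path <- tempfile(fileext = ".json")
  write_state_prob_ensemble(ens, path)
  ens2 <- read_state_prob_ensemble(path)
  expect_length(ens2$members, length(ens$members))
  p1 <- predict_state_prob(ens$members[[2]]$par, fish[[1]]$inputs)$prob
  p2 <- predict_state_prob(ens2$members[[2]]$par, fish[[1]]$inputs)$prob
  expect_equal(p1, p2, tolerance = 1e-12)
})
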