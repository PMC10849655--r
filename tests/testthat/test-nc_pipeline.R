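make_session_from_raster <- function(raster, speed_fun, id = "s",
                                     behavior_rate = 10) {
  ann <- annotation_from_raster(raster, id)
  tb <- seq(1 / behavior_rate, ann$duration, by = 1 / behavior_rate)
  nc_session(id, ann, data.frame(t = tb, walking_speed = speed_fun(tb)))
}

test_that("simulate_session matches single-neuron simulation and causality", {
  pop <- sample_population(3, c(5, 20), c(0.1, 2), seed = 3)
  study <- small_study()
  s <- study[[1]]
  tt <- seq(1, 100, by = 1)
  rec <- simulate_session(pop, s, "ma", dt_song = 0.01, target_times = tt)
  expect_equal(dim(rec$activity), c(length(tt), 3))

  # all-quiet session produces a zero recording
  quiet <- nc_session("q", song_annotation(NULL, 50),
                      data.frame(t = seq(0.5, 50, 0.5),
                                 walking_speed = rep(2, 100)))
  recq <- simulate_session(pop, quiet, "ma", target_times = c(10, 20))
  expect_true(all(recq$activity == 0))

  # single-neuron consistency with ma_simulate at sampled times
  one <- population_params(pop[1, ])
  rec1 <- simulate_session(one, s, "ma", dt_song = 0.01, target_times = tt)
  full <- ma_simulate(natcont:::pop_row_params(one, 1),
                      rasterize(s$song, 0.01))
  expect_equal(as.vector(rec1$activity), full$r[round(tt / 0.01)],
               tolerance = 1e-12)

  # perturbing song after t leaves activity at t unchanged
  iv <- s$song$intervals
  iv2 <- rbind(iv[iv$end <= 60, ], data.frame(start = 80, end = 100,
                                              mode = "pulse"))
  s2 <- nc_session(s$session_id,
                   song_annotation(iv2, s$song$duration), s$behavior)
  iv3 <- iv[iv$end <= 60, ]
  s3 <- nc_session(s$session_id,
                   song_annotation(iv3, s$song$duration), s$behavior)
  t_pre <- seq(1, 60, by = 1)
  a2 <- simulate_session(pop, s2, "ma", target_times = t_pre)$activity
  a3 <- simulate_session(pop, s3, "ma", target_times = t_pre)$activity
  expect_equal(a2, a3)
})

test_that("forward_average_target averages over the lookahead window", {
  r <- song_raster(rep(0L, 100), rep(0L, 100), 1)
  const <- make_session_from_raster(r, function(tb) rep(3.5, length(tb)))
  tg <- forward_average_target(const, window = 1)
  expect_true(all(tg$target == 3.5))

  stepf <- make_session_from_raster(r, function(tb) as.numeric(tb > 50))
  tg2 <- forward_average_target(stepf, window = 1)
  expect_equal(tg2$target[tg2$t == 50], 1)   # window fully after the step
  expect_equal(tg2$target[tg2$t == 20], 0)

  # a 60 s window comes from the same code path
  tg3 <- forward_average_target(stepf, window = 60)
  expect_equal(tg3$target[tg3$t == 0], mean(as.numeric(seq(0.1, 60, 0.1) > 50)))
  expect_true(all(tg3$t + 60 <= 100 + 1e-9))
  expect_error(forward_average_target(const, window = 1000), "exceeds")
})

test_that("ridge readout solves the normal equations and shrinks correctly", {
  set.seed(5)
  X <- matrix(rnorm(200 * 6), 200, 6)
  w_true <- c(2, -1, 0.5, 0, 1, -2)
  y <- drop(X %*% w_true) + 4
  fit <- fit_readout(list(X), list(y), alpha = 1e-8)
  pred <- predict(fit, X)
  expect_lt(max(abs(pred - y)), 1e-4)
  # recover weights on the original scale to 1e-3 relative
  w_orig <- fit$weights / fit$scale
  expect_lt(max(abs(w_orig - w_true)) / max(abs(w_true)), 1e-3)

  # matches an independent SVD-based ridge solve at finite alpha
  alpha <- 3.7
  Z <- scale(X)
  sv <- svd(Z)
  w_svd <- sv$v %*% ((sv$d / (sv$d^2 + alpha)) * crossprod(sv$u, y - mean(y)))
  fit2 <- fit_readout(list(X), list(y), alpha = alpha)
  expect_lt(max(abs(fit2$weights - w_svd)), 1e-8)

  # huge penalty: weights shrink to zero, prediction to the training mean
  fit3 <- fit_readout(list(X), list(y), alpha = 1e12)
  expect_lt(max(abs(fit3$weights)), 1e-6)
  expect_lt(max(abs(predict(fit3, X) - mean(y))), 1e-4)
})

test_that("nc_score recovers a noiseless synthetic study and bounds VE", {
  study <- small_study()
  gt <- attr(study, "ground_truth")
  sc <- nc_score(gt$pop, study, "ma", n_splits = 6, seed = 5)
  expect_gt(sc$mean_ve, 0.99)
  expect_true(all(sc$ve_per_split <= 1))

  # shuffling targets in time removes all signal
  shuffled_sessions <- lapply(study, function(s) {
    b <- s$behavior
    set.seed(17)
    b$walking_speed <- sample(b$walking_speed)
    nc_session(s$session_id, s$song, b)
  })
  scs <- nc_score(gt$pop, shuffled_sessions, "ma", n_splits = 6, seed = 5)
  expect_lt(scs$mean_ve, 0.05)

  # splits are session-level partitions
  for (sp in sc$splits) {
    expect_true(all(sp %in% seq_along(study)))
    expect_lt(length(sp), length(study))
  }

  # readout prediction is invariant to neuron ordering
  perm <- rev(seq_len(nrow(gt$pop)))
  pop_perm <- population_params(gt$pop[perm, ])
  sc2 <- nc_score(pop_perm, study, "ma", n_splits = 6, seed = 5, alpha = 1e-4)
  sc1 <- nc_score(gt$pop, study, "ma", n_splits = 6, seed = 5, alpha = 1e-4)
  expect_equal(sc1$ve_per_split, sc2$ve_per_split, tolerance = 1e-9)
})

test_that("held-out VE approaches the generative noise ceiling", {
  # targets generated exactly as w . activity + noise on the feature grid,
  # so the expected VE in the small-penalty limit is 1 - Var(eps)/Var(y)
  study <- small_study()
  gt <- attr(study, "ground_truth")
  tt <- seq(1, 119, by = 1)
  feats <- lapply(study, function(s)
    simulate_session(gt$pop, s, "ma", target_times = tt)$activity)
  w <- gt$weights
  for (noise in c(0.02, 0.1, 0.2)) {
    set.seed(round(100 * noise))
    eps <- lapply(feats, function(X) rnorm(nrow(X), 0, noise))
    targs <- mapply(function(X, e) drop(X %*% w) + e, feats, eps,
                    SIMPLIFY = FALSE)
    sc <- natcont:::score_feature_splits(feats, targs, alpha = 1e-8,
                                         n_splits = 6, seed = 5)
    ceilings <- vapply(sc$splits, function(tr) {
      te <- setdiff(seq_along(feats), tr)
      y <- unlist(targs[te])
      1 - sum(unlist(eps[te])^2) / sum((y - mean(y))^2)
    }, numeric(1))
    expect_lt(abs(sc$mean_ve - mean(ceilings)), 0.02)
  }
})

test_that("shuffle_songs permutes pairings reproducibly and degrades VE", {
  study <- small_study()
  gt <- attr(study, "ground_truth")
  two <- shuffle_songs(study[1:2], seed = 3)
  expect_equal(two[[1]]$song$intervals$start, study[[2]]$song$intervals$start)
  expect_equal(two[[2]]$song$intervals$start, study[[1]]$song$intervals$start)
  expect_identical(lapply(shuffle_songs(study, 9), function(s) s$song$intervals),
                   lapply(shuffle_songs(study, 9), function(s) s$song$intervals))

  scs <- nc_score(gt$pop, shuffle_songs(study, 9), "ma", n_splits = 6, seed = 5)
  sc <- nc_score(gt$pop, study, "ma", n_splits = 6, seed = 5)
  expect_lt(scs$mean_ve, sc$mean_ve)
  expect_error(shuffle_songs(study[1], 1), "at least 2")
})

test_that("baselines use paired splits and capture their generative signals", {
  # behavior that is a linear function of elapsed time: timestamp explains it
  r <- song_raster(rep(0L, 1200), rep(0L, 1200), 0.1)
  lin <- lapply(1:4, function(i)
    make_session_from_raster(r, function(tb) 2 + 0.05 * tb,
                             id = sprintf("lin%d", i)))
  bl <- baseline_predictors(lin, baselines = "timestamp", n_splits = 4,
                            seed = 5, alpha = 1e-8)
  expect_gt(bl$mean_ve[1], 0.999)

  # behavior built from the trailing bout-duration signal
  study <- small_study()
  bout_sessions <- lapply(study, function(s) {
    bs <- bout_stats(s$song, times = s$behavior$t, window = 120)
    nc_session(s$session_id, s$song,
               data.frame(t = s$behavior$t,
                          walking_speed = pmax(10 - 0.8 * bs$mean_bout_duration, 0)))
  })
  bl2 <- baseline_predictors(bout_sessions,
                             baselines = c("timestamp", "bout_duration"),
                             n_splits = 6, seed = 5)
  ve_bout <- bl2$mean_ve[bl2$baseline == "bout_duration"]
  # the generative ceiling is below 1 because the target is forward-
  # averaged over 1 s while the feature is the instantaneous bout signal
  expect_gt(ve_bout, 0.7)
  expect_gt(ve_bout, bl2$mean_ve[bl2$baseline == "timestamp"])

  # identical split protocol as nc_score under the same seed
  sc <- nc_score(attr(study, "ground_truth")$pop, bout_sessions, "ma",
                 n_splits = 6, seed = 5)
  expect_identical(attr(bl2, "scores")$bout_duration$splits, sc$splits)
})

test_that("nc_sweep enumerates regimes and respects PC projections", {
  study <- small_study()[1:4]
  factory <- function(n, seed) sample_population(n, c(20, 120), c(0.1, 2),
                                                 seed = seed)
  grid <- nc_sweep(factory, study, "regime_grid", n_neurons = 4, seed = 2,
                   n_splits = 2, alpha = 1e-2, stride = 2, dt_song = 0.02)
  expect_equal(nrow(grid), 12)
  expect_setequal(unique(grid$tau_a_regime), c("fast", "medium", "slow", "none"))
  expect_equal(sum(grid$tau_a_regime == "none"), 3)

  # full-rank PC projection leaves the score unchanged
  pop <- factory(5, 9)
  sc_full <- nc_score(pop, study, "ma", n_splits = 3, seed = 5, alpha = 1e-3)
  sc_proj <- nc_score(pop, study, "ma", n_splits = 3, seed = 5, alpha = 1e-3,
                      n_pcs = 5)
  expect_equal(sc_full$ve_per_split, sc_proj$ve_per_split, tolerance = 1e-8)

  het <- nc_sweep(factory, study, "heterogeneity", n_neurons = 4, seed = 2,
                  n_splits = 2, alpha = 1e-2, stride = 2, dt_song = 0.02)
  expect_setequal(het$config, c("het_tau_a", "het_tau_int"))
})

test_that("mean VE is non-decreasing with population size in expectation", {
  study <- small_study()[1:4]
  factory <- function(n, seed) sample_population(n, c(20, 120), c(0.1, 2),
                                                 seed = seed)
  sw <- nc_sweep(factory, study, "population_size", sizes = c(2, 12),
                 n_instantiations = 3, seed = 3, n_splits = 3,
                 alpha = 1e-3, stride = 2, dt_song = 0.02)
  expect_gte(sw$mean_ve[sw$size == 12], sw$mean_ve[sw$size == 2])
})

test_that("study io round-trips sessions through CSV plus manifest", {
  skip_if_not_installed("yaml")
  study <- small_study()[1:2]
  dir <- tempfile("study")
  write_study(study, dir)
  back <- read_study(file.path(dir, "sessions.yaml"))
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$song$intervals$start, study[[1]]$song$intervals$start,
               tolerance = 1e-6)
  expect_equal(back[[1]]$behavior$walking_speed,
               study[[1]]$behavior$walking_speed, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
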