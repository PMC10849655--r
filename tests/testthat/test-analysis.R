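test_that("response entropy matches exact histogram values", {
  expect_equal(response_entropy(rep(0.3, 100))$entropy_bits, 0)
  expect_equal(response_entropy(rep(0.3, 100))$normalized_entropy, 0)

  unif <- rep(1:16, each = 5)
  e <- response_entropy(unif, n_bins = 16)
  expect_equal(e$entropy_bits, 4)
  expect_equal(e$normalized_entropy, 1)

  two <- rep(c(0, 1), each = 8)
  e2 <- response_entropy(two, n_bins = 16)
  expect_equal(e2$entropy_bits, 1)
  expect_equal(e2$normalized_entropy, 0.25)
})

test_that("entropy with observed-range binning is invariant to affine maps", {
  set.seed(8)
  v <- rnorm(500)
  h0 <- response_entropy(v)$entropy_bits
  expect_equal(response_entropy(3.2 * v + 7)$entropy_bits, h0, tolerance = 1e-9)
  expect_equal(response_entropy(0.01 * v - 2)$entropy_bits, h0, tolerance = 1e-9)
})

test_that("slow integration with fast adaptation spreads the activity histogram", {
  # an adapting slow integrator explores its range more evenly on natural
  # song than a fast non-adapting neuron (bimodal response)
  songs <- lapply(1:6, function(i)
    rasterize(generate_song(default_song_params(), 120, seed = 50 + i), 0.02))
  gather <- function(p) unlist(lapply(songs, function(r) ma_simulate(p, r)$r))
  h_fast <- response_entropy(gather(ma_params(0.5, Inf, 0.5, 0.5)))
  h_slow <- response_entropy(gather(ma_params(60, 2, 0.5, 0.5)))
  expect_gt(h_slow$normalized_entropy, h_fast$normalized_entropy)
})

test_that("population PCA is orthonormal, variance-complete, and sign-fixed", {
  set.seed(12)
  X <- matrix(rnorm(300 * 5), 300, 5) %*% diag(c(3, 2, 1, 0.5, 0.1))
  y <- drop(X %*% c(1, -2, 0.5, 1, -1)) + rnorm(300, 0, 0.1)
  res <- population_pca(list(X), list(y), alpha = 1e-6)
  expect_equal(unname(crossprod(res$rotation)), diag(5), tolerance = 1e-8)
  expect_true(all(diff(res$sdev) <= 1e-12))
  expect_equal(sum(res$sdev^2), sum(apply(X, 2, var)) * (299 / 299),
               tolerance = 1e-8)
  expect_equal(sum(res$explained_variance), 1)
  # sign convention: every PC weight on the behavior regressor is negative
  expect_true(all(res$readout_weights <= 0))
  # flipping any stored PC would flip its regressor weight positive
  refit <- natcont:::ridge_core(res$projections, y, 1e-6, scale. = FALSE)
  expect_true(all(refit$w <= 0))

  # rank-1 activity concentrates in the first PC
  Z <- outer(rnorm(100), c(1, 2, 3))
  r1 <- population_pca(list(Z))
  expect_gt(r1$explained_variance[1], 0.999)
  expect_warning(population_pca(list(Z[1:2, ])), "rank")
})

test_that("log-log slope fit is exact on pure power laws", {
  lag <- exp(seq(log(0.1), log(100), length.out = 25))
  expect_lt(abs(fit_loglog_slope(lag, lag^0.7) - 0.7), 1e-10)
  expect_lt(abs(fit_loglog_slope(lag, 3 * lag^0.5) - 0.5), 1e-10)
  expect_error(fit_loglog_slope(1, 1), "two")
})

test_that("identical songs give zero trajectory separation", {
  base <- rasterize(generate_song(default_song_params(), 60, seed = 2), 0.1)
  pop <- sample_population(5, 1e6, c(0.1, 2), seed = 3)
  sc <- trajectory_distance_scaling(pop, list(base, base), n_pairs = 1,
                                    n_reps = 1, seed = 1)
  expect_true(all(sc$mean_distance == 0))
  expect_true(is.na(sc$gamma_mean))
})

test_that("i.i.d. songs drive diffusive (gamma ~ 0.5) trajectory separation", {
  base <- rasterize(generate_song(default_song_params(), 300, seed = 4), 0.1)
  songs <- lapply(1:12, function(i) scramble_iid(base, seed = 60 + i))
  pop <- sample_population(10, 1e6, c(0.1, 2), seed = 5)
  sc <- trajectory_distance_scaling(pop, songs, n_pairs = 20, n_reps = 5,
                                    seed = 6)
  expect_lt(abs(sc$gamma_mean - 0.5), 0.1)

  # the non-adapting pure integrator is the textbook random-walk limit
  pop_lti <- sample_population(10, 1e6, Inf, seed = 7)
  sc2 <- trajectory_distance_scaling(pop_lti, songs, n_pairs = 20, n_reps = 5,
                                     seed = 6)
  expect_lt(abs(sc2$gamma_mean - 0.5), 0.1)
})

test_that("finite integration timescales saturate distances at long lags", {
  base <- rasterize(generate_song(default_song_params(), 300, seed = 4), 0.1)
  songs <- lapply(1:8, function(i) scramble_iid(base, seed = 80 + i))
  pop <- sample_population(10, 5, c(0.1, 2), seed = 5)  # tau_int = 5 s
  sc <- trajectory_distance_scaling(pop, songs, n_pairs = 10, n_reps = 3,
                                    seed = 6)
  # growth from early to mid lags, then a flat saturation regime
  d <- sc$mean_distance
  n <- length(d)
  early <- mean(d[1:3]); mid <- mean(d[ceiling(n / 2) + (-1:1)])
  late <- mean(d[(n - 2):n])
  expect_gt(mid / early, 1.5)
  expect_lt(abs(late / mid - 1), 0.5)
  # a restricted lag grid is available for fitting before saturation
  sc_small <- trajectory_distance_scaling(pop, songs, n_pairs = 10, n_reps = 3,
                                          lag_grid = exp(seq(log(0.1), log(5),
                                                             length.out = 10)),
                                          seed = 6)
  expect_gt(sc_small$gamma_mean, 0.3)
  expect_error(trajectory_distance_scaling(pop, songs, lag_grid = c(1, 1e5),
                                           seed = 1), "lag grid")
})

test_that("accumulation correlates with song density and transition rate", {
  segs <- lapply(1:20, function(i) {
    f <- exp(seq(-1, 1, length.out = 20))[i]
    sp <- song_gen_params(mean_dwell = c(quiet = 2 * f, sine = 0.6, pulse = 0.4))
    generate_song(sp, 60, seed = 300 + i)
  })
  # a slow non-adapting integrator accumulates total song: density corr ~ 1
  lti <- accumulation_correlations(ma_params(600, Inf, 0.5, 0.5), segs)
  expect_gt(lti$corr_density, 0.95)

  # transition-rate correlation strengthens as adaptation gets faster
  ct <- vapply(c(0.5, 2, 10), function(ta)
    accumulation_correlations(ma_params(60, ta, 0.5, 0.5), segs)$corr_transitions,
    numeric(1))
  expect_gt(ct[1], ct[3])

  # identical segments leave the correlation undefined but flagged
  same <- replicate(10, segs[[5]], simplify = FALSE)
  expect_warning(res <- accumulation_correlations(ma_params(60, 2, 0.5, 0.5),
                                                  same), "zero-variance")
  expect_true(res$flagged)
})

test_that("reservoir readouts reproduce realizable and constant targets", {
  base <- rasterize(generate_song(default_song_params(), 120, seed = 14), 0.1)
  pop <- sample_population(8, 120, c(0.1, 2), seed = 15)
  m <- simulate_population(pop, base, "ma")
  w <- seq(-1, 1, length.out = 8)
  target <- drop(m %*% w) + 2
  fit <- reservoir_readout(m, target)
  expect_lt(fit$rmse, 1e-6 * sd(target))
  expect_lt(reservoir_readout(m, rep(5, nrow(m)))$rmse, 1e-8)
})

test_that("MA trajectories express slow targets better than matched LN", {
  base <- rasterize(generate_song(default_song_params(), 320, seed = 16), 0.1)
  pop <- sample_population(10, 120, c(0.1, 2), seed = 17)
  sw <- reservoir_sweep(pop, list(base), periods = c(320, 640),
                        models = c("ma", "ln"))
  for (p in c(320, 640)) {
    rma <- sw$rmse[sw$model == "ma" & sw$period_s == p]
    rln <- sw$rmse[sw$model == "ln" & sw$period_s == p]
    expect_lt(rma, rln)
  }
})

test_that("smoothed variance explained rewards matching slow structure", {
  set.seed(20)
  t <- seq(0.1, 200, by = 0.1)
  slow <- sin(2 * pi * t / 100)
  target <- slow + rnorm(length(t), 0, 0.5)
  raw <- 1 - sum((target - slow)^2) / sum((target - mean(target))^2)
  smoothed <- lowfreq_ve(slow, target, dt = 0.1, smooth_window = 30)
  expect_gt(smoothed, raw)
  expect_gt(smoothed, 0.9)
})
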