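# Characterization analyses: response-entropy song information, population
# PCA with a behavioral sign convention, power-law scaling of
# inter-trajectory distances, accumulation correlations, and
# reservoir-style readouts of target waveforms.

#' Song information of a deterministic response (histogram entropy)
#'
#' The encoders are deterministic, so the conditional entropy of activity
#' given song is zero and the mutual information between activity and
#' song equals the response entropy H[r], estimated from the 1-D histogram
#' of activity samples over equal-width bins spanning the neuron's
#' observed range.
#'
#' @param values activity samples (finite numerics).
#' @param n_bins histogram bins (default 16).
#' @param support `"observed"` (the samples' min/max) or `"fixed"` (use
#'   `fixed_range`).
#' @param fixed_range length-2 range when `support = "fixed"`.
#' @return An `info_result`: `entropy_bits`, `normalized_entropy`
#'   (relative to uniform over `n_bins`), `n_bins`.
#' @export
response_entropy <- function(values, n_bins = 16,
                             support = c("observed", "fixed"),
                             fixed_range = NULL) {
  support <- match.arg(support)
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("need at least one finite sample")
  rng <- if (support == "observed") range(values) else fixed_range
  if (is.null(rng) || length(rng) != 2) stop("fixed support needs a range")
  h_bits <- 0
  if (diff(rng) > 0) {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    v <- pmin(pmax(values, rng[1]), rng[2])
    counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                            n_bins), nbins = n_bins)
    p <- counts / sum(counts)
    p <- p[p > 0]
    h_bits <- -sum(p * log2(p))
  }
  structure(list(entropy_bits = h_bits,
                 normalized_entropy = h_bits / log2(n_bins),
                 n_bins = n_bins),
            class = "info_result")
}

#' Population PCA with behavioral sign convention
#'
#' Principal components of the mean-centered pooled activity, sorted by
#' variance. When targets are supplied, a ridge regressor of the target is
#' re-fit on the PC projections and each component's sign is flipped so
#' that its weight on the walking-speed regressor is negative (an increase
#' along any PC then predicts slowing).
#'
#' @param recordings list of `population_recording` (or matrices); rows
#'   are pooled across sessions.
#' @param targets optional list of aligned target vectors for the sign
#'   convention.
#' @param alpha ridge penalty for the sign-fixing regressor.
#' @return list with `rotation` (neurons x PCs), `sdev`,
#'   `explained_variance`, `projections` (pooled), `readout_weights`
#'   (on the sign-fixed projections; `NULL` without targets), and
#'   `rank_flagged` when there are fewer pooled timepoints than neurons.
#' @export
population_pca <- function(recordings, targets = NULL, alpha = 1e-8) {
  X <- do.call(rbind, lapply(recordings, function(r)
    if (inherits(r, "population_recording")) r$activity else r))
  flagged <- nrow(X) < ncol(X)
  if (flagged) warning("fewer pooled timepoints than neurons: truncated rank")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pr$rotation
  proj <- pr$x
  w <- NULL
  if (!is.null(targets)) {
    y <- unlist(targets)
    if (length(y) != nrow(X)) stop("targets must align with pooled rows")
    fit <- ridge_core(proj, y, alpha, scale. = FALSE)
    flip <- fit$w > 0
    rot[, flip] <- -rot[, flip]
    proj[, flip] <- -proj[, flip]
    w <- fit$w
    w[flip] <- -w[flip]
  }
  list(rotation = rot, sdev = pr$sdev,
       explained_variance = pr$sdev^2 / sum(pr$sdev^2),
       projections = proj, readout_weights = w, rank_flagged = flagged)
}

#' Least-squares slope on log-log axes
#'
#' @param lag positive lags (seconds).
#' @param dist positive mean distances.
#' @return Scalar slope of `log(dist) ~ log(lag)`.
#' @export
fit_loglog_slope <- function(lag, dist) {
  keep <- is.finite(lag) & is.finite(dist) & lag > 0 & dist > 0
  x <- log(lag[keep]); y <- log(dist[keep])
  if (length(x) < 2) stop("need at least two positive points")
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Power-law scaling of inter-trajectory distances
#'
#' For repeated random selections of song pairs, computes the Euclidean
#' distance in neural state space between the two population trajectories
#' at matched elapsed times, averages distances over pairs, and fits a
#' least-squares line to log(mean distance) versus log(time). The slope
#' gamma characterizes how trajectories separate: gamma = 0.5 is the
#' diffusive (random-walk) limit of integrating uncorrelated inputs.
#'
#' @param pop a [population_params].
#' @param songs list of [song_annotation] or [song_raster] objects of
#'   equal duration.
#' @param model `"ma"` or `"ln"`.
#' @param n_pairs song pairs per repetition (default 100).
#' @param n_reps repetitions (default 30).
#' @param lag_grid lags (seconds); default 20 log-spaced points from 0.1 s
#'   to 80% of the song duration (choose the grid to exclude the
#'   saturation regime when integration timescales are finite).
#' @param dt raster resolution for annotation inputs (default 0.1 s).
#' @param seed pair-selection seed.
#' @return A `scaling_result`: `gamma_mean`, `gamma_sd`, `lag_s`,
#'   `mean_distance` (grand mean over reps), `n_pairs`, `n_reps`.
#' @export
trajectory_distance_scaling <- function(pop, songs, model = c("ma", "ln"),
                                        n_pairs = 100, n_reps = 30,
                                        lag_grid = NULL, dt = 0.1, seed = 1) {
  model <- match.arg(model)
  if (length(songs) < 2) stop("need at least 2 songs")
  rasters <- lapply(songs, function(s) {
    if (inherits(s, "song_raster")) s else rasterize(s, dt)
  })
  nb <- vapply(rasters, function(r) length(r$I_s), integer(1))
  n <- min(nb)
  dt_use <- rasters[[1]]$dt
  dur <- n * dt_use
  if (is.null(lag_grid))
    lag_grid <- exp(seq(log(max(dt_use, 0.1)), log(0.8 * dur), length.out = 20))
  idx <- unique(pmin(pmax(round(lag_grid / dt_use), 1), n))
  lags <- idx * dt_use
  if (max(lag_grid) > dur + 1e-9) stop("lag grid outside song duration")
  # simulate once per song; keep only the lag-index rows
  traj <- lapply(rasters, function(r) {
    m <- simulate_population(pop, r, model)
    m[idx, , drop = FALSE]
  })
  S <- length(traj)
  all_pairs <- t(utils::combn(S, 2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  gammas <- numeric(n_reps)
  mean_d_acc <- matrix(0, n_reps, length(idx))
  for (rep in seq_len(n_reps)) {
    pick <- all_pairs[sample.int(nrow(all_pairs), n_pairs,
                                 replace = n_pairs > nrow(all_pairs)), ,
                      drop = FALSE]
    dsum <- numeric(length(idx))
    for (q in seq_len(nrow(pick))) {
      dd <- traj[[pick[q, 1]]] - traj[[pick[q, 2]]]
      dsum <- dsum + sqrt(rowSums(dd^2))
    }
    md <- dsum / nrow(pick)
    mean_d_acc[rep, ] <- md
    gammas[rep] <- if (sum(md > 0) >= 2) fit_loglog_slope(lags, md) else NA_real_
  }
  structure(list(gamma_mean = if (all(is.na(gammas))) NA_real_
                              else mean(gammas, na.rm = TRUE),
                 gamma_sd = sd(gammas),
                 gammas = gammas, lag_s = lags,
                 mean_distance = colMeans(mean_d_acc),
                 n_pairs = n_pairs, n_reps = n_reps),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("<scaling_result: gamma = %.3f +/- %.3f (%d reps x %d pairs, lags %.2g-%.3g s)>\n",
              x$gamma_mean, x$gamma_sd, x$n_reps, x$n_pairs,
              min(x$lag_s), max(x$lag_s)))
  invisible(x)
}

#' Correlation of accumulated activity with song features
#'
#' Simulates one MA neuron over each song segment from a zero initial
#' state and correlates (Pearson) the final activity with the segment's
#' song density and transition rate.
#'
#' @param params an [ma_params].
#' @param songs list of [song_annotation] segments (each at least
#'   `segment_len` long; >= 10 segments).
#' @param segment_len seconds of each segment used (default 60).
#' @param dt raster resolution.
#' @return list with `corr_density`, `corr_transitions` (NA with a flag if
#'   a feature has zero variance across segments), and the per-segment
#'   table.
#' @export
accumulation_correlations <- function(params, songs, segment_len = 60,
                                      dt = 0.01) {
  if (length(songs) < 10) stop("need at least 10 segments")
  rows <- do.call(rbind, lapply(songs, function(s) {
    stopifnot(inherits(s, "song_annotation"))
    if (s$duration < segment_len) stop("segment shorter than segment_len")
    fe <- song_features(s, span = c(0, segment_len))
    iv <- s$intervals[s$intervals$start < segment_len, , drop = FALSE]
    if (nrow(iv) > 0) iv$end <- pmin(iv$end, segment_len)
    seg <- song_annotation(iv, segment_len, s$session_id)
    tr <- ma_simulate(params, rasterize(seg, dt))
    data.frame(final_activity = tail(tr$r, 1),
               song_density = fe$song_density,
               transitions_per_min = fe$transitions_per_min)
  }))
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  cd <- safe_cor(rows$final_activity, rows$song_density)
  ct <- safe_cor(rows$final_activity, rows$transitions_per_min)
  if (is.na(cd) || is.na(ct)) warning("zero-variance feature: correlation undefined")
  list(corr_density = cd, corr_transitions = ct,
       flagged = is.na(cd) || is.na(ct), segments = rows)
}

#' Reservoir-style linear readout of a target waveform
#'
#' Trains a ridge readout (tiny penalty, essentially least squares) of a
#' target time series from the neuron activity columns of one recording,
#' and evaluates the RMSE on the same trajectory (in-sample, matching the
#' single-song demonstration protocol).
#'
#' @param recording a `population_recording` or activity matrix.
#' @param target numeric target sampled on the recording grid.
#' @param alpha ridge penalty (default 1e-15).
#' @return A `reservoir_fit`: `weights`, `intercept`, `rmse`, `alpha`,
#'   `prediction`.
#' @export
reservoir_readout <- function(recording, target, alpha = 1e-15) {
  X <- if (inherits(recording, "population_recording")) recording$activity
       else recording
  if (nrow(X) != length(target)) stop("target must be sampled on the recording grid")
  fit <- ridge_core(X, target, alpha)
  pred <- ridge_predict(fit, X)
  structure(list(weights = fit$w, intercept = fit$my,
                 rmse = sqrt(mean((target - pred)^2)), alpha = alpha,
                 prediction = pred),
            class = "reservoir_fit")
}

#' Reservoir RMSE versus target period
#'
#' For each song and each target period, simulates the population
#' trajectory, trains an in-sample linear readout to reproduce a sine wave
#' of that period, and records the RMSE. Comparing `"ma"` with `"ln"`
#' trajectories shows which code can be linearly transformed into slow
#' output signals.
#'
#' @param pop a [population_params].
#' @param songs list of [song_annotation] or [song_raster].
#' @param periods target sine periods, seconds. `NULL` uses twice each
#'   song's duration (half-period equal to the song).
#' @param models encoders to evaluate.
#' @param dt raster resolution for annotation inputs.
#' @param alpha ridge penalty.
#' @return data.frame `song`, `period_s`, `model`, `rmse`.
#' @export
reservoir_sweep <- function(pop, songs, periods = NULL,
                            models = c("ma", "ln"), dt = 0.1, alpha = 1e-15) {
  rows <- list()
  for (si in seq_along(songs)) {
    s <- songs[[si]]
    raster <- if (inherits(s, "song_raster")) s else rasterize(s, dt)
    dur <- length(raster$I_s) * raster$dt
    tt <- raster$t0 + seq_along(raster$I_s) * raster$dt
    pers <- if (is.null(periods)) 2 * dur else periods
    for (model in models) {
      m <- simulate_population(pop, raster, model)
      for (p in pers) {
        tgt <- sin(2 * pi * tt / p)
        fit <- reservoir_readout(m, tgt, alpha)
        rows[[length(rows) + 1]] <- data.frame(song = si, period_s = p,
                                               model = model, rmse = fit$rmse)
      }
    }
  }
  do.call(rbind, rows)
}

#' Variance explained after low-pass smoothing
#'
#' Helper for asking how much of the slow component of behavior a
#' prediction captures: both target and prediction are smoothed by a
#' symmetric moving average before computing 1 - SSE/SStot. Exploratory;
#' not benchmarked against published values.
#'
#' @param prediction,target aligned numeric vectors on a uniform grid.
#' @param dt sample spacing, seconds.
#' @param smooth_window moving-average window, seconds (default 30).
#' @return Scalar variance explained of the smoothed signals.
#' @export
lowfreq_ve <- function(prediction, target, dt, smooth_window = 30) {
  k <- max(1L, round(smooth_window / dt))
  if (k %% 2 == 0) k <- k + 1L
  sm <- function(x) stats::filter(x, rep(1 / k, k), sides = 2)
  p <- sm(prediction); y <- sm(target)
  keep <- !is.na(p) & !is.na(y)
  1 - sum((y[keep] - p[keep])^2) / sum((y[keep] - mean(y[keep]))^2)
}
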