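# Natural Continuation steps 3-4: artificial population recordings over
# behavioral sessions, and scoring of encoding models by held-out
# ridge-readout prediction of behavior.

#' A courtship session: song stimulus plus behavior trace
#'
#' @param session_id identifier.
#' @param song a [song_annotation].
#' @param behavior data.frame with columns `t` (seconds) and
#'   `walking_speed` (mm/s, >= 0); optional further columns (e.g.
#'   `forward`, `lateral`) may be used as alternative targets.
#' @return An object of class `nc_session`.
#' @export
nc_session <- function(session_id, song, behavior) {
  stopifnot(inherits(song, "song_annotation"))
  if (!all(c("t", "walking_speed") %in% names(behavior)))
    stop("behavior needs columns t, walking_speed")
  if (any(behavior$t < -1e-9) || any(behavior$t > song$duration + 1e-9))
    stop("behavior times must lie within [0, duration]")
  if (any(behavior$walking_speed < 0)) stop("walking_speed must be >= 0")
  if (is.unsorted(behavior$t)) behavior <- behavior[order(behavior$t), ]
  structure(list(session_id = session_id, song = song, behavior = behavior),
            class = "nc_session")
}

#' @export
print.nc_session <- function(x, ...) {
  cat(sprintf("<nc_session '%s': %.0f s, %d behavior samples, song density %.3f>\n",
              x$session_id, x$song$duration, nrow(x$behavior),
              song_features(x$song)$song_density))
  invisible(x)
}

#' Simulate an artificial population recording over a session
#'
#' Each neuron is simulated on the session's song raster from a zero
#' initial state; activity is sampled at `target_times`, where the value
#' reported at time t is the model state at the last raster bin boundary
#' at or before t (so it depends on song strictly up to t).
#'
#' @param pop a [population_params].
#' @param session an [nc_session].
#' @param model `"ma"` or `"ln"`.
#' @param dt_song raster resolution, seconds.
#' @param target_times sampling times (seconds) within the session.
#' @return A `population_recording`: list with `session_id`, `t`, and the
#'   time-by-neuron `activity` matrix.
#' @export
simulate_session <- function(pop, session, model = c("ma", "ln"),
                             dt_song = 0.01, target_times) {
  model <- match.arg(model)
  stopifnot(inherits(session, "nc_session"))
  if (any(target_times < 0) || any(target_times > session$song$duration + 1e-9))
    stop("target_times must lie within the session")
  raster <- rasterize(session$song, dt_song)
  m <- simulate_population(pop, raster, model)
  idx <- pmin(floor(target_times / dt_song + 1e-9), nrow(m))
  act <- matrix(0, length(target_times), ncol(m),
                dimnames = list(NULL, colnames(m)))
  pos <- idx >= 1
  act[pos, ] <- m[idx[pos], , drop = FALSE]
  structure(list(session_id = session$session_id, t = target_times,
                 activity = act),
            class = "population_recording")
}

#' Forward-averaged behavioral target
#'
#' `target(t)` is the mean of the behavior samples in `(t, t + window]`;
#' times without any sample in the window are dropped.
#'
#' @param session an [nc_session].
#' @param window forward-averaging window, seconds (default 1).
#' @param times candidate times; default a `stride`-spaced grid.
#' @param stride spacing of the default time grid, seconds.
#' @param column behavior column to average (default `"walking_speed"`).
#' @return data.frame with columns `t` and `target`.
#' @export
forward_average_target <- function(session, window = 1, times = NULL,
                                   stride = 1, column = "walking_speed") {
  stopifnot(inherits(session, "nc_session"))
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  b <- session$behavior
  tb <- b$t; v <- b[[column]]
  if (is.null(v)) stop("unknown behavior column")
  if (window > session$song$duration) stop("window exceeds the session")
  if (is.null(times)) times <- seq(0, session$song$duration - window, by = stride)
  times <- times[times + window <= max(tb) + 1e-9]
  cs <- cumsum(v)
  lo <- findInterval(times, tb)            # samples with tb <= t (excluded)
  hi <- findInterval(times + window + 1e-12, tb)
  cnt <- hi - lo
  keep <- cnt >= 1
  tot <- (c(0, cs)[hi + 1] - c(0, cs)[lo + 1])[keep]
  data.frame(t = times[keep], target = tot / cnt[keep])
}

# --- ridge machinery -------------------------------------------------------

# standardize-train/apply-test ridge with unpenalized intercept, solved by
# the normal equations; deterministic
ridge_core <- function(Xtr, ytr, alpha, scale. = TRUE) {
  mx <- colMeans(Xtr)
  sx <- if (scale.) apply(Xtr, 2, sd) else rep(1, ncol(Xtr))
  sx[!is.finite(sx) | sx <= 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, mx), 2, sx, "/")
  my <- mean(ytr)
  A <- crossprod(Ztr) + diag(alpha, ncol(Ztr))
  w <- solve(A, crossprod(Ztr, ytr - my))
  list(w = drop(w), mx = mx, sx = sx, my = my, alpha = alpha)
}

ridge_predict <- function(fit, X, rotation = NULL) {
  Z <- sweep(sweep(X, 2, fit$mx), 2, fit$sx, "/")
  if (!is.null(rotation)) Z <- Z %*% rotation
  drop(fit$my + Z %*% fit$w)
}

#' Fit a ridge readout of behavior from population activity
#'
#' Solves the ridge normal equations on the pooled training rows; features
#' are standardized on the training data and the intercept is unpenalized.
#'
#' @param recordings list of `population_recording` (or matrices).
#' @param targets list of numeric target vectors, aligned row-wise.
#' @param alpha ridge penalty (added to the standardized Gram matrix).
#' @return An object of class `nc_readout` with `weights` (standardized
#'   scale), `intercept`, `alpha`, and the training centering/scaling.
#' @export
fit_readout <- function(recordings, targets, alpha = 1) {
  X <- do.call(rbind, lapply(recordings, function(r)
    if (inherits(r, "population_recording")) r$activity else r))
  y <- unlist(targets)
  if (nrow(X) != length(y)) stop("recordings and targets must align row-wise")
  fit <- ridge_core(X, y, alpha)
  structure(list(weights = fit$w, intercept = fit$my, alpha = alpha,
                 center = fit$mx, scale = fit$sx),
            class = "nc_readout")
}

#' @export
predict.nc_readout <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "population_recording")) newdata$activity else newdata
  ridge_predict(list(w = object$weights, mx = object$center, sx = object$scale,
                     my = object$intercept), X)
}

# deterministic session-level splits shared across models and baselines
make_splits <- function(n_sessions, n_splits, train_frac, seed) {
  n_train <- min(max(round(train_frac * n_sessions), 1), n_sessions - 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_splits), function(k) sort(sample.int(n_sessions, n_train)))
}

# evaluate one train/test partition of per-session feature matrices
ridge_eval <- function(ftr, ytr, fte, yte, alpha, n_pcs = NULL) {
  Xtr <- do.call(rbind, ftr); Ytr <- unlist(ytr)
  rot <- NULL
  fit <- ridge_core(Xtr, Ytr, alpha)
  if (!is.null(n_pcs)) {
    Ztr <- sweep(sweep(Xtr, 2, fit$mx), 2, fit$sx, "/")
    k <- min(n_pcs, ncol(Ztr))
    rot <- prcomp(Ztr, center = FALSE, scale. = FALSE)$rotation[, seq_len(k),
                                                                drop = FALSE]
    P <- Ztr %*% rot
    A <- crossprod(P) + diag(alpha, ncol(P))
    fit$w <- drop(solve(A, crossprod(P, Ytr - fit$my)))
  }
  preds <- lapply(fte, function(X) ridge_predict(fit, X, rot))
  yte_pool <- unlist(yte); pred_pool <- unlist(preds)
  list(preds = preds, sse = sum((yte_pool - pred_pool)^2),
       sstot = sum((yte_pool - mean(yte_pool))^2))
}

choose_alpha <- function(features, targets, alpha_grid, n_pcs = NULL) {
  S <- length(features)
  if (S < 2) return(alpha_grid[ceiling(length(alpha_grid) / 2)])
  folds <- seq_len(S)  # leave-one-session-out over training sessions
  sse <- vapply(alpha_grid, function(a) {
    sum(vapply(folds, function(f) {
      ridge_eval(features[-f], targets[-f], features[f], targets[f], a, n_pcs)$sse
    }, numeric(1)))
  }, numeric(1))
  alpha_grid[which.min(sse)]
}

score_feature_splits <- function(features, targets, alpha = NULL, n_splits = 30,
                                 train_frac = 0.8, seed = 1, n_pcs = NULL,
                                 alpha_grid = 10^seq(-4, 4), pooled = TRUE) {
  S <- length(features)
  if (S < 2) stop("need at least 2 sessions")
  splits <- make_splits(S, n_splits, train_frac, seed)
  ve <- numeric(n_splits)
  alphas <- numeric(n_splits)
  for (k in seq_len(n_splits)) {
    tr <- splits[[k]]; te <- setdiff(seq_len(S), tr)
    a <- if (is.null(alpha)) choose_alpha(features[tr], targets[tr],
                                          alpha_grid, n_pcs) else alpha
    alphas[k] <- a
    ev <- ridge_eval(features[tr], targets[tr], features[te], targets[te],
                     a, n_pcs)
    if (pooled) {
      ve[k] <- 1 - ev$sse / ev$sstot
    } else {
      per <- mapply(function(p, y) 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                    ev$preds, targets[te])
      ve[k] <- mean(per)
    }
  }
  structure(list(ve_per_split = ve, mean_ve = mean(ve),
                 se_ve = sd(ve) / sqrt(n_splits), n_splits = n_splits,
                 train_frac = train_frac, splits = splits, alphas = alphas),
            class = "nc_score")
}

#' @export
print.nc_score <- function(x, ...) {
  cat(sprintf("<nc_score: mean VE = %.4f (SE %.4f) over %d splits>\n",
              x$mean_ve, x$se_ve, x$n_splits))
  invisible(x)
}

#' Score an encoding model by held-out behavioral prediction
#'
#' The Natural Continuation score: artificial recordings are generated for
#' every session, a ridge readout is fit on the pooled training sessions
#' of each split, and variance explained (1 - SSE/SStot) is computed over
#' the pooled held-out timepoints. Splits are at the session level and are
#' a deterministic function of `(seed, n_splits, train_frac)`, so
#' different models and baselines can be compared on paired splits.
#'
#' @param pop a [population_params].
#' @param sessions list of [nc_session].
#' @param model `"ma"` or `"ln"`.
#' @param alpha ridge penalty; `NULL` (default) selects it per split by
#'   leave-one-session-out cross-validation on the training sessions over
#'   `alpha_grid`.
#' @param n_splits,train_frac split protocol (defaults 30 and 0.8).
#' @param seed split RNG seed.
#' @param window forward-averaging window for the walking-speed target.
#' @param stride target sampling stride, seconds.
#' @param dt_song raster resolution for the simulations.
#' @param n_pcs if set, recordings are projected onto the top `n_pcs`
#'   training-data PCs before the readout.
#' @param pooled pool held-out timepoints across sessions (default) or
#'   average per-session VE.
#' @param alpha_grid candidate penalties for internal selection.
#' @param column behavior column to predict.
#' @return An `nc_score` object: `ve_per_split`, `mean_ve`, `se_ve`,
#'   `n_splits`, `train_frac`, and the splits used.
#' @export
nc_score <- function(pop, sessions, model = c("ma", "ln"), alpha = NULL,
                     n_splits = 30, train_frac = 0.8, seed = 1, window = 1,
                     stride = 1, dt_song = 0.01, n_pcs = NULL, pooled = TRUE,
                     alpha_grid = 10^seq(-4, 4), column = "walking_speed") {
  model <- match.arg(model)
  if (length(sessions) < 2) stop("need at least 2 sessions")
  prep <- lapply(sessions, function(s) {
    tg <- forward_average_target(s, window = window, stride = stride,
                                 column = column)
    rec <- simulate_session(pop, s, model, dt_song, tg$t)
    list(X = rec$activity, y = tg$target)
  })
  score_feature_splits(lapply(prep, `[[`, "X"), lapply(prep, `[[`, "y"),
                       alpha = alpha, n_splits = n_splits,
                       train_frac = train_frac, seed = seed, n_pcs = n_pcs,
                       alpha_grid = alpha_grid, pooled = pooled)
}

#' Shuffle songs across sessions
#'
#' Permutes the song/behavior pairing (preferring a derangement), leaving
#' behavior untouched; each reassigned song is truncated, or padded with
#' quiet, to the receiving session's duration. Used as a negative control:
#' predictivity surviving the shuffle does not reflect song history.
#'
#' @param sessions list of [nc_session] (>= 2).
#' @param seed permutation seed.
#' @return list of [nc_session] with permuted songs.
#' @export
shuffle_songs <- function(sessions, seed = 1) {
  n <- length(sessions)
  if (n < 2) stop("need at least 2 sessions to shuffle")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- if (n == 2) c(2L, 1L) else {
    p <- sample.int(n)
    for (i in seq_len(100)) {
      if (!any(p == seq_len(n))) break
      p <- sample.int(n)
    }
    p
  }
  lapply(seq_len(n), function(i) {
    s <- sessions[[i]]
    donor <- sessions[[perm[i]]]$song
    dur <- s$song$duration
    iv <- donor$intervals
    iv <- iv[iv$start < dur, , drop = FALSE]
    if (nrow(iv) > 0) iv$end <- pmin(iv$end, dur)
    song <- song_annotation(iv, duration = dur,
                            session_id = paste0(s$session_id, "_shuffled"))
    nc_session(s$session_id, song, s$behavior)
  })
}

#' Baseline predictors of behavior
#'
#' Scores simple non-population predictors with the identical session-level
#' split protocol (same seed, hence paired splits): (a) the timestamp
#' (elapsed session time) alone; (b) the trailing 2-minute mean song-bout
#' duration; (c) a pair of linear filters applied directly to the binary
#' sine and pulse inputs, with filter taps fit by ridge on lag-binned
#' inputs.
#'
#' @param sessions list of [nc_session].
#' @param baselines subset of `"timestamp"`, `"bout_duration"`,
#'   `"song_filters"`.
#' @param bout_window trailing window for the bout-duration baseline (s).
#' @param lag_edges increasing lag-bin edges (seconds) for the filter
#'   baseline; each feature is the fraction of a mode in a trailing lag bin.
#' @param dt_song raster resolution for the filter baseline.
#' @inheritParams nc_score
#' @return data.frame with one row per baseline (`baseline`, `mean_ve`,
#'   `se_ve`); the full `nc_score` objects are attached as attribute
#'   `"scores"`.
#' @export
baseline_predictors <- function(sessions,
                                baselines = c("timestamp", "bout_duration",
                                              "song_filters"),
                                window = 1, stride = 1, bout_window = 120,
                                lag_edges = c(0, 1, 2, 5, 10, 20, 40, 80, 160),
                                dt_song = 0.1, alpha = NULL, n_splits = 30,
                                train_frac = 0.8, seed = 1, pooled = TRUE,
                                alpha_grid = 10^seq(-4, 4),
                                column = "walking_speed") {
  baselines <- match.arg(baselines, several.ok = TRUE)
  targets <- lapply(sessions, forward_average_target, window = window,
                    stride = stride, column = column)
  feats_for <- function(b) {
    lapply(seq_along(sessions), function(i) {
      s <- sessions[[i]]; tt <- targets[[i]]$t
      if (b == "timestamp") {
        matrix(tt, ncol = 1, dimnames = list(NULL, "t"))
      } else if (b == "bout_duration") {
        matrix(bout_stats(s$song, times = tt, window = bout_window)$mean_bout_duration,
               ncol = 1, dimnames = list(NULL, "mean_bout_duration"))
      } else {
        lagged_song_features(s$song, tt, lag_edges, dt_song)
      }
    })
  }
  scores <- lapply(baselines, function(b) {
    score_feature_splits(feats_for(b), lapply(targets, `[[`, "target"),
                         alpha = alpha, n_splits = n_splits,
                         train_frac = train_frac, seed = seed,
                         alpha_grid = alpha_grid, pooled = pooled)
  })
  names(scores) <- baselines
  out <- data.frame(baseline = baselines,
                    mean_ve = vapply(scores, `[[`, numeric(1), "mean_ve"),
                    se_ve = vapply(scores, `[[`, numeric(1), "se_ve"))
  attr(out, "scores") <- scores
  out
}

# trailing lag-binned sine/pulse fractions: feature (m, k) at time t is the
# fraction of mode m in (t - edges[k+1], t - edges[k]]
lagged_song_features <- function(song, times, lag_edges, dt_song = 0.1) {
  raster <- rasterize(song, dt_song)
  K <- length(lag_edges) - 1
  out <- matrix(0, length(times), 2 * K)
  colnames(out) <- c(paste0("sine_lag", seq_len(K)), paste0("pulse_lag", seq_len(K)))
  cs <- c(0, cumsum(raster$I_s)); cp <- c(0, cumsum(raster$I_p))
  idx <- pmin(floor(times / dt_song + 1e-9), length(raster$I_s))
  for (k in seq_len(K)) {
    lo <- pmax(idx - round(lag_edges[k + 1] / dt_song), 0)
    hi <- pmax(idx - round(lag_edges[k] / dt_song), 0)
    n <- pmax(hi - lo, 0)
    out[, k] <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / n, 0)
    out[, K + k] <- ifelse(n > 0, (cp[hi + 1] - cp[lo + 1]) / n, 0)
  }
  out
}

#' Sweep analyses of the NC score
#'
#' - `"population_size"`: mean VE versus population size for repeated
#'   random draws from the factory.
#' - `"n_pcs"`: VE with recordings projected onto the top-k PCs.
#' - `"regime_grid"`: all fast/medium/slow integration-timescale by
#'   fast/medium/slow/no-adaptation cells (timescales resampled inside
#'   each regime).
#' - `"heterogeneity"`: heterogeneous tau_a with fixed tau_int versus
#'   heterogeneous tau_int with fixed tau_a.
#'
#' @param pop_factory `function(n, seed)` returning a [population_params];
#'   default samples the fast-adapt/slow-integrate regime.
#' @param sessions list of [nc_session].
#' @param sweep which sweep to run.
#' @param sizes population sizes (`population_size`).
#' @param n_instantiations random redraws per size (`population_size`).
#' @param ks PC counts (`n_pcs`; default 1..n_neurons).
#' @param n_neurons base population size for the other sweeps.
#' @param het_fixed_tau_int,het_fixed_tau_a fixed values for the
#'   heterogeneity comparison (seconds).
#' @param seed base seed for population draws.
#' @param ... passed to [nc_score] (e.g. `alpha`, `n_splits`, `stride`).
#' @return A tidy data.frame of mean VE versus the swept variable.
#' @export
nc_sweep <- function(pop_factory = NULL, sessions,
                     sweep = c("population_size", "n_pcs", "regime_grid",
                               "heterogeneity"),
                     sizes = c(1, 2, 5, 10, 15, 20), n_instantiations = 30,
                     ks = NULL, n_neurons = 20, het_fixed_tau_int = 120,
                     het_fixed_tau_a = 0.5, seed = 1, ...) {
  sweep <- match.arg(sweep)
  if (is.null(pop_factory))
    pop_factory <- function(n, seed)
      sample_population(n, c(20, 120), c(0.1, 2), "uniform01", seed)
  if (sweep == "population_size") {
    rows <- do.call(rbind, lapply(sizes, function(nn) {
      ves <- vapply(seq_len(n_instantiations), function(j) {
        pop <- pop_factory(nn, seed + 131 * j + 7919 * nn)
        nc_score(pop, sessions, seed = seed, ...)$mean_ve
      }, numeric(1))
      data.frame(size = nn, mean_ve = mean(ves), sd_ve = sd(ves))
    }))
    rows
  } else if (sweep == "n_pcs") {
    pop <- pop_factory(n_neurons, seed)
    if (is.null(ks)) ks <- seq_len(n_neurons)
    do.call(rbind, lapply(ks, function(k) {
      sc <- nc_score(pop, sessions, n_pcs = k, seed = seed, ...)
      data.frame(n_pcs = k, mean_ve = sc$mean_ve, se_ve = sc$se_ve)
    }))
  } else if (sweep == "regime_grid") {
    pop0 <- pop_factory(n_neurons, seed)
    grid <- expand.grid(tau_int_regime = c("fast", "medium", "slow"),
                        tau_a_regime = c("fast", "medium", "slow", "none"),
                        stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      pop <- perturb_population(pop0, "resample_regime", field = "tau_int",
                                spec = grid$tau_int_regime[i], seed = seed + i)
      pop <- perturb_population(pop, "resample_regime", field = "tau_a",
                                spec = grid$tau_a_regime[i],
                                seed = seed + 100 + i)
      sc <- nc_score(pop, sessions, seed = seed, ...)
      data.frame(tau_int_regime = grid$tau_int_regime[i],
                 tau_a_regime = grid$tau_a_regime[i],
                 mean_ve = sc$mean_ve, se_ve = sc$se_ve)
    }))
  } else {
    cfgs <- list(
      het_tau_a = sample_population(n_neurons, het_fixed_tau_int, c(0.1, 2),
                                    "uniform01", seed),
      het_tau_int = sample_population(n_neurons, c(20, 120), het_fixed_tau_a,
                                      "uniform01", seed))
    do.call(rbind, lapply(names(cfgs), function(nm) {
      sc <- nc_score(cfgs[[nm]], sessions, seed = seed, ...)
      data.frame(config = nm, mean_ve = sc$mean_ve, se_ve = sc$se_ve)
    }))
  }
}
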