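# Synthetic-data generation: ground-truth populations, synthetic
# block-stimulus recordings, and synthetic courtship studies with known
# song-to-behavior mappings, so every pipeline stage is testable without
# any external dataset.

#' Default song generator parameters
#'
#' Exponential dwells with mean quiet 3 s, sine 0.6 s, pulse 0.4 s and the
#' default transition matrix, producing bouts of roughly 1-30 s separated
#' by quiet gaps: an order-of-magnitude emulation of courtship song
#' statistics, not a calibration to any measured distribution.
#'
#' @return A [song_gen_params].
#' @export
default_song_params <- function() song_gen_params()

#' Generate a synthetic courtship study
#'
#' Per session: a song is generated from the semi-Markov model, the
#' ground-truth MA population is simulated over it, and walking speed is
#' produced as a floored linear readout of the population activity plus
#' Gaussian noise:
#' `speed(t) = max(0, intercept + w . activity(t) + N(0, noise_sd))`.
#' Per-session seeds are derived arithmetically from `seed`, so earlier
#' sessions are unchanged when `n_sessions` grows.
#'
#' Courtship sessions differ substantially in how much and how densely the
#' male sings, and that across-session variability is what makes the
#' song/behavior pairing informative. The generator therefore scales each
#' session's mean dwell times by lognormal session-level factors
#' (`song_heterogeneity`), giving sessions a realistic spread of song
#' densities; with no heterogeneity every session shares one accumulation
#' profile and even mispaired songs predict it.
#'
#' @param n_sessions number of sessions.
#' @param session_duration seconds per session.
#' @param song_params a [song_gen_params].
#' @param pop ground-truth [population_params]; default a 20-neuron
#'   fast-adapt/slow-integrate draw.
#' @param readout_weights per-neuron weights (mm/s per activity unit);
#'   default negative weights (song accumulation predicts slowing).
#' @param intercept baseline walking speed, mm/s.
#' @param noise_sd behavioral noise SD, mm/s.
#' @param song_heterogeneity length-2 SDs of the session-level log scale
#'   factors applied to the quiet and mode mean dwells.
#' @param behavior_rate behavior sampling rate, Hz.
#' @param dt_song raster resolution for the ground-truth simulation.
#' @param seed master seed.
#' @return list of [nc_session]; the ground truth (`pop`, `weights`,
#'   `intercept`, `noise_sd`, per-session seeds) is attached as attribute
#'   `"ground_truth"`.
#' @export
make_synthetic_study <- function(n_sessions = 10, session_duration = 300,
                                 song_params = default_song_params(),
                                 pop = NULL, readout_weights = NULL,
                                 intercept = 12, noise_sd = 0,
                                 song_heterogeneity = c(quiet = 0.7, modes = 0.4),
                                 behavior_rate = 10, dt_song = 0.01,
                                 seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(pop))
    pop <- sample_population(20, c(20, 120), c(0.1, 2), "uniform01",
                             seed = seed + 901)
  n <- nrow(pop)
  if (is.null(readout_weights)) {
    old <- .Random.seed_save()
    set.seed(as.integer(seed) + 577)
    readout_weights <- runif(n, -1.5, -0.5)
    .Random.seed_restore(old)
  }
  if (length(readout_weights) != n)
    stop("readout_weights length must equal the population size")
  session_seeds <- as.integer(seed) + 7919L * seq_len(n_sessions)
  sessions <- lapply(seq_len(n_sessions), function(i) {
    sid <- sprintf("synth%03d", i)
    old <- .Random.seed_save()
    set.seed(session_seeds[i] + 2L)
    dwell <- song_params$mean_dwell *
      exp(rnorm(2, 0, song_heterogeneity))[c(1, 2, 2)]
    .Random.seed_restore(old)
    sp_i <- song_gen_params(dwell, song_params$transition_probs,
                            song_params$dwell_family, song_params$gamma_shape)
    song <- generate_song(sp_i, session_duration,
                          seed = session_seeds[i], session_id = sid)
    raster <- rasterize(song, dt_song)
    act <- simulate_population(pop, raster, "ma")
    tb <- seq(1 / behavior_rate, session_duration, by = 1 / behavior_rate)
    idx <- pmin(floor(tb / dt_song + 1e-9), nrow(act))
    drive <- intercept + as.vector(act[idx, , drop = FALSE] %*% readout_weights)
    old <- .Random.seed_save()
    set.seed(session_seeds[i] + 1L)
    eps <- if (noise_sd > 0) rnorm(length(tb), 0, noise_sd) else 0
    .Random.seed_restore(old)
    nc_session(sid, song,
               data.frame(t = tb, walking_speed = pmax(drive + eps, 0)))
  })
  attr(sessions, "ground_truth") <- list(pop = pop, weights = readout_weights,
                                         intercept = intercept,
                                         noise_sd = noise_sd,
                                         session_seeds = session_seeds)
  sessions
}

#' Generate synthetic block-stimulus recordings
#'
#' Per ground-truth neuron, the noiseless sine and pulse block responses
#' are computed over the stimulus-plus-post window at the frame rate,
#' i.i.d. Gaussian noise is added per trial, and trials are averaged.
#'
#' @param ground_truth a [population_params] or list of [ma_params].
#' @param noise_sd per-trial noise SD (activity units).
#' @param n_trials trials averaged per neuron.
#' @param spec a [block_stimulus_spec].
#' @param seed master seed (per-neuron streams derived arithmetically).
#' @return list of [block_response_set], one per neuron; the ground-truth
#'   parameters are attached as attribute `"ground_truth"`.
#' @export
make_block_recordings <- function(ground_truth, noise_sd = 0, n_trials = 10,
                                  spec = block_stimulus_spec(), seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  plist <- if (inherits(ground_truth, "population_params")) {
    lapply(seq_len(nrow(ground_truth)), function(i)
      pop_row_params(ground_truth, i))
  } else ground_truth
  tt <- block_frame_times(spec)
  out <- lapply(seq_along(plist), function(i) {
    p <- plist[[i]]
    make_trace <- function(mode, sub_seed) {
      clean <- ma_block_response(p, mode, tt, spec$stim_duration)
      if (noise_sd > 0) {
        old <- .Random.seed_save()
        set.seed(as.integer(seed) + 104729L * i + sub_seed)
        noisy <- replicate(n_trials, clean + rnorm(length(tt), 0, noise_sd))
        .Random.seed_restore(old)
        rowMeans(noisy)
      } else clean
    }
    block_response_set(sine = data.frame(t = tt, value = make_trace("sine", 0L)),
                       pulse = data.frame(t = tt, value = make_trace("pulse", 1L)),
                       recording_id = sprintf("gt%03d", i))
  })
  attr(out, "ground_truth") <- plist
  out
}
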