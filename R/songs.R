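# Song sequences: annotations, rasters, generation, scrambling, features.
#
# A courtship song is a sequence of sine and pulse segments separated by
# quiet. Times are in seconds; intervals are half-open [start, end).

SONG_MODES <- c("sine", "pulse")

#' Construct a song annotation
#'
#' An annotation is an ordered list of non-overlapping sine/pulse intervals
#' over a session of known duration; uncovered time is quiet.
#'
#' @param intervals data.frame with columns `start`, `end` (seconds) and
#'   `mode` (`"sine"` or `"pulse"`). May have zero rows (all-quiet session).
#' @param duration session duration in seconds.
#' @param session_id identifier string.
#' @return An object of class `song_annotation`.
#' @export
song_annotation <- function(intervals, duration, session_id = "session") {
  if (is.null(intervals) || nrow(intervals) == 0) {
    intervals <- data.frame(start = numeric(0), end = numeric(0),
                            mode = character(0))
  }
  intervals <- data.frame(start = as.numeric(intervals$start),
                          end = as.numeric(intervals$end),
                          mode = as.character(intervals$mode))
  ann <- structure(list(session_id = session_id,
                        intervals = intervals,
                        duration = as.numeric(duration)),
                   class = "song_annotation")
  validate_song_annotation(ann)
  ann
}

validate_song_annotation <- function(ann) {
  iv <- ann$intervals
  if (!is.finite(ann$duration) || ann$duration <= 0)
    stop("duration must be a positive number")
  if (nrow(iv) == 0) return(invisible(ann))
  if (!all(iv$mode %in% SONG_MODES))
    stop("interval modes must be 'sine' or 'pulse'")
  if (is.unsorted(iv$start))
    stop("intervals must be sorted by start time")
  if (any(iv$end <= iv$start))
    stop("every interval must have end > start")
  if (any(iv$start < 0) || any(iv$end > ann$duration + 1e-9))
    stop("intervals must lie within [0, duration]")
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-12))
    stop("intervals must not overlap")
  invisible(ann)
}

#' @export
print.song_annotation <- function(x, ...) {
  cat(sprintf("<song_annotation '%s': %.1f s, %d intervals, density %.3f>\n",
              x$session_id, x$duration, nrow(x$intervals),
              sum(x$intervals$end - x$intervals$start) / x$duration))
  invisible(x)
}

#' Construct a song raster
#'
#' Binary, mutually exclusive sine/pulse indicator sequences on a uniform
#' time grid; bin `b` covers `[t0 + (b-1) dt, t0 + b dt)`.
#'
#' @param I_s,I_p integer 0/1 vectors of equal length with `I_s * I_p == 0`.
#' @param dt bin width in seconds.
#' @param t0 start time of the raster (seconds).
#' @return An object of class `song_raster`.
#' @export
song_raster <- function(I_s, I_p, dt, t0 = 0) {
  I_s <- as.integer(I_s); I_p <- as.integer(I_p)
  if (length(I_s) != length(I_p)) stop("I_s and I_p must have equal length")
  if (!all(I_s %in% 0:1) || !all(I_p %in% 0:1))
    stop("raster values must be 0 or 1")
  if (any(I_s * I_p != 0)) stop("sine and pulse are mutually exclusive")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  structure(list(dt = dt, I_s = I_s, I_p = I_p, t0 = t0),
            class = "song_raster")
}

#' @export
print.song_raster <- function(x, ...) {
  cat(sprintf("<song_raster: %d bins @ %.3g s (%.1f s), sine %.3f, pulse %.3f>\n",
              length(x$I_s), x$dt, length(x$I_s) * x$dt,
              mean(x$I_s), mean(x$I_p)))
  invisible(x)
}

#' Rasterize a song annotation
#'
#' Bins of width `dt`; a bin is labeled with mode m iff its midpoint lies
#' inside an interval of that mode. The number of bins is
#' `ceiling(duration / dt)`.
#'
#' @param annotation a [song_annotation].
#' @param dt bin width, seconds.
#' @return A [song_raster].
#' @export
rasterize <- function(annotation, dt) {
  validate_song_annotation(annotation)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  n <- ceiling(annotation$duration / dt)
  mids <- (seq_len(n) - 0.5) * dt
  I_s <- integer(n); I_p <- integer(n)
  iv <- annotation$intervals
  if (nrow(iv) > 0) {
    idx <- findInterval(mids, iv$start)
    hit <- idx >= 1 & mids < iv$end[pmax(idx, 1)]
    mode_hit <- iv$mode[pmax(idx, 1)]
    I_s[hit & mode_hit == "sine"] <- 1L
    I_p[hit & mode_hit == "pulse"] <- 1L
  }
  song_raster(I_s, I_p, dt, t0 = 0)
}

#' Convert a raster back to an annotation
#'
#' Maximal runs of each mode become intervals. Useful for computing song
#' features of scrambled (raster-level) songs.
#'
#' @param raster a [song_raster].
#' @param session_id identifier for the resulting annotation.
#' @return A [song_annotation] of duration `length * dt`.
#' @export
annotation_from_raster <- function(raster, session_id = "raster") {
  n <- length(raster$I_s)
  state <- ifelse(raster$I_s == 1, "sine", ifelse(raster$I_p == 1, "pulse", "quiet"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != "quiet"
  iv <- data.frame(start = starts[keep] * raster$dt,
                   end = ends[keep] * raster$dt,
                   mode = r$values[keep])
  song_annotation(iv, duration = n * raster$dt, session_id = session_id)
}

#' Parameters of the semi-Markov song generator
#'
#' The generator alternates dwell periods in the three states quiet, sine,
#' pulse; dwell durations are exponential (or gamma) with state-specific
#' means, and the next state is drawn from a row-stochastic transition
#' matrix with zero diagonal.
#'
#' @param mean_dwell named numeric, mean dwell per state (seconds) in the
#'   order quiet, sine, pulse.
#' @param transition_probs 3x3 row-stochastic matrix, zero diagonal, rows
#'   and columns ordered quiet, sine, pulse.
#' @param dwell_family `"exponential"` or `"gamma"`.
#' @param gamma_shape shape parameter when `dwell_family = "gamma"`.
#' @return An object of class `song_gen_params`.
#' @export
song_gen_params <- function(mean_dwell = c(quiet = 3, sine = 0.6, pulse = 0.4),
                            transition_probs = default_transition_probs(),
                            dwell_family = c("exponential", "gamma"),
                            gamma_shape = 1) {
  dwell_family <- match.arg(dwell_family)
  mean_dwell <- as.numeric(mean_dwell)
  if (length(mean_dwell) != 3 || any(!is.finite(mean_dwell)) || any(mean_dwell <= 0))
    stop("mean_dwell must be 3 positive numbers (quiet, sine, pulse)")
  tp <- as.matrix(transition_probs)
  if (!all(dim(tp) == c(3, 3)) || any(tp < 0) ||
      any(abs(rowSums(tp) - 1) > 1e-8) || any(abs(diag(tp)) > 1e-12))
    stop("transition_probs must be 3x3 row-stochastic with zero diagonal")
  if (dwell_family == "gamma" && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("gamma_shape must be positive")
  structure(list(mean_dwell = stats::setNames(mean_dwell, c("quiet", "sine", "pulse")),
                 transition_probs = tp, dwell_family = dwell_family,
                 gamma_shape = gamma_shape),
            class = "song_gen_params")
}

#' @rdname song_gen_params
#' @export
default_transition_probs <- function() {
  m <- rbind(c(0, 0.5, 0.5),
             c(0.4, 0, 0.6),
             c(0.6, 0.4, 0))
  dimnames(m) <- list(c("quiet", "sine", "pulse"), c("quiet", "sine", "pulse"))
  m
}

draw_dwell <- function(params, state) {
  m <- params$mean_dwell[[state]]
  if (params$dwell_family == "exponential") rexp(1, rate = 1 / m)
  else rgamma(1, shape = params$gamma_shape, scale = m / params$gamma_shape)
}

#' Generate a song annotation from the semi-Markov model
#'
#' @param params a [song_gen_params].
#' @param duration session duration, seconds.
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @param session_id identifier for the annotation.
#' @param init_state starting state (default `"quiet"`: sessions begin
#'   before singing).
#' @return A [song_annotation].
#' @export
generate_song <- function(params, duration, seed = 1, session_id = "synthetic",
                          init_state = "quiet") {
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  stopifnot(inherits(params, "song_gen_params"))
  states <- c("quiet", "sine", "pulse")
  if (!init_state %in% states) stop("invalid init_state")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  t <- 0
  state <- init_state
  cap <- max(64L, ceiling(3 * duration / min(params$mean_dwell)))
  starts <- numeric(cap); ends <- numeric(cap); modes <- character(cap)
  k <- 0L
  while (t < duration) {
    d <- max(draw_dwell(params, state), 1e-6)
    e <- min(t + d, duration)
    if (state != "quiet") {
      k <- k + 1L
      if (k > length(starts)) {  # grow by doubling
        starts <- c(starts, numeric(length(starts)))
        ends <- c(ends, numeric(length(ends)))
        modes <- c(modes, character(length(modes)))
      }
      starts[k] <- t; ends[k] <- e; modes[k] <- state
    }
    t <- t + d
    state <- sample(states, 1, prob = params$transition_probs[state, ])
  }
  idx <- seq_len(k)
  song_annotation(data.frame(start = starts[idx], end = ends[idx],
                             mode = modes[idx]),
                  duration = duration, session_id = session_id)
}

# save/restore the global RNG state so seeded helpers do not clobber the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Scramble a raster into an i.i.d. song
#'
#' Each output bin is drawn independently from the empirical marginal
#' distribution over quiet/sine/pulse of the input raster, destroying all
#' temporal correlations while preserving expected marginal frequencies.
#'
#' @param raster a [song_raster].
#' @param seed integer RNG seed.
#' @return A [song_raster] of the same length and dt.
#' @export
scramble_iid <- function(raster, seed = 1) {
  n <- length(raster$I_s)
  if (n == 0) stop("empty raster")
  p <- c(quiet = mean(raster$I_s == 0 & raster$I_p == 0),
         sine = mean(raster$I_s), pulse = mean(raster$I_p))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draw <- sample.int(3, n, replace = TRUE, prob = p)
  song_raster(as.integer(draw == 2), as.integer(draw == 3), raster$dt, raster$t0)
}

#' Song bouts
#'
#' A bout is a maximal union of song intervals in which consecutive
#' intervals are separated by quiet of at most `gap_tolerance` seconds
#' (default 0: any quiet ends a bout; contiguous sine and pulse belong to
#' the same bout).
#'
#' @param annotation a [song_annotation].
#' @param gap_tolerance maximum quiet gap (seconds) bridged within a bout.
#' @return data.frame with columns `start`, `end`, `duration`.
#' @export
song_bouts <- function(annotation, gap_tolerance = 0) {
  validate_song_annotation(annotation)
  iv <- annotation$intervals
  if (nrow(iv) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), duration = numeric(0)))
  bs <- iv$start[1]; be <- iv$end[1]
  starts <- numeric(0); ends <- numeric(0)
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] - be <= gap_tolerance + 1e-12) {
        be <- max(be, iv$end[i])
      } else {
        starts <- c(starts, bs); ends <- c(ends, be)
        bs <- iv$start[i]; be <- iv$end[i]
      }
    }
  }
  starts <- c(starts, bs); ends <- c(ends, be)
  data.frame(start = starts, end = ends, duration = ends - starts)
}

#' Trailing-window mean bout duration
#'
#' At each requested time t, the mean duration of bouts ending within
#' `(t - window, t]` (0 if none). This is the classic bout-duration
#' predictor of female slowing.
#'
#' @param annotation a [song_annotation].
#' @param times evaluation times (seconds); default a 1 s grid.
#' @param window trailing window, seconds (default 120).
#' @param gap_tolerance see [song_bouts].
#' @return list with `times`, `mean_bout_duration`, and the `bouts` table.
#' @export
bout_stats <- function(annotation, times = NULL, window = 120, gap_tolerance = 0) {
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  bouts <- song_bouts(annotation, gap_tolerance)
  if (is.null(times)) times <- seq(0, annotation$duration, by = 1)
  mbd <- vapply(times, function(t) {
    sel <- bouts$end > t - window & bouts$end <= t
    if (any(sel)) mean(bouts$duration[sel]) else 0
  }, numeric(1))
  list(times = times, mean_bout_duration = mbd, bouts = bouts)
}

#' Summary features of a song span
#'
#' @param annotation a [song_annotation].
#' @param span numeric length-2 `(start, end)` within the session; default
#'   the whole session.
#' @param gap_tolerance bout gap tolerance for the bout durations.
#' @return list of class `song_features`: `song_density` (fraction of the
#'   span singing), `transitions_per_min` (quiet-to-song onsets plus
#'   sine/pulse switches per minute), `sine_pulse_ratio` (Inf-flagged when
#'   no pulse), `mean_mode_duration` (seconds, over mode intervals
#'   intersecting the span), `bout_durations`.
#' @export
song_features <- function(annotation, span = NULL, gap_tolerance = 0) {
  validate_song_annotation(annotation)
  if (is.null(span)) span <- c(0, annotation$duration)
  if (length(span) != 2 || span[2] <= span[1])
    stop("span must be (start, end) with end > start")
  if (span[1] < -1e-9 || span[2] > annotation$duration + 1e-9)
    stop("span must lie within the session")
  L <- span[2] - span[1]
  iv <- annotation$intervals
  keep <- which(iv$end > span[1] & iv$start < span[2])
  civ <- iv[keep, , drop = FALSE]
  orig_dur <- civ$end - civ$start
  if (nrow(civ) > 0) {
    civ$start <- pmax(civ$start, span[1])
    civ$end <- pmin(civ$end, span[2])
  }
  sing <- sum(civ$end - civ$start)
  sine_t <- sum((civ$end - civ$start)[civ$mode == "sine"])
  pulse_t <- sum((civ$end - civ$start)[civ$mode == "pulse"])
  # transitions: onsets out of quiet plus contiguous sine<->pulse switches
  tol <- 1e-9
  n_trans <- 0L
  if (nrow(civ) > 0) {
    gaps <- if (nrow(civ) > 1) civ$start[-1] - civ$end[-nrow(civ)] else numeric(0)
    onsets <- 1L + sum(gaps > tol)
    switches <- sum(gaps <= tol &
                    civ$mode[-1] != civ$mode[-nrow(civ)])
    n_trans <- onsets + switches
  }
  bouts <- song_bouts(annotation, gap_tolerance)
  bkeep <- bouts$end > span[1] & bouts$start < span[2]
  ratio <- if (pulse_t > 0) sine_t / pulse_t else Inf
  structure(list(song_density = sing / L,
                 transitions_per_min = n_trans / (L / 60),
                 sine_pulse_ratio = ratio,
                 sine_pulse_ratio_flagged = !is.finite(ratio),
                 mean_mode_duration = if (nrow(civ) > 0) mean(orig_dur) else NA_real_,
                 bout_durations = bouts$duration[bkeep]),
            class = "song_features")
}
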