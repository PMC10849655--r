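# Fitting the MA and LN encoders to trial-averaged block-stimulus traces.
#
# The block protocol presents 10 s of pure sine or pure pulse song followed
# by a 10 s post-stimulus period, sampled at a calcium-imaging frame rate
# (~8 Hz). Because the stimulus is piecewise constant, both encoders have
# closed-form block responses, making the loss cheap to evaluate.

#' Block stimulus specification
#'
#' @param stim_duration seconds of pure-mode song (default 10).
#' @param post_duration seconds of post-stimulus quiet (default 10).
#' @param frame_rate sampling rate in Hz (default 8).
#' @return list of class `block_stimulus_spec`.
#' @export
block_stimulus_spec <- function(stim_duration = 10, post_duration = 10,
                                frame_rate = 8) {
  if (stim_duration <= 0 || post_duration <= 0 || frame_rate <= 0)
    stop("durations and frame_rate must be positive")
  structure(list(stim_duration = stim_duration, post_duration = post_duration,
                 frame_rate = frame_rate), class = "block_stimulus_spec")
}

#' Frame midpoint times of a block protocol
#' @param spec a [block_stimulus_spec].
#' @return Numeric vector of frame-midpoint times (seconds).
#' @export
block_frame_times <- function(spec) {
  n <- round((spec$stim_duration + spec$post_duration) * spec$frame_rate)
  (seq_len(n) - 0.5) / spec$frame_rate
}

#' Trial-averaged block responses for one recording
#'
#' @param sine,pulse data.frames with columns `t` (seconds) and `value`
#'   (trial-averaged response, e.g. dF/F).
#' @param recording_id identifier.
#' @return list of class `block_response_set`.
#' @export
block_response_set <- function(sine, pulse, recording_id = "rec") {
  for (tr in list(sine, pulse))
    if (!all(c("t", "value") %in% names(tr))) stop("traces need columns t, value")
  structure(list(sine = sine, pulse = pulse, recording_id = recording_id),
            class = "block_response_set")
}

#' Closed-form MA response to a pure-mode block
#'
#' During the stimulus the response follows [ma_step_response]; afterwards
#' the drive is zero and the activity decays as
#' `S(T) exp(-(t-T)/tau_int)`.
#'
#' @inheritParams ma_step_response
#' @param stim_duration block length T, seconds.
#' @return Numeric vector of activities at times `t` since block onset.
#' @export
ma_block_response <- function(params, mode, t, stim_duration = 10) {
  r <- numeric(length(t))
  during <- t <= stim_duration
  r[during] <- ma_step_response(params, mode, t[during])
  if (any(!during)) {
    rT <- ma_step_response(params, mode, stim_duration)
    r[!during] <- rT * exp(-(t[!during] - stim_duration) / params$tau_int)
  }
  r
}

#' Closed-form LN response to a pure-mode block
#'
#' Pre-rectification the matched LN response to a block is the step
#' response minus the delayed step response (superposition); the signed
#' rectification is then applied.
#'
#' @inheritParams ma_block_response
#' @return Numeric vector of activities.
#' @export
ln_block_response <- function(params, mode, t, stim_duration = 10) {
  z <- ma_step_response(params, mode, t)
  late <- t > stim_duration
  if (any(late))
    z[late] <- z[late] - ma_step_response(params, mode, t[late] - stim_duration)
  p <- params$polarity
  p * pmax(p * z, 0)
}

#' Coefficient of determination between model and data traces
#'
#' `1 - SSE / SStot` with `SStot` about the data mean; 0 by convention
#' when the data have zero variance.
#'
#' @param model_trace,data_trace numeric vectors or `response_trace`
#'   objects on the same grid.
#' @return Scalar R^2 (<= 1).
#' @export
goodness_r2 <- function(model_trace, data_trace) {
  m <- if (inherits(model_trace, "response_trace")) model_trace$r else model_trace
  d <- if (inherits(data_trace, "response_trace")) data_trace$r else data_trace
  if (length(m) != length(d)) stop("traces must have equal length")
  sstot <- sum((d - mean(d))^2)
  if (sstot == 0) return(0)
  1 - sum((d - m)^2) / sstot
}

# polarity from the sign of the largest-magnitude sample of either trace
infer_polarity <- function(y) {
  if (all(y == 0)) return(1)
  sgn <- sign(y[which.max(abs(y))])
  if (sgn == 0) 1 else sgn
}

TAU_LO <- 1e-3
TAU_HI <- 1e4

clamp_tau <- function(theta) pmin(pmax(exp(theta), TAU_LO), TAU_HI)

# profiled amplitudes: x_m enters the MA block response linearly, so the
# optimal x_m for fixed timescales is a clamped least-squares projection
profiled_ma_loss <- function(theta, ts, ys, tp, yp, stim_duration) {
  tau <- clamp_tau(theta)
  base <- ma_params(tau[1], tau[2], 1, 1, 1)
  bs <- ma_block_response(base, "sine", ts, stim_duration)
  bp <- ma_block_response(base, "pulse", tp, stim_duration)
  xs <- if (sum(bs^2) > 0) max(0, sum(bs * ys) / sum(bs^2)) else 0
  xp <- if (sum(bp^2) > 0) max(0, sum(bp * yp) / sum(bp^2)) else 0
  list(sse = sum((ys - xs * bs)^2) + sum((yp - xp * bp)^2), x_s = xs, x_p = xp)
}

fit_result <- function(params, r2, loss, converged, model) {
  structure(list(params = params, r2 = r2, loss = loss,
                 converged = converged, model = model),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<%s fit: R2 = %.4f, loss = %.4g, converged = %s>\n",
              toupper(x$model), x$r2, x$loss, x$converged))
  print(x$params)
  invisible(x)
}

#' Fit the MA model to block responses
#'
#' Minimizes the summed squared error between the closed-form MA block
#' response (sampled at the data times) and both mode traces jointly over
#' the four parameters. Timescales are optimized in log space with a
#' multi-start grid; the selectivities are profiled out analytically
#' (they enter the response linearly). Polarity is set from the sign of
#' the dominant response.
#'
#' @param data a [block_response_set].
#' @param spec a [block_stimulus_spec].
#' @param tau_grid multi-start grid of timescales, seconds.
#' @param control passed to [stats::optim] (Nelder-Mead).
#' @return A `fit_result` with an [ma_params], `r2`, final `loss`, and a
#'   convergence flag.
#' @export
fit_ma <- function(data, spec = block_stimulus_spec(),
                   tau_grid = c(0.3, 3, 30, 100), control = list()) {
  stopifnot(inherits(data, "block_response_set"))
  ts <- data$sine$t; tp <- data$pulse$t
  ysr <- data$sine$value; ypr <- data$pulse$value
  if (any(!is.finite(c(ysr, ypr)))) stop("NaN in response traces")
  pol <- infer_polarity(c(ysr, ypr))
  ys <- pol * ysr; yp <- pol * ypr
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 2000), control)
  starts <- rbind(as.matrix(expand.grid(log(tau_grid), log(tau_grid))),
                  cbind(log(tau_grid), log(TAU_HI)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ],
               function(th) profiled_ma_loss(th, ts, ys, tp, yp,
                                             spec$stim_duration)$sse,
               method = "Nelder-Mead", control = ctrl)
    if (is.null(best) || o$value < best$value) best <- o
  }
  tau <- clamp_tau(best$par)
  pl <- profiled_ma_loss(best$par, ts, ys, tp, yp, spec$stim_duration)
  tau_a <- if (tau[2] >= 0.9 * TAU_HI) Inf else tau[2]
  params <- ma_params(tau[1], tau_a, pl$x_s, pl$x_p, pol)
  pred <- c(ma_block_response(params, "sine", ts, spec$stim_duration),
            ma_block_response(params, "pulse", tp, spec$stim_duration))
  fit_result(params, goodness_r2(pred, c(ysr, ypr)), pl$sse,
             best$convergence == 0, "ma")
}

#' Fit the matched LN model to block responses
#'
#' The LN filters are parameterized by the same four parameters via the
#' step-response matching of [ln_from_ma]; the fit descends those four
#' parameters against the squared error of the (rectified) LN block
#' response, which differs from the MA response only in the post-stimulus
#' (offset) period. Initialized from the MA fit plus the timescale grid.
#'
#' @inheritParams fit_ma
#' @return A `fit_result` with an [ma_params] carrying the LN filter
#'   parameterization (`model = "ln"`).
#' @export
fit_ln <- function(data, spec = block_stimulus_spec(),
                   tau_grid = c(0.3, 3, 30, 100), control = list()) {
  stopifnot(inherits(data, "block_response_set"))
  ts <- data$sine$t; tp <- data$pulse$t
  ysr <- data$sine$value; ypr <- data$pulse$value
  if (any(!is.finite(c(ysr, ypr)))) stop("NaN in response traces")
  pol <- infer_polarity(c(ysr, ypr))
  ys <- pol * ysr; yp <- pol * ypr

  # positive-polarity pre-rectification block basis for unit amplitude
  basis <- function(tau, tt, mode) {
    ln_block_response(ma_params(tau[1], tau[2], 1, 1, 1), mode, tt,
                      spec$stim_duration)
  }
  loss4 <- function(th) {
    tau <- clamp_tau(th[1:2])
    xs <- max(th[3], 0); xp <- max(th[4], 0)
    zs <- pmax(xs * basis(tau, ts, "sine"), 0)
    zp <- pmax(xp * basis(tau, tp, "pulse"), 0)
    sum((ys - zs)^2) + sum((yp - zp)^2)
  }
  # starts: MA fit plus the timescale grid with amplitudes profiled on the
  # unrectified basis
  mafit <- fit_ma(data, spec, tau_grid, control)
  mp <- mafit$params
  starts <- list(c(log(mp$tau_int), log(min(mp$tau_a, TAU_HI)), mp$x_s, mp$x_p))
  grid <- rbind(as.matrix(expand.grid(log(tau_grid), log(tau_grid))),
                cbind(log(tau_grid), log(TAU_HI)))
  for (i in seq_len(nrow(grid))) {
    tau <- clamp_tau(grid[i, ])
    bs <- basis(tau, ts, "sine"); bp <- basis(tau, tp, "pulse")
    xs <- if (sum(bs^2) > 0) max(0, sum(bs * ys) / sum(bs^2)) else 0
    xp <- if (sum(bp^2) > 0) max(0, sum(bp * yp) / sum(bp^2)) else 0
    starts[[length(starts) + 1]] <- c(grid[i, ], xs, xp)
  }
  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 4000), control)
  best <- NULL
  for (s in starts) {
    o <- optim(s, loss4, method = "Nelder-Mead", control = ctrl)
    if (is.null(best) || o$value < best$value) best <- o
  }
  tau <- clamp_tau(best$par[1:2])
  tau_a <- if (tau[2] >= 0.9 * TAU_HI) Inf else tau[2]
  params <- ma_params(tau[1], tau_a, max(best$par[3], 0), max(best$par[4], 0), pol)
  pred <- c(ln_block_response(params, "sine", ts, spec$stim_duration),
            ln_block_response(params, "pulse", tp, spec$stim_duration))
  fit_result(params, goodness_r2(pred, c(ysr, ypr)), best$value,
             best$convergence == 0, "ln")
}

#' Read / write block-response CSVs
#'
#' Long format with columns `recording_id,mode,t_s,dff`.
#'
#' @param path CSV file path.
#' @return `read_block_responses_csv`: a list of [block_response_set].
#' @export
read_block_responses_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$recording_id), function(d) {
    block_response_set(
      sine = data.frame(t = d$t_s[d$mode == "sine"], value = d$dff[d$mode == "sine"]),
      pulse = data.frame(t = d$t_s[d$mode == "pulse"], value = d$dff[d$mode == "pulse"]),
      recording_id = d$recording_id[1])
  })
}

#' @rdname read_block_responses_csv
#' @param sets list of [block_response_set].
#' @export
write_block_responses_csv <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    rbind(data.frame(recording_id = s$recording_id, mode = "sine",
                     t_s = s$sine$t, dff = s$sine$value),
          data.frame(recording_id = s$recording_id, mode = "pulse",
                     t_s = s$pulse$t, dff = s$pulse$value))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
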