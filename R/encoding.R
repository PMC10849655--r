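# Encoding models: the multiplicative-adaptation (MA) dynamical encoder,
# its closed-form step response, and the linear-nonlinear (LN) encoder
# analytically matched to the same four parameters.

#' MA model parameters
#'
#' The multiplicative-adaptation encoder is a 4-parameter dynamical system:
#' \deqn{\tau_{int}\,dr/dt = -r + x_s(1-a_s)I_s + x_p(1-a_p)I_p}
#' \deqn{\tau_a\,da_m/dt = -a_m + I_m, \quad m \in \{s, p\}}
#' Song drives activity through gain factors \eqn{1-a_m} set by
#' mode-specific adaptation variables, followed by leaky integration with
#' timescale `tau_int`. `tau_a = Inf` disables adaptation (LTI limit).
#' `polarity` is a pure sign factor applied to the output (negative-going
#' calcium responses).
#'
#' @param tau_int integration timescale, seconds (> 0).
#' @param tau_a adaptation timescale, seconds (> 0; `Inf` allowed).
#' @param x_s,x_p sine/pulse selectivities (>= 0, dimensionless).
#' @param polarity +1 or -1.
#' @return An object of class `ma_params`.
#' @export
ma_params <- function(tau_int, tau_a, x_s, x_p, polarity = 1) {
  if (!is.finite(tau_int) || tau_int <= 0) stop("tau_int must be positive")
  if (is.na(tau_a) || tau_a <= 0) stop("tau_a must be positive or Inf")
  if (!is.finite(x_s) || x_s < 0 || !is.finite(x_p) || x_p < 0)
    stop("x_s and x_p must be non-negative")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(tau_int = tau_int, tau_a = tau_a,
                 x_s = x_s, x_p = x_p, polarity = polarity),
            class = "ma_params")
}

#' @export
print.ma_params <- function(x, ...) {
  cat(sprintf("<ma_params: tau_int=%.3g s, tau_a=%.3g s, x_s=%.3g, x_p=%.3g, polarity=%+d>\n",
              x$tau_int, x$tau_a, x$x_s, x$x_p, x$polarity))
  invisible(x)
}

#' A population of MA neurons
#'
#' Stored as a data.frame with columns `neuron_id`, `tau_int`, `tau_a`,
#' `x_s`, `x_p`, `polarity` (one row per neuron; `tau_a` may be `Inf`).
#'
#' @param df data.frame with at least `tau_int`, `tau_a`, `x_s`, `x_p`.
#' @return An object of class `population_params` (a data.frame).
#' @export
population_params <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0) stop("population must be nonempty")
  if (is.null(df$neuron_id)) df$neuron_id <- sprintf("n%03d", seq_len(nrow(df)))
  if (is.null(df$polarity)) df$polarity <- 1
  req <- c("tau_int", "tau_a", "x_s", "x_p")
  if (!all(req %in% names(df))) stop("missing population columns")
  for (i in seq_len(nrow(df)))
    ma_params(df$tau_int[i], df$tau_a[i], df$x_s[i], df$x_p[i], df$polarity[i])
  df <- df[, c("neuron_id", req, "polarity")]
  class(df) <- c("population_params", "data.frame")
  df
}

pop_row_params <- function(pop, i) {
  ma_params(pop$tau_int[i], pop$tau_a[i], pop$x_s[i], pop$x_p[i], pop$polarity[i])
}

#' Simulate the MA model on a song raster
#'
#' Uses exact exponential updates on each constant-input bin (the
#' adaptation variables relax exponentially toward the inputs; the
#' activity update against the resulting constant-plus-exponential drive
#' has a closed form), so the result is exact at any raster resolution.
#'
#' @param params an [ma_params].
#' @param raster a [song_raster].
#' @param init named numeric initial state `c(r=, a_s=, a_p=)`
#'   (default all zero: sessions begin before singing).
#' @return A `response_trace`: list with `t` (bin-end times) and `r`.
#' @export
ma_simulate <- function(params, raster, init = c(r = 0, a_s = 0, a_p = 0)) {
  stopifnot(inherits(params, "ma_params"), inherits(raster, "song_raster"))
  if (length(raster$I_s) == 0) stop("zero-length raster")
  m <- ma_core(params$tau_int, params$tau_a, params$x_s, params$x_p,
               params$polarity, raster$I_s, raster$I_p, raster$dt,
               init[["r"]], init[["a_s"]], init[["a_p"]])
  response_trace(t = raster$t0 + seq_along(raster$I_s) * raster$dt,
                 r = m[, 1], neuron_id = "ma")
}

#' @rdname ma_simulate
#' @param pop a [population_params].
#' @param model `"ma"` or `"ln"` (matched LN built via [ln_from_ma]).
#' @param ln_grid_len filter support in seconds for the LN path; default
#'   covers ten times the slowest finite timescale, capped at the raster
#'   duration.
#' @return For `simulate_population`: a time-by-neuron activity matrix with
#'   attribute `t` (bin-end times).
#' @export
simulate_population <- function(pop, raster, model = c("ma", "ln"),
                                ln_grid_len = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(pop, "population_params"), inherits(raster, "song_raster"))
  n <- length(raster$I_s)
  if (n == 0) stop("zero-length raster")
  tvec <- raster$t0 + seq_len(n) * raster$dt
  if (model == "ma") {
    z <- rep(0, nrow(pop))
    m <- ma_core(pop$tau_int, pop$tau_a, pop$x_s, pop$x_p, pop$polarity,
                 raster$I_s, raster$I_p, raster$dt, z, z, z)
  } else {
    dur <- n * raster$dt
    m <- matrix(0, n, nrow(pop))
    for (i in seq_len(nrow(pop))) {
      pr <- pop_row_params(pop, i)
      need <- 10 * max(pr$tau_int, if (is.finite(pr$tau_a)) pr$tau_a else 0)
      gl <- if (is.null(ln_grid_len)) min(need, dur) else ln_grid_len
      ln <- ln_from_ma(pr, grid_dt = raster$dt, grid_len = gl,
                       warn = !is.null(ln_grid_len))
      m[, i] <- ln_simulate(ln, raster)$r
    }
  }
  colnames(m) <- pop$neuron_id
  attr(m, "t") <- tvec
  m
}

response_trace <- function(t, r, neuron_id = "") {
  structure(list(t = t, r = r, neuron_id = neuron_id), class = "response_trace")
}

#' Closed-form step response of the MA model
#'
#' Response from zero initial state to a sustained pure-mode input switched
#' on at t = 0:
#' \deqn{r(t) = x_m \frac{\tau_a}{\tau_a-\tau_{int}}
#'   (e^{-t/\tau_a} - e^{-t/\tau_{int}})}
#' with the degenerate limit \eqn{x_m (t/\tau) e^{-t/\tau}} when
#' \eqn{\tau_a = \tau_{int}} and the LTI form
#' \eqn{x_m(1 - e^{-t/\tau_{int}})} when `tau_a = Inf`. The output is
#' multiplied by `polarity`, matching [ma_simulate] on a constant raster.
#'
#' @param params an [ma_params].
#' @param mode `"sine"` or `"pulse"`.
#' @param t times since step onset (seconds, >= 0); vectorized.
#' @return Numeric vector of activities.
#' @export
ma_step_response <- function(params, mode = c("sine", "pulse"), t) {
  mode <- match.arg(mode)
  if (any(t < 0)) stop("t must be non-negative")
  x <- if (mode == "sine") params$x_s else params$x_p
  ti <- params$tau_int; ta <- params$tau_a
  r <- if (!is.finite(ta)) {
    x * (1 - exp(-t / ti))
  } else if (abs(ta - ti) < 1e-12 * ti) {
    x * (t / ti) * exp(-t / ti)
  } else {
    x * ta / (ta - ti) * (exp(-t / ta) - exp(-t / ti))
  }
  params$polarity * r
}

#' Linear-nonlinear model matched to MA parameters
#'
#' Constructs filters whose discrete step response on the grid equals
#' [ma_step_response] exactly: `h_m[k] = (S(k dt) - S((k-1) dt)) / dt`.
#' The LN and MA models then produce identical responses to any
#' single-mode block stimulus (pre-rectification) up to grid error.
#'
#' @param params an [ma_params].
#' @param grid_dt filter grid resolution, seconds.
#' @param grid_len filter support, seconds. A warning is issued (when
#'   `warn`) if shorter than ten times the slowest finite timescale.
#' @param warn warn on short filter support.
#' @return An object of class `ln_model` with fields `h_s`, `h_p`, `dt`,
#'   `polarity`, `source_params`.
#' @export
ln_from_ma <- function(params, grid_dt = 0.01, grid_len = NULL, warn = TRUE) {
  stopifnot(inherits(params, "ma_params"))
  slowest <- max(params$tau_int, if (is.finite(params$tau_a)) params$tau_a else 0)
  if (is.null(grid_len)) grid_len <- 10 * slowest
  if (!is.finite(grid_dt) || grid_dt <= 0 || grid_len <= 0)
    stop("grid parameters must be positive")
  if (warn && grid_len < 10 * slowest)
    warning("filter support shorter than 10x the slowest timescale")
  K <- max(1L, ceiling(grid_len / grid_dt))
  tk <- seq_len(K) * grid_dt
  step_s <- ma_step_response(params, "sine", tk)
  step_p <- ma_step_response(params, "pulse", tk)
  structure(list(h_s = diff(c(0, step_s)) / grid_dt,
                 h_p = diff(c(0, step_p)) / grid_dt,
                 dt = grid_dt, polarity = params$polarity,
                 source_params = params),
            class = "ln_model")
}

# causal discrete convolution: y[b] = sum_k h[k] x[b-k+1] * dt
causal_conv <- function(x, h, dt) {
  n <- length(x)
  if (length(h) == 0) return(rep(0, n))
  y <- convolve(c(x, rep(0, length(h))), rev(h), type = "open")
  y[seq_len(n)] * dt
}

#' Simulate the LN model on a song raster
#'
#' Causal convolution of the binary inputs with the sine/pulse filters,
#' summed, then the signed rectification
#' `g(z) = polarity * max(polarity * z, 0)`.
#'
#' @param model an `ln_model` (see [ln_from_ma]).
#' @param raster a [song_raster]; its `dt` must equal the filter grid.
#' @return A `response_trace` on the raster's bin-end times.
#' @export
ln_simulate <- function(model, raster) {
  stopifnot(inherits(model, "ln_model"), inherits(raster, "song_raster"))
  if (abs(model$dt - raster$dt) > 1e-9 * model$dt)
    stop("raster dt must match the filter grid dt")
  z <- causal_conv(raster$I_s, model$h_s, model$dt) +
       causal_conv(raster$I_p, model$h_p, model$dt)
  p <- model$polarity
  response_trace(t = raster$t0 + seq_along(z) * raster$dt,
                 r = p * pmax(p * z, 0), neuron_id = "ln")
}

#' Timescale regime bounds
#'
#' `"fast"` is 0.1-2 s, `"medium"` 2-20 s, `"slow"` 20-120 s.
#'
#' @param name regime name.
#' @return list with `name`, `low`, `high` (seconds).
#' @export
regime_spec <- function(name = c("fast", "medium", "slow")) {
  name <- match.arg(name)
  b <- switch(name, fast = c(0.1, 2), medium = c(2, 20), slow = c(20, 120))
  list(name = name, low = b[1], high = b[2])
}

#' Sample a random MA population
#'
#' Timescales and selectivities are drawn uniformly on the given ranges;
#' a scalar range fixes the value for all neurons, and `tau_a_range = Inf`
#' disables adaptation.
#'
#' @param n number of neurons.
#' @param tau_int_range length-2 range, or a scalar for a fixed value.
#' @param tau_a_range as above; may be `Inf`.
#' @param selectivity_mode `"uniform01"` (x_s, x_p ~ U(0,1)) or `"pure"`
#'   (each neuron responds to exactly one mode with x = 1).
#' @param seed integer RNG seed.
#' @return A [population_params].
#' @export
sample_population <- function(n, tau_int_range = c(20, 120),
                              tau_a_range = c(0.1, 2),
                              selectivity_mode = c("uniform01", "pure"),
                              seed = 1) {
  selectivity_mode <- match.arg(selectivity_mode)
  if (n < 1) stop("n must be >= 1")
  draw_range <- function(rng, n) {
    if (length(rng) == 1) rep(rng, n)
    else if (length(rng) == 2 && rng[2] > rng[1]) runif(n, rng[1], rng[2])
    else stop("range must be a scalar or (low, high) with high > low")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  tau_int <- draw_range(tau_int_range, n)
  tau_a <- draw_range(tau_a_range, n)
  if (selectivity_mode == "uniform01") {
    x_s <- runif(n); x_p <- runif(n)
  } else {
    pure_sine <- runif(n) < 0.5
    x_s <- as.numeric(pure_sine); x_p <- as.numeric(!pure_sine)
  }
  population_params(data.frame(tau_int = tau_int, tau_a = tau_a,
                               x_s = x_s, x_p = x_p, polarity = 1))
}

#' Perturb a population
#'
#' `"no_adaptation"` sets `tau_a = Inf`; `"no_sine"` sets `x_s = 0`;
#' `"no_pulse"` sets `x_p = 0`; `"resample_regime"` redraws a timescale
#' uniformly inside a named regime (`spec`), or removes adaptation when
#' `spec = "none"` and `field = "tau_a"`.
#'
#' @param pop a [population_params].
#' @param perturbation one of `"no_adaptation"`, `"no_sine"`,
#'   `"no_pulse"`, `"resample_regime"`.
#' @param field for `resample_regime`: `"tau_int"` or `"tau_a"`.
#' @param spec for `resample_regime`: a [regime_spec], a regime name, or
#'   `"none"` (tau_a only).
#' @param seed RNG seed for resampling.
#' @return A perturbed [population_params].
#' @export
perturb_population <- function(pop, perturbation = c("no_adaptation", "no_sine",
                                                     "no_pulse", "resample_regime"),
                               field = c("tau_a", "tau_int"), spec = NULL,
                               seed = 1) {
  perturbation <- match.arg(perturbation)
  stopifnot(inherits(pop, "population_params"))
  out <- pop
  if (perturbation == "no_adaptation") {
    out$tau_a <- Inf
  } else if (perturbation == "no_sine") {
    out$x_s <- 0
  } else if (perturbation == "no_pulse") {
    out$x_p <- 0
  } else {
    field <- match.arg(field)
    if (is.character(spec) && identical(spec, "none")) {
      if (field != "tau_a") stop("regime 'none' applies to tau_a only")
      out$tau_a <- Inf
    } else {
      if (is.character(spec)) spec <- regime_spec(spec)
      if (is.null(spec)) stop("resample_regime requires a regime spec")
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(as.integer(seed))
      out[[field]] <- runif(nrow(out), spec$low, spec$high)
    }
  }
  population_params(out)
}

#' Read / write population parameter CSVs
#'
#' Columns `neuron_id,tau_int_s,tau_a_s,x_s,x_p,polarity`; `tau_a_s` may be
#' `inf`.
#'
#' @param path CSV file path.
#' @return `read_population_csv`: a [population_params].
#' @export
read_population_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ta <- df$tau_a_s
  if (is.character(ta)) ta <- ifelse(tolower(trimws(ta)) == "inf", Inf, as.numeric(ta))
  population_params(data.frame(neuron_id = df$neuron_id, tau_int = df$tau_int_s,
                               tau_a = ta, x_s = df$x_s, x_p = df$x_p,
                               polarity = df$polarity))
}

#' @rdname read_population_csv
#' @param pop a [population_params].
#' @export
write_population_csv <- function(pop, path) {
  out <- data.frame(neuron_id = pop$neuron_id, tau_int_s = pop$tau_int,
                    tau_a_s = ifelse(is.finite(pop$tau_a),
                                     as.character(pop$tau_a), "inf"),
                    x_s = pop$x_s, x_p = pop$x_p, polarity = pop$polarity)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
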