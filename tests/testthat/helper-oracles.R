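# Independent oracles and fixture builders used across the test suite.

# Explicit-Euler integration of the MA system at a fine step: the
# independent oracle for the exact piecewise-exponential integrator.
euler_ma <- function(params, raster, dt_fine = 1e-4) {
  n <- length(raster$I_s)
  steps <- round(n * raster$dt / dt_fine)
  r <- 0; a_s <- 0; a_p <- 0
  out <- numeric(n); j <- 1
  for (k in seq_len(steps)) {
    b <- min(floor((k - 1) * dt_fine / raster$dt) + 1, n)
    Is <- raster$I_s[b]; Ip <- raster$I_p[b]
    drive <- params$x_s * (1 - a_s) * Is + params$x_p * (1 - a_p) * Ip
    r <- r + dt_fine * (-r + drive) / params$tau_int
    if (is.finite(params$tau_a)) {
      a_s <- a_s + dt_fine * (-a_s + Is) / params$tau_a
      a_p <- a_p + dt_fine * (-a_p + Ip) / params$tau_a
    }
    while (j <= n && k * dt_fine >= j * raster$dt - 1e-12) {
      out[j] <- params$polarity * r
      j <- j + 1
    }
  }
  out
}

# short random song raster with both modes present
random_raster <- function(seed, duration = 2, dt = 0.01) {
  sp <- song_gen_params(mean_dwell = c(quiet = 0.3, sine = 0.2, pulse = 0.15))
  rasterize(generate_song(sp, duration, seed = seed), dt)
}

random_ma_params <- function(seed, tau_int_range = c(0.1, 5),
                             tau_a_range = c(0.1, 5)) {
  set.seed(seed)
  ma_params(runif(1, tau_int_range[1], tau_int_range[2]),
            runif(1, tau_a_range[1], tau_a_range[2]),
            runif(1, 0.1, 1), runif(1, 0.1, 1))
}

# small synthetic study shared by pipeline tests (built once per run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_synthetic_study(n_sessions = 6, session_duration = 120,
                                     pop = sample_population(8, c(20, 120),
                                                             c(0.1, 2),
                                                             seed = 41),
                                     noise_sd = 0, seed = 7)
    cache
  }
})
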