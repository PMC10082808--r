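# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Straight constant-velocity walk of one pedestrian.
straight_traj <- function(id, n = 100, dt = 0.05, x0 = 0, y0 = 0,
                          vx = 1.2, vy = 0, t0 = 0) {
  t <- t0 + dt * (0:(n - 1L))
  tibble::tibble(time = t, id = id, x = x0 + vx * (t - t0),
                 y = y0 + vy * (t - t0))
}

# Two members walking abreast at constant separation d along +x.
abreast_dyad <- function(d = 0.8, n = 100, dt = 0.05, speed = 1.2) {
  dplyr::bind_rows(
    straight_traj("m1", n, dt, x0 = 0, y0 = d / 2, vx = speed),
    straight_traj("m2", n, dt, x0 = 0, y0 = -d / 2, vx = speed)
  )
}

# A group-frame series built directly (columns as to_group_frame returns).
frame_series <- function(time, x, y, vx = NULL, vy = NULL) {
  if (is.null(vx)) vx <- finite_diff_test(time, x)
  if (is.null(vy)) vy <- finite_diff_test(time, y)
  tibble::tibble(time = time, x = x, y = y, vx = vx, vy = vy,
                 group_speed = 1)
}

finite_diff_test <- function(t, x) {
  n <- length(t)
  v <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    v[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  v
}

# Dense-resampling brute-force oracle for the interpolated minimum distance:
# on every inter-sample interval, evaluate r(t_k) + s v(t_k) on a fine grid,
# then refine around the grid argmin so the oracle error is << 1e-9
# (independent of the closed-form projection used by min_distance).
brute_min_distance <- function(frame, n_dense = 4000L) {
  n <- nrow(frame)
  best_r <- sqrt(frame$x[n]^2 + frame$y[n]^2)
  for (k in seq_len(n - 1L)) {
    dt <- frame$time[k + 1L] - frame$time[k]
    s <- seq(0, dt, length.out = n_dense)
    r <- sqrt((frame$x[k] + s * frame$vx[k])^2 +
                (frame$y[k] + s * frame$vy[k])^2)
    j <- which.min(r)
    lo <- s[max(1L, j - 1L)]
    hi <- s[min(n_dense, j + 1L)]
    s2 <- seq(lo, hi, length.out = n_dense)
    r2 <- sqrt((frame$x[k] + s2 * frame$vx[k])^2 +
                 (frame$y[k] + s2 * frame$vy[k])^2)
    best_r <- min(best_r, min(r2))
  }
  best_r
}

# Random piecewise-linear group-frame series (velocities independent of the
# chord, as the interpolation rule allows).
random_frame <- function(n_samples = 8L) {
  t <- cumsum(c(0, stats::runif(n_samples - 1L, 0.02, 0.2)))
  tibble::tibble(
    time = t,
    x = stats::rnorm(n_samples, 0, 2),
    y = stats::rnorm(n_samples, 0, 2),
    vx = stats::rnorm(n_samples, 0, 2),
    vy = stats::rnorm(n_samples, 0, 2),
    group_speed = 1
  )
}

# Small simulated dataset shared by several test files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_scenario(n_encounters = 40)
      cache <<- c(simulate_dataset(sc, default_class_specs("strength"),
                                   seed = 7),
                  list(scenario = sc))
    }
    cache
  }
})
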