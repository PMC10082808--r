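# Internal numerical helpers shared across modules.

# Condition constructors: all package errors carry a subclass so callers and
# tests can distinguish format, validation, configuration and empty-analysis
# failures.
ped_stop <- function(message, class) {
  rlang::abort(message, class = c(paste0("pedscatter_", class), "pedscatter_error"))
}

# Central finite differences on an irregular grid; one-sided at the ends.
# x is a numeric vector sampled at strictly increasing times t.
finite_diff <- function(t, x) {
  n <- length(t)
  if (n < 2L) {
    return(rep(NA_real_, n))
  }
  v <- numeric(n)
  if (n == 2L) {
    v[] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
    return(v)
  }
  idx <- 2L:(n - 1L)
  v[idx] <- (x[idx + 1L] - x[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  v[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  v[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  v
}

# Linear interpolation of a column onto new times; NA outside the support.
resample_linear <- function(t, x, t_out) {
  stats::approx(t, x, xout = t_out, method = "linear", rule = 1)$y
}

# Rotate 2D points by angle theta (counter-clockwise). x, y vectors.
rotate_xy <- function(x, y, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  list(x = ct * x - st * y, y = st * x + ct * y)
}

# Maximal runs of TRUE in a logical vector -> list of index ranges.
true_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(function(s, e) c(s, e), starts[keep], ends[keep])
}

# 2D scalar cross product.
cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

`%||%` <- function(a, b) if (is.null(a)) b else a

new_log <- function() {
  tibble::tibble(
    stage = character(), n_before = integer(), n_after = integer(),
    note = character()
  )
}

log_stage <- function(log, stage, n_before, n_after, note = "") {
  dplyr::bind_rows(log, tibble::tibble(
    stage = stage, n_before = as.integer(n_before),
    n_after = as.integer(n_after), note = note
  ))
}
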