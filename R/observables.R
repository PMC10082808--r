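#' Window entry time
#'
#' First sample of the group-frame series with `|x| <= W` and `|y| <= W`. If
#' the series already starts inside the window, the first time is returned
#' with a flag.
#'
#' @param frame A [to_group_frame()] series.
#' @param W Window half-width (same units as the frame coordinates).
#' @return List `t_prime`, `index`, `began_inside`, or `NULL` if the
#'   individual never enters the window (no-encounter signal).
#' @export
entry_time <- function(frame, W = 4) {
  inside <- abs(frame$x) <= W & abs(frame$y) <= W
  if (!any(inside)) {
    return(NULL)
  }
  k <- which(inside)[1L]
  list(t_prime = frame$time[k], index = k, began_inside = k == 1L)
}

#' Straight-line (impact-parameter) distance
#'
#' The minimum distance from the group (origin) that the individual would
#' attain if it kept moving in a straight line from its window-entry
#' position: `r_b = |r(t') x v| / |v|` with `v` the mean of the `n_avg`
#' relative-velocity samples ending at the entry instant (fewer are used if
#' the series is shorter; the count actually used is reported).
#'
#' @param frame A [to_group_frame()] series.
#' @param entry An [entry_time()] result.
#' @param n_avg Number of velocity samples averaged (entry sample inclusive).
#' @param include_entry If `FALSE`, average the `n_avg` samples strictly
#'   before the entry instant instead.
#' @return List `r_b`, `n_avg_used`, `v_entry` (mean relative speed), or
#'   `NULL` when the averaged velocity vanishes (degenerate-velocity signal).
#' @export
straight_line_distance <- function(frame, entry, n_avg = 4L,
                                   include_entry = TRUE) {
  k <- entry$index
  hi <- if (include_entry) k else k - 1L
  lo <- max(1L, hi - n_avg + 1L)
  if (hi < 1L) {
    return(NULL)
  }
  vbx <- mean(frame$vx[lo:hi])
  vby <- mean(frame$vy[lo:hi])
  nv <- sqrt(vbx^2 + vby^2)
  if (nv == 0 || !is.finite(nv)) {
    return(NULL)
  }
  rb <- abs(cross2(frame$x[k], frame$y[k], vbx, vby)) / nv
  list(r_b = rb, n_avg_used = hi - lo + 1L, v_entry = nv)
}

#' Interpolated minimum distance and closest-approach time
#'
#' Minimizes `|r(t)|` over the encounter, interpolating between consecutive
#' samples with `r(t) = r(t_k) + (t - t_k) v(t_k)` so that minima between
#' sampling instants are found in closed form (the projection of the origin
#' onto each linear piece, clamped to the inter-sample interval). Ties
#' resolve to the earliest time.
#'
#' @param frame A [to_group_frame()] series.
#' @param W Window half-width; only in-window samples at or after the entry
#'   are considered (brief out-of-window jitter between them is bridged by
#'   the linear interpolation). `NULL` uses the whole series.
#' @param entry Optional [entry_time()] result (recomputed if missing).
#' @return List `r_0`, `t_c`, `at_exit_boundary` (minimum attained at the
#'   last in-window sample, possible censoring), or `NULL` with no usable
#'   samples.
#' @export
min_distance <- function(frame, W = NULL, entry = NULL) {
  if (is.null(W)) {
    idx <- seq_len(nrow(frame))
  } else {
    if (is.null(entry)) entry <- entry_time(frame, W)
    if (is.null(entry)) {
      return(NULL)
    }
    inside <- abs(frame$x) <= W & abs(frame$y) <= W
    idx <- which(inside & seq_len(nrow(frame)) >= entry$index)
  }
  if (length(idx) < 1L) {
    return(NULL)
  }
  tt <- frame$time[idx]
  x <- frame$x[idx]
  y <- frame$y[idx]
  vx <- frame$vx[idx]
  vy <- frame$vy[idx]
  n <- length(idx)

  best_r <- sqrt(x[n]^2 + y[n]^2)
  best_t <- tt[n]
  if (n >= 2L) {
    k <- seq_len(n - 1L)
    dt <- tt[k + 1L] - tt[k]
    v2 <- vx[k]^2 + vy[k]^2
    s <- ifelse(v2 > 0, -(x[k] * vx[k] + y[k] * vy[k]) / v2, 0)
    s <- pmin(pmax(s, 0), dt)
    px <- x[k] + s * vx[k]
    py <- y[k] + s * vy[k]
    r <- sqrt(px^2 + py^2)
    tc <- tt[k] + s
    # which.min returns the first (earliest) minimizer, so ties resolve to
    # the earliest t_c; the final sample is the last candidate.
    j <- which.min(c(r, best_r))
    if (j <= length(r)) {
      best_r <- r[j]
      best_t <- tc[j]
    }
  }
  list(r_0 = best_r, t_c = best_t,
       at_exit_boundary = n >= 2L && best_t == tt[n])
}

#' Collision-avoidance potential evaluator
#'
#' The dimensionless probed potential `U' = (r0^2 - rb^2) / r0^2`, derived
#' from energy conservation in a two-body scattering picture with the
#' asymptotic kinetic energy taken as the unit. `U' = 0` when the motion is
#' straight (`r0 = rb`), approaches 1 in the head-on limit (`rb = 0`), and
#' can only probe values below 1; it is negative when the pair ends up
#' closer than the straight-line prediction (environment bias).
#'
#' @param r0 Observed minimum distance(s), > 0.
#' @param rb Straight-line distance(s), >= 0.
#' @return Numeric vector of probed potential values; `NA` where `r0 <= 0`.
#' @export
avoidance_potential <- function(r0, rb) {
  ifelse(r0 > 0, (r0^2 - rb^2) / r0^2, NA_real_)
}

#' Scale observables by the class interpersonal distance
#'
#' @param observables Tibble with metric columns `r_b`, `r_0`.
#' @param d_class Class-average interpersonal distance, meters (> 0).
#' @return Input with `rbar_b` and `rbar_0` columns added.
#' @export
scale_observables <- function(observables, d_class) {
  if (!is.numeric(d_class) || d_class <= 0) {
    ped_stop("d_class must be a positive number", "config_error")
  }
  dplyr::mutate(observables,
    rbar_b = .data$r_b / d_class,
    rbar_0 = .data$r_0 / d_class
  )
}

#' Scaled mean member-to-center distance of a dyad
#'
#' Time average of each member's distance to the geometric center (half the
#' separation), in interpersonal-distance units. For a dyad whose separation
#' equals the class interpersonal distance this is exactly 0.5 — the scale at
#' which an individual's minimum distance signals passing between the
#' members.
#'
#' @param group_track A [build_group_track()] result.
#' @param d_class Class interpersonal distance, meters.
#' @return Scalar scaled distance.
#' @export
member_center_distance <- function(group_track, d_class) {
  if (d_class <= 0) ped_stop("d_class must be > 0", "config_error")
  mean(group_track$separation / 2) / d_class
}

# Full per-encounter observable extraction; NULL when the encounter fails a
# precondition (never inside window / degenerate velocity).
encounter_observables <- function(frame, W, n_avg = 4L,
                                  encounter_id = NA_character_,
                                  class_label = NA_character_) {
  entry <- entry_time(frame, W)
  if (is.null(entry)) {
    return(NULL)
  }
  sl <- straight_line_distance(frame, entry, n_avg = n_avg)
  if (is.null(sl)) {
    return(NULL)
  }
  md <- min_distance(frame, W = W, entry = entry)
  if (is.null(md)) {
    return(NULL)
  }
  tibble::tibble(
    encounter_id = encounter_id,
    class = class_label,
    t_prime = entry$t_prime,
    r_b = sl$r_b,
    r_0 = md$r_0,
    t_c = md$t_c,
    v_entry = sl$v_entry,
    n_avg_used = sl$n_avg_used,
    began_inside = entry$began_inside,
    at_exit_boundary = md$at_exit_boundary
  )
}
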