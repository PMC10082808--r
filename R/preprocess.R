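# Velocity columns: reuse if present (so filtering is idempotent), else
# central finite differences on the sample grid.
ensure_velocity <- function(df) {
  if (all(c("vx", "vy") %in% names(df))) {
    return(df)
  }
  df$vx <- finite_diff(df$time, df$x)
  df$vy <- finite_diff(df$time, df$y)
  df
}

#' Remove atypical motion from trajectories
#'
#' Splits each pedestrian's trace into maximal contiguous segments whose
#' instantaneous speed (central finite differences) stays inside
#' `speed_bounds`, dropping waiting/running episodes and segments shorter
#' than `min_duration`. Excursions outside the bounds lasting less than
#' `max_gap` are tolerated: braking or swerving during an avoidance
#' maneuver is characterizing motion, unlike sustained waiting or running.
#' Velocity columns computed here are carried along, so re-filtering a
#' filtered table is a no-op.
#'
#' @param trajectories Trajectory tibble (`time`, `id`, `x`, `y`).
#' @param speed_bounds Admissible speed interval (m/s), length 2.
#' @param min_duration Minimum retained segment duration, seconds.
#' @param max_gap Longest tolerated out-of-bounds excursion, seconds.
#' @return Tibble with added `vx`, `vy`, `segment_id` columns; zero rows if
#'   nothing survives.
#' @export
filter_atypical <- function(trajectories, speed_bounds = c(0.5, 3.0),
                            min_duration = 1.0, max_gap = 0.5) {
  key <- if ("segment_id" %in% names(trajectories)) "segment_id" else "id"
  pieces <- split(trajectories, trajectories[[key]])
  out <- lapply(names(pieces), function(nm) {
    df <- ensure_velocity(pieces[[nm]][order(pieces[[nm]]$time), ])
    speed <- sqrt(df$vx^2 + df$vy^2)
    mask <- speed >= speed_bounds[1] & speed <= speed_bounds[2]
    # tolerate sub-max_gap excursions (avoidance braking/swerving)
    for (r in true_runs(!mask)) {
      if (df$time[r[2]] - df$time[r[1]] < max_gap) mask[r[1]:r[2]] <- TRUE
    }
    runs <- true_runs(mask)
    runs <- Filter(function(r) {
      r[2] > r[1] && (df$time[r[2]] - df$time[r[1]]) >= min_duration
    }, runs)
    if (length(runs) == 0L) {
      return(NULL)
    }
    dplyr::bind_rows(lapply(seq_along(runs), function(j) {
      seg <- df[runs[[j]][1]:runs[[j]][2], ]
      seg$segment_id <- if (length(runs) == 1L && key == "segment_id") {
        nm
      } else {
        paste0(if (key == "id") nm else nm, "#", j)
      }
      seg
    }))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(time = numeric(), id = character(), x = numeric(),
                          y = numeric(), vx = numeric(), vy = numeric(),
                          segment_id = character())
  }
  res
}

#' Build the track of a dyad's geometric center
#'
#' Resamples member 2 onto member 1's timestamps over their common time
#' support (linear interpolation) and takes the arithmetic midpoint as the
#' group position; the member separation series is attached and the center
#' velocity estimated by central differences.
#'
#' @param member1,member2 Trajectory tibbles of the two members (`time`,
#'   `x`, `y`).
#' @param group_id,class_label Carried as attributes on the result.
#' @return Tibble `time`, `x`, `y`, `vx`, `vy`, `separation` with attributes
#'   `group_id` and `class_label`, or `NULL` if the members share fewer than
#'   two timestamps (encounter-skip signal).
#' @export
build_group_track <- function(member1, member2, group_id = NA_character_,
                              class_label = NA_character_) {
  m1 <- member1[order(member1$time), ]
  m2 <- member2[order(member2$time), ]
  lo <- max(min(m1$time), min(m2$time))
  hi <- min(max(m1$time), max(m2$time))
  grid <- m1$time[m1$time >= lo & m1$time <= hi]
  if (length(grid) < 2L) {
    return(NULL)
  }
  x1 <- m1$x[m1$time >= lo & m1$time <= hi]
  y1 <- m1$y[m1$time >= lo & m1$time <= hi]
  x2 <- resample_linear(m2$time, m2$x, grid)
  y2 <- resample_linear(m2$time, m2$y, grid)
  cx <- (x1 + x2) / 2
  cy <- (y1 + y2) / 2
  out <- tibble::tibble(
    time = grid, x = cx, y = cy,
    vx = finite_diff(grid, cx), vy = finite_diff(grid, cy),
    separation = sqrt((x1 - x2)^2 + (y1 - y2)^2)
  )
  attr(out, "group_id") <- group_id
  attr(out, "class_label") <- class_label
  out
}

#' Class-average interpersonal distance
#'
#' The distance unit used for scaled ("barred") observables: the unweighted
#' mean over groups of each group's time-averaged member separation.
#'
#' @param group_tracks List of [build_group_track()] results.
#' @param class_label Class to average over; `NULL` uses all groups.
#' @return Scalar distance in meters, with attribute `per_group` (named
#'   vector of per-group means).
#' @export
class_interpersonal_distance <- function(group_tracks, class_label = NULL) {
  if (!is.null(class_label)) {
    group_tracks <- Filter(function(g) {
      identical(attr(g, "class_label"), class_label)
    }, group_tracks)
  }
  if (length(group_tracks) == 0L) {
    ped_stop(paste0("no groups in class: ",
                    if (is.null(class_label)) "<all>" else class_label),
             "validation_error")
  }
  per_group <- vapply(group_tracks, function(g) mean(g$separation), numeric(1))
  names(per_group) <- vapply(group_tracks, function(g) {
    as.character(attr(g, "group_id"))
  }, character(1))
  structure(mean(per_group), per_group = per_group)
}

# Joint series of individual and (resampled) group state on the individual's
# timestamps over the common support. NULL when fewer than `min_samples`
# common samples exist.
joint_series <- function(group_track, individual, min_samples = 4L) {
  ind <- ensure_velocity(individual[order(individual$time), ])
  lo <- max(min(ind$time), min(group_track$time))
  hi <- min(max(ind$time), max(group_track$time))
  keep <- ind$time >= lo & ind$time <= hi
  if (sum(keep) < min_samples) {
    return(NULL)
  }
  ind <- ind[keep, ]
  tibble::tibble(
    time = ind$time,
    ix = ind$x, iy = ind$y, ivx = ind$vx, ivy = ind$vy,
    gx = resample_linear(group_track$time, group_track$x, ind$time),
    gy = resample_linear(group_track$time, group_track$y, ind$time),
    gvx = resample_linear(group_track$time, group_track$vx, ind$time),
    gvy = resample_linear(group_track$time, group_track$vy, ind$time)
  )
}

#' Select frontal group-individual encounters
#'
#' An encounter is each maximal run of samples for which the individual lies
#' inside the square window `[-W, W]^2` of the group-centered frame; it is
#' frontal when the angle between group and individual velocities at the
#' entry sample is at least `frontal_angle_min` degrees (180 = exactly
#' head-on). A pedestrian leaving and genuinely re-entering the window
#' starts a new encounter, but exits shorter than `gap_merge` seconds are
#' treated as boundary sampling jitter and merged, and runs shorter than
#' `min_duration` are discarded.
#'
#' @param group_track A [build_group_track()] result.
#' @param individual Individual trajectory segment (`time`, `x`, `y`, and
#'   optionally `vx`, `vy`).
#' @param frontal_angle_min Minimum velocity-velocity angle in degrees.
#' @param W Window half-width, meters.
#' @param gap_merge Maximum out-of-window gap (seconds) merged into one
#'   encounter.
#' @param min_duration Minimum encounter duration, seconds.
#' @return Manifest tibble (`group_id`, `individual_id`, `class`, `entry_index`,
#'   `t_entry`, `t_exit`, `angle_at_entry`, `began_inside`); zero rows when no
#'   frontal encounter exists.
#' @export
select_frontal_encounters <- function(group_track, individual,
                                      frontal_angle_min = 135, W = 4,
                                      gap_merge = 0.5, min_duration = 0.5) {
  empty <- tibble::tibble(
    group_id = character(), individual_id = character(), class = character(),
    entry_index = integer(), t_entry = numeric(), t_exit = numeric(),
    angle_at_entry = numeric(), began_inside = logical()
  )
  js <- joint_series(group_track, individual)
  if (is.null(js)) {
    return(empty)
  }
  theta <- atan2(js$gvy, js$gvx)
  fr <- rotate_xy(js$ix - js$gx, js$iy - js$gy, -theta)
  inside <- abs(fr$x) <= W & abs(fr$y) <= W
  runs <- true_runs(inside)
  if (length(runs) > 1L) {
    merged <- list(runs[[1L]])
    for (r in runs[-1L]) {
      prev <- merged[[length(merged)]]
      if (js$time[r[1]] - js$time[prev[2]] <= gap_merge) {
        merged[[length(merged)]] <- c(prev[1], r[2])
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
    runs <- merged
  }
  runs <- Filter(function(r) js$time[r[2]] - js$time[r[1]] >= min_duration, runs)
  if (length(runs) == 0L) {
    return(empty)
  }
  rows <- lapply(seq_along(runs), function(j) {
    k <- runs[[j]][1]
    dot <- js$gvx[k] * js$ivx[k] + js$gvy[k] * js$ivy[k]
    ng <- sqrt(js$gvx[k]^2 + js$gvy[k]^2)
    ni <- sqrt(js$ivx[k]^2 + js$ivy[k]^2)
    ang <- if (ng > 0 && ni > 0) {
      acos(pmin(pmax(dot / (ng * ni), -1), 1)) * 180 / pi
    } else {
      NA_real_
    }
    tibble::tibble(
      group_id = as.character(attr(group_track, "group_id")),
      individual_id = as.character(individual$id[1]),
      class = as.character(attr(group_track, "class_label")),
      entry_index = k,
      t_entry = js$time[k], t_exit = js$time[runs[[j]][2]],
      angle_at_entry = ang,
      began_inside = k == 1L
    )
  })
  out <- dplyr::bind_rows(rows)
  out[!is.na(out$angle_at_entry) & out$angle_at_entry >= frontal_angle_min, ]
}

#' Transform an encounter into the group-centered co-moving frame
#'
#' Per timestamp: translate so the group center sits at the origin, rotate so
#' the group velocity points along `+x`, and shift velocities by the group
#' velocity. The rotation preserves the relative distance `|r(t)|` exactly.
#' Timestamps where the group is momentarily stationary (speed below
#' `degenerate_speed`) are dropped and counted.
#'
#' @param group_track A [build_group_track()] result.
#' @param individual Individual trajectory segment.
#' @param degenerate_speed Group speed below which the frame orientation is
#'   undefined, m/s.
#' @return Tibble `time`, `x`, `y` (individual position in the group frame),
#'   `vx`, `vy` (relative velocity in that frame), `group_speed`, with
#'   attribute `n_dropped_degenerate`; `NULL` if the group is stationary
#'   throughout (encounter-skip signal).
#' @export
to_group_frame <- function(group_track, individual, degenerate_speed = 1e-9) {
  js <- joint_series(group_track, individual)
  if (is.null(js)) {
    return(NULL)
  }
  gspeed <- sqrt(js$gvx^2 + js$gvy^2)
  ok <- gspeed > degenerate_speed
  n_dropped <- sum(!ok)
  if (sum(ok) < 2L) {
    return(NULL)
  }
  js <- js[ok, ]
  gspeed <- gspeed[ok]
  theta <- atan2(js$gvy, js$gvx)
  pos <- rotate_xy(js$ix - js$gx, js$iy - js$gy, -theta)
  vel <- rotate_xy(js$ivx - js$gvx, js$ivy - js$gvy, -theta)
  out <- tibble::tibble(
    time = js$time, x = pos$x, y = pos$y, vx = vel$x, vy = vel$y,
    group_speed = gspeed
  )
  attr(out, "n_dropped_degenerate") <- n_dropped
  out
}
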