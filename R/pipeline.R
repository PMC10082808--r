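# Build all group tracks from filtered segments + annotations. Returns a
# list of tracks (one per overlapping member-segment pair).
build_all_group_tracks <- function(filtered, annotations) {
  tracks <- list()
  for (i in seq_len(nrow(annotations))) {
    gid <- annotations$group_id[i]
    cls <- annotations$class_label[i]
    seg1 <- filtered[filtered$id == annotations$member_id_1[i], ]
    seg2 <- filtered[filtered$id == annotations$member_id_2[i], ]
    if (nrow(seg1) == 0L || nrow(seg2) == 0L) next
    pairs <- expand.grid(s1 = unique(seg1$segment_id), s2 = unique(seg2$segment_id),
                         stringsAsFactors = FALSE)
    j <- 0L
    for (p in seq_len(nrow(pairs))) {
      gt <- build_group_track(seg1[seg1$segment_id == pairs$s1[p], ],
                              seg2[seg2$segment_id == pairs$s2[p], ],
                              group_id = gid, class_label = cls)
      if (is.null(gt)) next
      j <- j + 1L
      attr(gt, "group_id") <- if (nrow(pairs) > 1L) paste0(gid, "#", j) else gid
      attr(gt, "base_group_id") <- gid
      tracks[[length(tracks) + 1L]] <- gt
    }
  }
  tracks
}

# Observables + in-window frame positions for every frontal encounter of one
# (group track, individual segment) pair.
pair_encounters <- function(gtrack, iseg, config) {
  manifest <- select_frontal_encounters(gtrack, iseg,
                                        frontal_angle_min = config$frontal_angle_min,
                                        W = config$window_half_width,
                                        gap_merge = config$encounter_gap_merge,
                                        min_duration = config$min_encounter_duration)
  if (nrow(manifest) == 0L) {
    return(NULL)
  }
  frame <- to_group_frame(gtrack, iseg)
  if (is.null(frame)) {
    return(NULL)
  }
  manifest <- manifest[order(manifest$t_entry), ]
  obs <- list()
  pos <- list()
  t_floor <- -Inf
  for (j in seq_len(nrow(manifest))) {
    sub <- frame[frame$time > t_floor & frame$time <= manifest$t_exit[j], ]
    eid <- paste(attr(gtrack, "group_id"), manifest$individual_id[j], j, sep = "|")
    o <- encounter_observables(sub, W = config$window_half_width,
                               n_avg = config$velocity_averaging_samples,
                               encounter_id = eid,
                               class_label = manifest$class[j])
    if (!is.null(o)) {
      o$group_id <- as.character(attr(gtrack, "base_group_id") %||% attr(gtrack, "group_id"))
      o$individual_id <- manifest$individual_id[j]
      o$angle_at_entry <- manifest$angle_at_entry[j]
      obs[[length(obs) + 1L]] <- o
      inw <- sub[abs(sub$x) <= config$window_half_width &
                   abs(sub$y) <= config$window_half_width &
                   sub$time >= o$t_prime, c("x", "y")]
      inw$class <- manifest$class[j]
      pos[[length(pos) + 1L]] <- inw
    }
    t_floor <- manifest$t_exit[j]
  }
  if (length(obs) == 0L) {
    return(NULL)
  }
  list(observables = dplyr::bind_rows(obs), positions = dplyr::bind_rows(pos))
}

#' Extract frontal group-individual encounters and their observables
#'
#' Runs the preprocessing chain — atypical-motion filtering, group-center
#' tracks, class interpersonal distances, frontal-encounter selection, frame
#' transform — and computes per-encounter observables (entry time,
#' straight-line distance, interpolated minimum distance) in meters and in
#' interpersonal-distance units.
#'
#' @param trajectories Trajectory tibble (`time`, `id`, `x`, `y`).
#' @param annotations Dyad annotation tibble.
#' @param config A [run_config()].
#' @return List: `observables` (one row per encounter, metric and scaled),
#'   `d_class` (tibble class/d), `positions` (scaled in-window frame
#'   positions for maps), `group_tracks`, `log`.
#' @export
extract_encounters <- function(trajectories, annotations, config = run_config()) {
  trajectories <- validate_trajectories(trajectories)
  log <- new_log()

  n_ped <- length(unique(trajectories$id))
  filtered <- filter_atypical(trajectories, config$speed_bounds,
                              config$min_segment_duration)
  log <- log_stage(log, "filter_atypical", n_ped,
                   length(unique(filtered$id)),
                   paste0(length(unique(filtered$segment_id)), " segments"))

  tracks <- build_all_group_tracks(filtered, annotations)
  log <- log_stage(log, "group_tracks", nrow(annotations), length(tracks))
  if (length(tracks) == 0L) {
    ped_stop("empty analysis: no group track could be built", "empty_analysis")
  }

  classes <- sort(unique(vapply(tracks, function(g) attr(g, "class_label"), character(1))))
  d_class <- tibble::tibble(
    class = classes,
    d = vapply(classes, function(cl) {
      as.numeric(class_interpersonal_distance(tracks, cl))
    }, numeric(1))
  )

  members <- unique(c(annotations$member_id_1, annotations$member_id_2))
  ind <- filtered[!filtered$id %in% members, ]
  isegs <- split(ind, ind$segment_id)
  log <- log_stage(log, "individual_segments", n_ped - length(members),
                   length(isegs))

  # time-range prefilter keeps pairing linear in practice
  iranges <- if (length(isegs) > 0L) {
    t(vapply(isegs, function(s) range(s$time), numeric(2)))
  } else {
    matrix(numeric(0), ncol = 2)
  }
  obs <- list()
  pos <- list()
  n_pairs <- 0L
  for (gt in tracks) {
    gr <- range(gt$time)
    cand <- which(iranges[, 1] < gr[2] & iranges[, 2] > gr[1])
    for (ci in cand) {
      n_pairs <- n_pairs + 1L
      pe <- pair_encounters(gt, isegs[[ci]], config)
      if (is.null(pe)) next
      obs[[length(obs) + 1L]] <- pe$observables
      pos[[length(pos) + 1L]] <- pe$positions
    }
  }
  observables <- dplyr::bind_rows(obs)
  log <- log_stage(log, "frontal_encounters", n_pairs, nrow(observables))
  if (nrow(observables) == 0L) {
    ped_stop("empty analysis: no frontal encounter survived the filters",
             "empty_analysis")
  }

  observables <- observables |>
    dplyr::left_join(d_class, by = "class") |>
    dplyr::mutate(rbar_b = .data$r_b / .data$d, rbar_0 = .data$r_0 / .data$d)
  positions <- dplyr::bind_rows(pos) |>
    dplyr::left_join(d_class, by = "class") |>
    dplyr::mutate(x = .data$x / .data$d, y = .data$y / .data$d) |>
    dplyr::select("x", "y", "class")

  list(observables = observables, d_class = d_class, positions = positions,
       group_tracks = tracks, log = log)
}

#' Run the full group-individual analysis pipeline
#'
#' Orchestrates encounter extraction, 0.5-unit binned statistics of the
#' scaled minimum distance versus the scaled straight-line distance, per-bin
#' ANOVA across classes, intrusion probabilities with Pearson chi-squared
#' tests, the linear straight-line-distance calibration, probed
#' collision-avoidance potential points with power-law and exponential fits
#' per class, and 2D density maps (cumulative-normalized and
#' relative-to-average). Deterministic given inputs and config.
#'
#' @inheritParams extract_encounters
#' @return A `"ped_analysis"` bundle: `config`, `log`, `observables`,
#'   `d_class`, `binned`, `anova`, `intrusion` (probabilities + tests),
#'   `correction`, `potential` (`points`, `fits`), `maps` (`cumulative`,
#'   `relative`).
#' @export
run_pipeline <- function(trajectories, annotations, config = run_config()) {
  ex <- extract_encounters(trajectories, annotations, config)
  obs <- ex$observables
  log <- ex$log

  binned <- bin_pairs(obs, config$bin_width)
  anova <- anova_per_bin(obs, config$bin_width)
  intrusion <- intrusion_table(obs, config$intrusion_thresholds, config$bin_width)

  if (is.null(config$rb_correction_floor)) {
    obs$rbar_b_corrected <- obs$rbar_b
    correction <- list(slope = 1, intercept = 0, applied = FALSE,
                       n_calibration = 0L)
  } else {
    corr <- rb_linear_correction(obs, floor = config$rb_correction_floor)
    obs <- corr$observables
    correction <- corr[c("slope", "intercept", "applied", "n_calibration")]
  }
  log <- log_stage(log, "rb_correction", nrow(obs), nrow(obs),
                   sprintf("slope=%.4f intercept=%.4f applied=%s",
                           correction$slope, correction$intercept,
                           correction$applied))

  binned_corr <- bin_pairs(obs, config$bin_width, rb_col = "rbar_b_corrected")
  points <- potential_points(binned_corr)
  classes <- sort(unique(obs$class))
  fits <- dplyr::bind_rows(lapply(classes, function(cl) {
    pts <- points[points$class == cl, ]
    fits_to_table(list(fit_power_law(pts), fit_exponential(pts)), cl, "scaled")
  }))

  half_width_scaled <- config$window_half_width / min(ex$d_class$d)
  cumulative <- density_map(ex$positions, cell = config$grid_cell,
                            half_width = half_width_scaled,
                            mode = "cumulative-normalized")
  relative <- NULL
  if (length(classes) >= 2L) {
    relative <- density_map(ex$positions, cell = config$grid_cell,
                            half_width = half_width_scaled, mode = "relative")
  } else {
    log <- log_stage(log, "relative_maps", 1L, 0L, "single class: skipped")
  }

  structure(list(
    config = config, log = log, observables = obs, d_class = ex$d_class,
    binned = binned, anova = anova, intrusion = intrusion,
    correction = correction,
    potential = list(points = points, fits = fits),
    maps = list(cumulative = cumulative, relative = relative)
  ), class = "ped_analysis")
}

#' Individual-individual comparison pipeline
#'
#' Applies the same observable / binning / potential chain to pairs of lone
#' pedestrians, with one individual of each pair playing the group-center
#' role. Distances stay in meters (there is no interpersonal distance to
#' scale by), making the fitted potentials directly comparable with
#' group-individual fits computed in meters.
#'
#' @param trajectories Trajectory tibble.
#' @param config A [run_config()]; `bin_width` is interpreted in meters.
#' @param exclude_ids Pedestrian ids to leave out (e.g. group members).
#' @return A `"ped_ii_analysis"` list: `observables`, `binned`, `correction`,
#'   `potential` (`points`, `fits`), `log`.
#' @export
individual_individual_pipeline <- function(trajectories, config = run_config(),
                                           exclude_ids = NULL) {
  trajectories <- validate_trajectories(trajectories)
  log <- new_log()
  traj <- trajectories[!trajectories$id %in% exclude_ids, ]
  n_ped <- length(unique(traj$id))
  if (n_ped < 2L) {
    ped_stop("individual-individual analysis needs at least 2 pedestrians",
             "empty_analysis")
  }
  filtered <- filter_atypical(traj, config$speed_bounds, config$min_segment_duration)
  segs <- split(filtered, filtered$segment_id)
  log <- log_stage(log, "filter_atypical", n_ped, length(segs))
  if (length(segs) < 2L) {
    ped_stop("empty analysis: fewer than 2 usable segments", "empty_analysis")
  }
  seg_ids <- vapply(segs, function(s) s$id[1], character(1))
  ranges <- t(vapply(segs, function(s) range(s$time), numeric(2)))

  obs <- list()
  n_pairs <- 0L
  for (i in seq_along(segs)) {
    for (j in seq_along(segs)) {
      if (j <= i || seg_ids[i] == seg_ids[j]) next
      if (ranges[i, 1] >= ranges[j, 2] || ranges[i, 2] <= ranges[j, 1]) next
      n_pairs <- n_pairs + 1L
      # deterministic target: lexicographically smaller id plays the center
      ord <- order(c(seg_ids[i], seg_ids[j]))
      tgt <- segs[[c(i, j)[ord[1]]]]
      oth <- segs[[c(i, j)[ord[2]]]]
      pseudo <- ensure_velocity(tgt)
      pseudo$separation <- NA_real_
      attr(pseudo, "group_id") <- tgt$id[1]
      attr(pseudo, "class_label") <- "individual"
      pe <- pair_encounters(pseudo, oth, config)
      if (!is.null(pe)) obs[[length(obs) + 1L]] <- pe$observables
    }
  }
  observables <- dplyr::bind_rows(obs)
  log <- log_stage(log, "frontal_pairs", n_pairs, nrow(observables))
  if (nrow(observables) == 0L) {
    ped_stop("empty analysis: no frontal individual-individual encounter",
             "empty_analysis")
  }
  # meters throughout: the scaled columns alias the metric ones
  observables$rbar_b <- observables$r_b
  observables$rbar_0 <- observables$r_0

  binned <- bin_pairs(observables, config$bin_width)
  if (is.null(config$rb_correction_floor)) {
    observables$rbar_b_corrected <- observables$rbar_b
    correction <- list(slope = 1, intercept = 0, applied = FALSE, n_calibration = 0L)
  } else {
    corr <- rb_linear_correction(observables, floor = config$rb_correction_floor)
    observables <- corr$observables
    correction <- corr[c("slope", "intercept", "applied", "n_calibration")]
  }
  binned_corr <- bin_pairs(observables, config$bin_width, rb_col = "rbar_b_corrected")
  points <- potential_points(binned_corr)
  fits <- fits_to_table(list(fit_power_law(points), fit_exponential(points)),
                        "individual", "meters")
  structure(list(
    config = config, log = log, observables = observables, binned = binned,
    correction = correction, potential = list(points = points, fits = fits)
  ), class = "ped_ii_analysis")
}

#' @export
print.ped_analysis <- function(x, ...) {
  cat("<ped_analysis>\n")
  cat("  encounters:", nrow(x$observables), "\n")
  cat("  classes:   ", paste(x$d_class$class, collapse = ", "), "\n")
  cat("  d_class:   ", paste(sprintf("%s=%.3f m", x$d_class$class, x$d_class$d),
                             collapse = ", "), "\n")
  cat("  rb correction: slope", format(x$correction$slope, digits = 4),
      "intercept", format(x$correction$intercept, digits = 4), "\n")
  invisible(x)
}
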