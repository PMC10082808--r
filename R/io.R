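#' Trajectory file dialect
#'
#' Maps the columns and units of a trajectory CSV onto the canonical
#' `time, id, x, y` schema in seconds and meters. The default dialect is the
#' package's own output format; `position_unit = "mm"` accommodates
#' range-sensor exports that record positions in millimeters.
#'
#' @param time,id,x,y Column names in the source file.
#' @param position_unit `"m"` or `"mm"`.
#' @param time_unit `"s"` or `"ms"`.
#' @return A list of class `"ped_dialect"`.
#' @export
trajectory_dialect <- function(time = "time", id = "id", x = "x", y = "y",
                               position_unit = c("m", "mm"),
                               time_unit = c("s", "ms")) {
  position_unit <- match.arg(position_unit)
  time_unit <- match.arg(time_unit)
  structure(
    list(
      time = time, id = id, x = x, y = y,
      position_scale = if (position_unit == "mm") 1e-3 else 1,
      time_scale = if (time_unit == "ms") 1e-3 else 1
    ),
    class = "ped_dialect"
  )
}

#' Validate a trajectory table
#'
#' Checks the invariants required downstream: canonical columns, finite
#' coordinates, and strictly increasing times within each pedestrian.
#'
#' @param trajectories Tibble with columns `time`, `id`, `x`, `y`.
#' @return The input, sorted by `(id, time)`, invisibly classed as validated.
#' @export
validate_trajectories <- function(trajectories) {
  required <- c("time", "id", "x", "y")
  missing <- setdiff(required, names(trajectories))
  if (length(missing) > 0) {
    ped_stop(paste0("trajectory table lacks columns: ", paste(missing, collapse = ", ")),
             "format_error")
  }
  if (!all(is.finite(trajectories$x)) || !all(is.finite(trajectories$y)) ||
      !all(is.finite(trajectories$time))) {
    ped_stop("trajectory table contains non-finite time or coordinates", "validation_error")
  }
  out <- dplyr::arrange(trajectories, .data$id, .data$time)
  bad <- out |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(ok = all(diff(.data$time) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    ped_stop(paste0("non-increasing timestamps for pedestrian(s): ",
                    paste(bad$id, collapse = ", ")), "validation_error")
  }
  out
}

#' Read pedestrian trajectories from a CSV file
#'
#' @param path CSV file path.
#' @param dialect A [trajectory_dialect()] describing column names and units.
#' @return A validated tibble with columns `time` (s), `id`, `x`, `y` (m),
#'   sorted by pedestrian and time.
#' @export
read_trajectories <- function(path, dialect = trajectory_dialect()) {
  if (!file.exists(path)) ped_stop(paste0("file not found: ", path), "format_error")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- c(dialect$time, dialect$id, dialect$x, dialect$y)
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0) {
    ped_stop(paste0("missing column(s) in ", path, ": ", paste(missing, collapse = ", ")),
             "format_error")
  }
  out <- tibble::tibble(
    time = as.numeric(raw[[dialect$time]]) * dialect$time_scale,
    id = as.character(raw[[dialect$id]]),
    x = as.numeric(raw[[dialect$x]]) * dialect$position_scale,
    y = as.numeric(raw[[dialect$y]]) * dialect$position_scale
  )
  validate_trajectories(out)
}

#' Write trajectories in the canonical dialect
#'
#' @param trajectories Trajectory tibble (`time`, `id`, `x`, `y`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories[, c("time", "id", "x", "y")], path, progress = FALSE)
  invisible(path)
}

#' Validate a dyad annotation table
#'
#' @param annotations Tibble with columns `group_id`, `member_id_1`,
#'   `member_id_2`, `class_label`.
#' @param trajectories Optional trajectory table for referential checks.
#' @param label_scheme `"relation"` or `"intensity"`; must match the declared
#'   label set.
#' @param labels Allowed class labels; defaults depend on the scheme
#'   (colleagues/couples/family/friends, or intensities 0-3).
#' @return The validated tibble with attribute `label_scheme`.
#' @export
validate_annotations <- function(annotations, trajectories = NULL,
                                 label_scheme = c("relation", "intensity"),
                                 labels = NULL) {
  label_scheme <- match.arg(label_scheme)
  if (is.null(labels)) {
    labels <- switch(label_scheme,
      relation = c("colleagues", "couples", "family", "friends"),
      intensity = c("0", "1", "2", "3")
    )
  }
  required <- c("group_id", "member_id_1", "member_id_2", "class_label")
  missing <- setdiff(required, names(annotations))
  if (length(missing) > 0) {
    ped_stop(paste0("annotation table lacks columns: ", paste(missing, collapse = ", ")),
             "format_error")
  }
  ann <- dplyr::mutate(annotations, dplyr::across(dplyr::all_of(required), as.character))
  if (any(ann$member_id_1 == ann$member_id_2)) {
    ped_stop("a dyad lists the same pedestrian twice", "validation_error")
  }
  bad_labels <- setdiff(unique(ann$class_label), labels)
  if (length(bad_labels) > 0) {
    ped_stop(paste0("class label(s) outside the '", label_scheme, "' scheme: ",
                    paste(bad_labels, collapse = ", ")), "validation_error")
  }
  members <- c(ann$member_id_1, ann$member_id_2)
  if (anyDuplicated(members)) {
    dup <- unique(members[duplicated(members)])
    ped_stop(paste0("pedestrian(s) assigned to more than one group: ",
                    paste(dup, collapse = ", ")), "validation_error")
  }
  if (!is.null(trajectories)) {
    absent <- setdiff(members, unique(trajectories$id))
    if (length(absent) > 0) {
      ped_stop(paste0("group member(s) absent from trajectories: ",
                      paste(absent, collapse = ", ")), "referential_error")
    }
  }
  attr(ann, "label_scheme") <- label_scheme
  ann
}

#' Read a dyad annotation table from CSV
#'
#' @inheritParams validate_annotations
#' @param path CSV with columns `group_id`, `member_id_1`, `member_id_2`,
#'   `class_label`.
#' @return Validated annotation tibble.
#' @export
read_annotations <- function(path, trajectories = NULL,
                             label_scheme = c("relation", "intensity"),
                             labels = NULL) {
  if (!file.exists(path)) ped_stop(paste0("file not found: ", path), "format_error")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_annotations(raw, trajectories, label_scheme, labels)
}

#' Write analysis results to a directory of CSV tables
#'
#' Each element of the bundle produced by [run_pipeline()] becomes one CSV;
#' density maps are written as one grid per class (rows are y indices).
#'
#' @param results A `"ped_analysis"` bundle.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!inherits(results, "ped_analysis")) {
    ped_stop("write_results expects a ped_analysis bundle", "validation_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  wr(results$observables, "observables")
  wr(results$binned, "binned")
  wr(results$anova, "anova")
  wr(results$intrusion$probabilities, "intrusion_probabilities")
  wr(results$intrusion$tests, "intrusion_tests")
  wr(results$potential$points, "potential_points")
  wr(results$potential$fits, "potential_fits")
  wr(results$log, "log")
  corr <- results$correction
  wr(tibble::tibble(slope = corr$slope, intercept = corr$intercept,
                    applied = corr$applied, n_calibration = corr$n_calibration),
     "rb_correction")
  for (cls in names(results$maps$relative)) {
    m <- results$maps$relative[[cls]]
    utils::write.table(m$z, file.path(dir, paste0("map_relative_", cls, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(results$maps$cumulative$z,
                     file.path(dir, "map_cumulative.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
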