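bin_index <- function(x, width) as.integer(floor(x / width))

#' Bin minimum distances by straight-line distance
#'
#' Quantizes the (scaled) straight-line distance into half-open bins
#' `[k w, (k+1) w)` and reports, per class and bin, the count, mean and
#' standard error of the (scaled) minimum distance. Bins with no data are
#' emitted with `n = 0` so the bin grid is complete across classes.
#'
#' @param observables Observables tibble.
#' @param bin_width Bin width (same units as `rb_col`).
#' @param rb_col,r0_col Column names of the binned distance and the
#'   aggregated distance.
#' @return Tibble `class`, `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean_r0`,
#'   `sem_r0`.
#' @export
bin_pairs <- function(observables, bin_width = 0.5,
                      rb_col = "rbar_b", r0_col = "rbar_0") {
  rb <- observables[[rb_col]]
  r0 <- observables[[r0_col]]
  cls <- as.character(observables$class)
  stats <- tibble::tibble(class = cls, bin = bin_index(rb, bin_width), r0 = r0) |>
    dplyr::group_by(.data$class, .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_r0 = mean(.data$r0),
      sem_r0 = ifelse(dplyr::n() >= 2L, stats::sd(.data$r0) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(
    class = sort(unique(cls)),
    bin = seq(min(stats$bin), max(stats$bin))
  )
  dplyr::left_join(grid, stats, by = c("class", "bin")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      bin_lo = .data$bin * bin_width,
      bin_hi = (.data$bin + 1L) * bin_width,
      bin_mid = .data$bin_lo + bin_width / 2
    ) |>
    dplyr::select("class", "bin_lo", "bin_hi", "bin_mid", "n", "mean_r0", "sem_r0")
}

#' Per-bin one-way ANOVA across classes
#'
#' For each straight-line-distance bin, a classical one-way fixed-effects
#' ANOVA (equal-variance F test) of the minimum distance across social
#' classes. Bins with fewer than two classes holding at least two
#' observations each get a missing p-value with a reason.
#'
#' @inheritParams bin_pairs
#' @return Tibble `bin_lo`, `bin_hi`, `n_classes`, `n_total`, `F`,
#'   `p_value`, `reason`.
#' @export
anova_per_bin <- function(observables, bin_width = 0.5,
                          rb_col = "rbar_b", r0_col = "rbar_0") {
  df <- tibble::tibble(
    class = as.character(observables$class),
    bin = bin_index(observables[[rb_col]], bin_width),
    r0 = observables[[r0_col]]
  )
  bins <- sort(unique(df$bin))
  rows <- lapply(bins, function(b) {
    sub <- df[df$bin == b, ]
    counts <- table(sub$class)
    usable <- names(counts)[counts >= 2L]
    base <- tibble::tibble(
      bin_lo = b * bin_width, bin_hi = (b + 1L) * bin_width,
      n_classes = length(usable), n_total = nrow(sub),
      F = NA_real_, p_value = NA_real_, reason = NA_character_
    )
    if (length(usable) < 2L) {
      base$reason <- if (length(usable) == 1L) "single class" else "insufficient data"
      return(base)
    }
    sub <- sub[sub$class %in% usable, ]
    ft <- stats::oneway.test(r0 ~ class, data = sub, var.equal = TRUE)
    base$F <- unname(ft$statistic)
    base$p_value <- unname(ft$p.value)
    base
  })
  dplyr::bind_rows(rows)
}

#' Intrusion probabilities and independence tests
#'
#' An intrusion is an encounter whose (scaled) minimum distance falls below a
#' threshold — by default 1 interpersonal distance (the individual ends up
#' closer to the group center than the members are to each other) and 0.5
#' (the mean member-to-center distance). Per class and bin the empirical
#' probability is the intrusion count over the bin total; per bin, a Pearson
#' chi-squared test (no continuity correction) probes independence of the
#' class x (intrude / not) contingency table.
#'
#' @inheritParams bin_pairs
#' @param thresholds Numeric vector of intrusion thresholds (same units as
#'   `r0_col`).
#' @return List with `probabilities` (class x bin x threshold tibble) and
#'   `tests` (bin x threshold chi-squared results; `unreliable` flags any
#'   expected cell count below 1).
#' @export
intrusion_table <- function(observables, thresholds = c(1.0, 0.5),
                            bin_width = 0.5,
                            rb_col = "rbar_b", r0_col = "rbar_0") {
  if (any(thresholds <= 0)) ped_stop("intrusion thresholds must be > 0", "config_error")
  df <- tibble::tibble(
    class = as.character(observables$class),
    bin = bin_index(observables[[rb_col]], bin_width),
    r0 = observables[[r0_col]]
  )
  probs <- dplyr::bind_rows(lapply(thresholds, function(th) {
    df |>
      dplyr::group_by(.data$class, .data$bin) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_intrusion = sum(.data$r0 < th),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        threshold = th,
        probability = .data$n_intrusion / .data$n,
        bin_lo = .data$bin * bin_width,
        bin_hi = (.data$bin + 1L) * bin_width
      )
  })) |>
    dplyr::select("threshold", "class", "bin_lo", "bin_hi", "n",
                  "n_intrusion", "probability")

  tests <- dplyr::bind_rows(lapply(thresholds, function(th) {
    sub_all <- probs[probs$threshold == th, ]
    dplyr::bind_rows(lapply(sort(unique(sub_all$bin_lo)), function(bl) {
      sub <- sub_all[sub_all$bin_lo == bl & sub_all$n > 0L, ]
      base <- tibble::tibble(
        threshold = th, bin_lo = bl, bin_hi = bl + bin_width,
        statistic = NA_real_, df = NA_real_, p_value = NA_real_,
        unreliable = NA, reason = NA_character_
      )
      if (nrow(sub) < 2L) {
        base$reason <- "single class"
        return(base)
      }
      tab <- cbind(intrude = sub$n_intrusion, pass = sub$n - sub$n_intrusion)
      if (any(colSums(tab) == 0L)) {
        base$reason <- "degenerate outcome column"
        return(base)
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      base$statistic <- unname(ct$statistic)
      base$df <- unname(ct$parameter)
      base$p_value <- unname(ct$p.value)
      base$unreliable <- any(ct$expected < 1)
      base
    }))
  }))
  list(probabilities = probs, tests = tests)
}

#' Linear calibration of the straight-line distance
#'
#' In a perfectly straight, wide environment the minimum distance equals the
#' straight-line distance once avoidance is negligible (large separations).
#' Curved or narrow environments bias the straight-line extrapolation
#' upward; this calibration fits `r0 = a rb + c` by least squares over the
#' large-separation regime (`rb >= floor`) and maps every straight-line
#' distance through the fitted line. In an unbiased environment `a ~ 1`,
#' `c ~ 0` and the correction is a near-identity.
#'
#' @inheritParams bin_pairs
#' @param floor Calibration floor: only encounters with `rb_col >= floor`
#'   inform the fit.
#' @param min_points Minimum calibration encounters; below it the identity is
#'   used with a warning.
#' @return List `observables` (input plus `<rb_col>_corrected`), `slope`,
#'   `intercept`, `applied`, `n_calibration`.
#' @export
rb_linear_correction <- function(observables, floor = 2.0, min_points = 10L,
                                 rb_col = "rbar_b", r0_col = "rbar_0") {
  rb <- observables[[rb_col]]
  r0 <- observables[[r0_col]]
  calib <- rb >= floor
  n_calib <- sum(calib)
  out_col <- paste0(rb_col, "_corrected")
  if (n_calib < min_points || stats::var(rb[calib]) == 0) {
    warning("too few calibration encounters with ", rb_col, " >= ", floor,
            "; straight-line distances left uncorrected", call. = FALSE)
    observables[[out_col]] <- rb
    return(list(observables = observables, slope = 1, intercept = 0,
                applied = FALSE, n_calibration = n_calib))
  }
  fit <- stats::lm(r0[calib] ~ rb[calib])
  a <- unname(stats::coef(fit)[2L])
  c0 <- unname(stats::coef(fit)[1L])
  # corrected values are still distances: clamp at zero
  observables[[out_col]] <- pmax(a * rb + c0, 0)
  list(observables = observables, slope = a, intercept = c0,
       applied = TRUE, n_calibration = n_calib)
}

hist2d <- function(x, y, cell, half_width) {
  n_cells <- as.integer(ceiling(2 * half_width / cell))
  ix <- as.integer(floor((x + half_width) / cell)) + 1L
  iy <- as.integer(floor((y + half_width) / cell)) + 1L
  ok <- ix >= 1L & ix <= n_cells & iy >= 1L & iy <= n_cells
  z <- matrix(0, nrow = n_cells, ncol = n_cells)
  if (any(ok)) {
    lin <- (ix[ok] - 1L) * n_cells + iy[ok]
    counts <- tabulate(lin, nbins = n_cells * n_cells)
    z <- matrix(counts, nrow = n_cells, ncol = n_cells)
  }
  list(z = z, n_dropped = sum(!ok), n_used = sum(ok))
}

#' 2D density maps of relative position
#'
#' Histograms the individual's position in the group-centered frame on a
#' square grid. Mode `"cumulative-normalized"` pools all positions and
#' scales the histogram by its maximum (max cell = 1). Mode `"relative"`
#' builds one probability-normalized map per class and subtracts the
#' unweighted across-class mean map, so positive cells mark where a class
#' sees the individual more often than average; the relative maps of all
#' classes sum to zero cell by cell.
#'
#' @param positions Tibble with columns `x`, `y` and, for mode
#'   `"relative"`, `class`.
#' @param cell Grid cell size (same units as the positions).
#' @param half_width Half-extent of the mapped square.
#' @param mode `"cumulative-normalized"` or `"relative"`.
#' @return For the cumulative mode a `ped_density_map` (list with `z` matrix
#'   indexed `[y, x]`, `x_edges`, `y_edges`, `mode`, counts); for the
#'   relative mode a named list of such maps, one per class.
#' @export
density_map <- function(positions, cell = 0.10, half_width = 4,
                        mode = c("cumulative-normalized", "relative")) {
  mode <- match.arg(mode)
  if (nrow(positions) == 0L) ped_stop("no positions to map", "validation_error")
  n_cells <- as.integer(ceiling(2 * half_width / cell))
  edges <- -half_width + cell * (0:n_cells)
  as_map <- function(z, h, m) {
    structure(list(z = z, x_edges = edges, y_edges = edges, cell = cell,
                   mode = m, n_dropped = h$n_dropped, n_used = h$n_used),
              class = "ped_density_map")
  }
  if (mode == "cumulative-normalized") {
    h <- hist2d(positions$x, positions$y, cell, half_width)
    if (h$n_used == 0L) ped_stop("all positions fall outside the map", "validation_error")
    return(as_map(h$z / max(h$z), h, mode))
  }
  if (!"class" %in% names(positions)) {
    ped_stop("relative maps need a 'class' column", "format_error")
  }
  classes <- sort(unique(as.character(positions$class)))
  if (length(classes) < 2L) ped_stop("relative maps need at least two classes", "validation_error")
  hs <- lapply(classes, function(cl) {
    sub <- positions[positions$class == cl, ]
    h <- hist2d(sub$x, sub$y, cell, half_width)
    if (h$n_used == 0L) {
      ped_stop(paste0("class '", cl, "' has no in-map positions"), "validation_error")
    }
    h
  })
  pmaps <- lapply(hs, function(h) h$z / h$n_used)
  mmap <- Reduce(`+`, pmaps) / length(pmaps)
  out <- Map(function(p, h) as_map(p - mmap, h, "relative"), pmaps, hs)
  names(out) <- classes
  out
}
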