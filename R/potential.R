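#' Probed collision-avoidance potential points
#'
#' Converts binned `(rb, r0)` statistics into probed potential values: for
#' each non-empty bin, `U' = (r0m^2 - rb^2) / r0m^2` with `r0m` the bin's
#' mean minimum distance and `rb` the bin midpoint. Each point is attached to
#' the abscissa `r0m`, the distance at which the potential is actually
#' probed. Negative values (minimum distance below the straight-line
#' prediction, an environment-bias signature) are retained but flagged.
#'
#' @param binned A [bin_pairs()] table.
#' @return Tibble `class`, `bin_lo`, `bin_hi`, `rb_rep`, `r0`, `U_prime`,
#'   `n`, `negative`.
#' @export
potential_points <- function(binned) {
  pts <- binned |>
    dplyr::filter(.data$n > 0L, is.finite(.data$mean_r0), .data$mean_r0 > 0) |>
    dplyr::mutate(
      rb_rep = .data$bin_mid,
      r0 = .data$mean_r0,
      U_prime = avoidance_potential(.data$mean_r0, .data$bin_mid),
      negative = .data$U_prime < 0
    ) |>
    dplyr::select("class", "bin_lo", "bin_hi", "rb_rep", "r0", "U_prime",
                  "n", "negative")
  n_skipped <- sum(binned$n > 0L & (!is.finite(binned$mean_r0) | binned$mean_r0 <= 0))
  attr(pts, "n_skipped_zero_r0") <- n_skipped
  pts
}

fit_skeleton <- function(model, par_names) {
  list(model = model, params = stats::setNames(c(NA_real_, NA_real_), par_names),
       se = stats::setNames(c(NA_real_, NA_real_), par_names),
       residual_norm = NA_real_, n_points = 0L, n_excluded_negative = 0L,
       converged = FALSE, flag = "skipped")
}

run_nls <- function(df, formula, start, lower, par_names, model) {
  out <- fit_skeleton(model, par_names)
  out$n_points <- nrow(df)
  fit <- tryCatch(
    stats::nls(formula, data = df, start = start, algorithm = "port",
               lower = lower, control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out$params[] <- unlist(start)
    out$converged <- FALSE
    out$flag <- "non-convergent: log-linear initializer reported"
    return(out)
  }
  co <- summary(fit)$coefficients
  out$params[] <- co[par_names, "Estimate"]
  out$se[] <- co[par_names, "Std. Error"]
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$converged <- TRUE
  out$flag <- "ok"
  out
}

prepare_fit_points <- function(points, exclude_negative) {
  df <- tibble::tibble(r0 = points$r0, U = points$U_prime)
  df <- df[is.finite(df$r0) & is.finite(df$U) & df$r0 > 0, ]
  n_neg <- sum(df$U <= 0)
  if (exclude_negative) df <- df[df$U > 0, ]
  list(df = df, n_neg = n_neg)
}

#' Fit a power-law potential
#'
#' Nonlinear least squares of `U' ~ k / r0^beta`, initialized from a
#' log-log linear regression on the positive points. Points with
#' non-positive `U'` cannot be represented by this form and are excluded by
#' default (counted in the result).
#'
#' @param points A [potential_points()] tibble (columns `r0`, `U_prime`).
#' @param exclude_negative Drop points with `U' <= 0` before fitting.
#' @return List: `model`, `params` (`k`, `beta`), `se`, `residual_norm`,
#'   `n_points`, `n_excluded_negative`, `converged`, `flag`.
#' @export
fit_power_law <- function(points, exclude_negative = TRUE) {
  pp <- prepare_fit_points(points, exclude_negative)
  df <- pp$df
  out <- fit_skeleton("power", c("k", "beta"))
  out$n_excluded_negative <- pp$n_neg
  if (nrow(df) == 0L) {
    out$params[] <- c(0, NA_real_)
    out$flag <- "degenerate: no positive potential values"
    return(out)
  }
  if (nrow(df) < 3L) {
    out$n_points <- nrow(df)
    out$flag <- "skipped: fewer than 3 usable points"
    return(out)
  }
  init <- stats::lm(log(U) ~ log(r0), data = df)
  start <- list(k = unname(exp(stats::coef(init)[1L])),
                beta = max(unname(-stats::coef(init)[2L]), 1e-6))
  res <- run_nls(df, U ~ k / r0^beta, start, lower = c(k = 0, beta = 1e-6),
                 par_names = c("k", "beta"), model = "power")
  res$n_excluded_negative <- pp$n_neg
  if (is.na(res$residual_norm)) {
    res$residual_norm <- sqrt(sum((df$U - res$params["k"] / df$r0^res$params["beta"])^2))
  }
  res
}

#' Fit an exponential potential
#'
#' Nonlinear least squares of `U' ~ a * exp(-c * r0)`, initialized from a
#' log-linear regression on the positive points.
#'
#' @inheritParams fit_power_law
#' @return As [fit_power_law()], with parameters `a`, `c`.
#' @export
fit_exponential <- function(points, exclude_negative = TRUE) {
  pp <- prepare_fit_points(points, exclude_negative)
  df <- pp$df
  out <- fit_skeleton("exponential", c("a", "c"))
  out$n_excluded_negative <- pp$n_neg
  if (nrow(df) == 0L) {
    out$params[] <- c(0, NA_real_)
    out$flag <- "degenerate: no positive potential values"
    return(out)
  }
  if (nrow(df) < 3L) {
    out$n_points <- nrow(df)
    out$flag <- "skipped: fewer than 3 usable points"
    return(out)
  }
  init <- stats::lm(log(U) ~ r0, data = df)
  start <- list(a = unname(exp(stats::coef(init)[1L])),
                c = unname(-stats::coef(init)[2L]))
  res <- run_nls(df, U ~ a * exp(-c * r0), start,
                 lower = c(a = 0, c = -Inf),
                 par_names = c("a", "c"), model = "exponential")
  res$n_excluded_negative <- pp$n_neg
  if (is.na(res$residual_norm)) {
    res$residual_norm <- sqrt(sum((df$U - res$params["a"] * exp(-res$params["c"] * df$r0))^2))
  }
  res
}

fits_to_table <- function(fits, class_label, units) {
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      class = class_label, units = units, model = f$model,
      par_scale = unname(f$params[1L]), par_shape = unname(f$params[2L]),
      se_scale = unname(f$se[1L]), se_shape = unname(f$se[2L]),
      residual_norm = f$residual_norm, n_points = f$n_points,
      n_excluded_negative = f$n_excluded_negative,
      converged = f$converged, flag = f$flag
    )
  }))
}
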