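#' Social class specification for simulated dyads
#'
#' Describes one social class of dyads: its typical interpersonal distance
#' and the ground-truth group-individual repulsion `U(r) = k_true / r^beta_true`
#' driving collision avoidance in the simulator. `intrusion_propensity` is the
#' probability that an individual ignores the repulsion altogether and walks
#' straight through (modeling intrusions as force suppression).
#'
#' @param label Class label (e.g. `"couples"` or `"strong"`).
#' @param d Mean interpersonal distance of the dyad, meters.
#' @param d_sd Between-dyad standard deviation of the interpersonal distance,
#'   meters.
#' @param k_true Repulsion strength (dimensionless potential amplitude).
#' @param beta_true Repulsion exponent (> 0).
#' @param intrusion_propensity Probability in \[0, 1\] of suppressing the
#'   repulsion for a given encounter.
#' @return A list of class `"ped_class_spec"`.
#' @export
class_spec <- function(label, d = 0.75, d_sd = 0.10,
                       k_true = 1.0, beta_true = 2.0,
                       intrusion_propensity = 0.1) {
  if (d <= 0) ped_stop("interpersonal distance d must be > 0", "config_error")
  if (k_true < 0) ped_stop("k_true must be >= 0", "config_error")
  if (beta_true <= 0) ped_stop("beta_true must be > 0", "config_error")
  if (intrusion_propensity < 0 || intrusion_propensity > 1) {
    ped_stop("intrusion_propensity must be in [0, 1]", "config_error")
  }
  structure(list(
    label = as.character(label), d = d, d_sd = d_sd,
    k_true = k_true, beta_true = beta_true,
    intrusion_propensity = intrusion_propensity
  ), class = "ped_class_spec")
}

#' Default simulated class sets
#'
#' `"strength"` gives three classes differing only in repulsion strength
#' (weak/medium/strong, `k_true` = 0.3/1/3 at `beta_true` = 2), the cleanest
#' setting for parameter-recovery studies. `"relation"` mimics the
#' qualitative ordering reported for social relations: couples and friends
#' avoid more and are intruded on less than colleagues and families, and
#' family dyads walk less tightly abreast.
#'
#' @param scheme `"strength"` or `"relation"`.
#' @return Named list of [class_spec()] objects.
#' @export
default_class_specs <- function(scheme = c("strength", "relation")) {
  scheme <- match.arg(scheme)
  specs <- switch(scheme,
    strength = list(
      weak   = class_spec("weak",   d = 0.75, k_true = 0.3, beta_true = 2, intrusion_propensity = 0.1),
      medium = class_spec("medium", d = 0.75, k_true = 1.0, beta_true = 2, intrusion_propensity = 0.1),
      strong = class_spec("strong", d = 0.75, k_true = 3.0, beta_true = 2, intrusion_propensity = 0.1)
    ),
    relation = list(
      colleagues = class_spec("colleagues", d = 0.75, k_true = 0.6, beta_true = 2, intrusion_propensity = 0.25),
      couples    = class_spec("couples",    d = 0.65, k_true = 3.0, beta_true = 2, intrusion_propensity = 0.05),
      family     = class_spec("family",     d = 0.85, d_sd = 0.15, k_true = 0.6, beta_true = 2, intrusion_propensity = 0.30),
      friends    = class_spec("friends",    d = 0.70, k_true = 2.0, beta_true = 2, intrusion_propensity = 0.10)
    )
  )
  specs
}

#' Simulation scenario
#'
#' Geometry and sampling of the synthetic corridor. A dyad walks along `+x`
#' at the corridor center line; one individual approaches head-on from
#' `corridor_length / 2` meters ahead with a uniformly drawn lateral offset,
#' so straight-line distances span all bins from 0 to beyond the observation
#' window. Positions are recorded every `sampling_period` seconds with
#' isotropic Gaussian noise.
#'
#' @param corridor_length Total relative path length covered per encounter,
#'   meters.
#' @param corridor_width Corridor width (bounds lateral offsets), meters.
#' @param desired_speed_mean,desired_speed_sd Desired walking speed
#'   distribution, m/s.
#' @param lateral_offset_range Range (min, max) of the magnitude of the
#'   individual's lateral offset from the group path, meters.
#' @param sampling_period Recording interval, seconds.
#' @param position_noise_sd Gaussian position noise at sampling, meters.
#' @param n_encounters Number of encounters in a dataset.
#' @param class_mix Named numeric vector of class weights (normalized
#'   internally); `NULL` = equal weights over the supplied class specs.
#' @param relaxation_time Desired-velocity relaxation time of the social
#'   force model, seconds.
#' @param cohesion_strength Dyad cohesion spring constant, 1/s^2.
#' @param mobility_factor Fraction of the repulsion acceleration applied to
#'   the dyad (groups deviate less than individuals).
#' @param force_floor Minimum center-individual distance used in the force
#'   law, meters (numerical safety; below any analysis scale).
#' @return A list of class `"ped_scenario"`.
#' @export
sim_scenario <- function(corridor_length = 24,
                         corridor_width = 10,
                         desired_speed_mean = 1.2,
                         desired_speed_sd = 0.2,
                         lateral_offset_range = c(0, 5),
                         sampling_period = 0.05,
                         position_noise_sd = 0.005,
                         n_encounters = 100L,
                         class_mix = NULL,
                         relaxation_time = 0.5,
                         cohesion_strength = 5,
                         mobility_factor = 0.5,
                         force_floor = 0.05) {
  stopifnot(corridor_length > 0, corridor_width > 0, desired_speed_mean > 0,
            sampling_period > 0, position_noise_sd >= 0, n_encounters >= 1,
            relaxation_time > 0, cohesion_strength >= 0,
            mobility_factor >= 0, force_floor > 0)
  if (length(lateral_offset_range) != 2L ||
      lateral_offset_range[1] < 0 ||
      lateral_offset_range[2] <= lateral_offset_range[1]) {
    ped_stop("lateral_offset_range must be (min, max) with 0 <= min < max", "config_error")
  }
  structure(list(
    corridor_length = corridor_length, corridor_width = corridor_width,
    desired_speed_mean = desired_speed_mean, desired_speed_sd = desired_speed_sd,
    lateral_offset_range = lateral_offset_range,
    sampling_period = sampling_period, position_noise_sd = position_noise_sd,
    n_encounters = as.integer(n_encounters), class_mix = class_mix,
    relaxation_time = relaxation_time, cohesion_strength = cohesion_strength,
    mobility_factor = mobility_factor, force_floor = force_floor
  ), class = "ped_scenario")
}

# Truncated-normal draw kept away from zero (speeds, separations).
draw_positive <- function(mean, sd, floor) {
  max(stats::rnorm(1L, mean, sd), floor)
}

#' Simulate one group-individual encounter
#'
#' Integrates a minimal social-force model with fixed-step explicit Euler at
#' `sampling_period / 10` and downsamples to the recording grid: each agent
#' relaxes toward its desired velocity, the dyad members are bound by a
#' cohesion spring about their interpersonal distance, and a central
#' repulsion of magnitude `|dU/dr|` for `U(r) = k_true / r^beta_true` acts
#' between group center and individual (fully on the individual, with a
#' reduced mobility factor on the dyad). With probability
#' `intrusion_propensity` the repulsion is suppressed for the whole
#' encounter, modeling intrusions.
#'
#' @param spec A [class_spec()].
#' @param scenario A [sim_scenario()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param t0 Start time of the encounter, seconds.
#' @param id_prefix Prefix for pedestrian ids (members get `_m1`/`_m2`, the
#'   individual `_i`).
#' @param include_individual If `FALSE`, simulate the dyad alone (used to
#'   study the cohesion dynamics in isolation).
#' @return List with `trajectories` (tibble `time`, `id`, `x`, `y`) and
#'   `truth` (one-row tibble: class, d, k_true, beta_true, offset, intruded,
#'   speeds).
#' @export
simulate_encounter <- function(spec, scenario = sim_scenario(), seed = NULL,
                               t0 = 0, id_prefix = "e0001",
                               include_individual = TRUE) {
  stopifnot(inherits(spec, "ped_class_spec"), inherits(scenario, "ped_scenario"))
  if (!is.null(seed)) set.seed(seed)

  sep0 <- draw_positive(spec$d, spec$d_sd, 0.2)
  v_g <- draw_positive(scenario$desired_speed_mean, scenario$desired_speed_sd, 0.3)
  v_i <- draw_positive(scenario$desired_speed_mean, scenario$desired_speed_sd, 0.3)
  off_mag <- stats::runif(1L, scenario$lateral_offset_range[1],
                          min(scenario$lateral_offset_range[2], scenario$corridor_width / 2))
  side <- sample(c(-1, 1), 1L)
  offset <- side * off_mag
  intruded <- stats::runif(1L) < spec$intrusion_propensity

  dt_rec <- scenario$sampling_period
  dt <- dt_rec / 10
  duration <- scenario$corridor_length / (v_g + v_i)
  n_rec <- floor(duration / dt_rec)
  n_agents <- if (include_individual) 3L else 2L

  approach <- scenario$corridor_length / 2
  p <- rbind(
    c(0, sep0 / 2),
    c(0, -sep0 / 2),
    c(approach, offset)
  )[seq_len(n_agents), , drop = FALSE]
  v_des <- rbind(c(v_g, 0), c(v_g, 0), c(-v_i, 0))[seq_len(n_agents), , drop = FALSE]

  repel <- include_individual && !intruded && spec$k_true > 0
  rec <- tryCatch(
    integrate_encounter_cpp(
      p0 = p, v_des = v_des, dyad = TRUE, rest_sep = sep0,
      k_coh = scenario$cohesion_strength, repel = repel,
      k = spec$k_true, beta = spec$beta_true,
      mob = scenario$mobility_factor, tau = scenario$relaxation_time,
      floor_r = scenario$force_floor, dt = dt, n_rec = n_rec, substeps = 10L
    ),
    error = function(e) ped_stop(conditionMessage(e), "integration_error")
  )

  times <- t0 + dt_rec * (0:n_rec)
  if (scenario$position_noise_sd > 0) {
    rec <- rec + stats::rnorm(length(rec), 0, scenario$position_noise_sd)
  }
  ids <- paste0(id_prefix, c("_m1", "_m2", "_i"))[seq_len(n_agents)]
  trajectories <- tibble::tibble(
    time = rep(times, times = n_agents),
    id = rep(ids, each = n_rec + 1L),
    x = as.vector(rec[, seq_len(n_agents)]),
    y = as.vector(rec[, n_agents + seq_len(n_agents)])
  )
  truth <- tibble::tibble(
    encounter_id = id_prefix, class = spec$label,
    d = spec$d, k_true = spec$k_true, beta_true = spec$beta_true,
    offset = offset, intruded = intruded,
    separation0 = sep0,
    v_group = v_g, v_individual = if (include_individual) v_i else NA_real_,
    t_start = t0, duration = n_rec * dt_rec
  )
  list(trajectories = trajectories, truth = truth)
}

#' Simulate a full encounter dataset
#'
#' Concatenates `scenario$n_encounters` independent encounters (disjoint in
#' time, unique pedestrian ids) with class labels drawn from the scenario's
#' class mix.
#'
#' @param scenario A [sim_scenario()].
#' @param class_specs Named list of [class_spec()] objects (names are the
#'   class labels).
#' @param seed Integer seed; all draws flow from it.
#' @return List with `trajectories`, `annotations` (group_id, member ids,
#'   class_label) and `truth` (one row per encounter).
#' @export
simulate_dataset <- function(scenario = sim_scenario(),
                             class_specs = default_class_specs("strength"),
                             seed = 1L) {
  stopifnot(inherits(scenario, "ped_scenario"))
  if (length(class_specs) == 0L) ped_stop("empty class mix", "config_error")
  labels <- vapply(class_specs, function(s) s$label, character(1))
  names(class_specs) <- labels
  mix <- scenario$class_mix
  if (is.null(mix)) mix <- stats::setNames(rep(1, length(labels)), labels)
  if (!all(names(mix) %in% labels) || sum(mix) <= 0) {
    ped_stop("class_mix names must match class specs and weights must sum > 0", "config_error")
  }
  mix <- mix / sum(mix)
  set.seed(seed)
  n <- scenario$n_encounters
  drawn <- sample(names(mix), n, replace = TRUE, prob = mix)

  traj <- vector("list", n)
  truth <- vector("list", n)
  ann <- vector("list", n)
  t0 <- 0
  for (e in seq_len(n)) {
    idp <- sprintf("e%04d", e)
    enc <- simulate_encounter(class_specs[[drawn[e]]], scenario,
                              t0 = t0, id_prefix = idp)
    traj[[e]] <- enc$trajectories
    truth[[e]] <- enc$truth
    ann[[e]] <- tibble::tibble(
      group_id = idp,
      member_id_1 = paste0(idp, "_m1"),
      member_id_2 = paste0(idp, "_m2"),
      class_label = drawn[e]
    )
    t0 <- t0 + enc$truth$duration + 10
  }
  list(
    trajectories = dplyr::bind_rows(traj),
    annotations = dplyr::bind_rows(ann),
    truth = dplyr::bind_rows(truth)
  )
}

#' Simulate one individual-individual encounter
#'
#' Two lone pedestrians on opposing courses with a central repulsion
#' `U(r) = k_true / r^beta_true` acting symmetrically on both. Used to
#' exercise the individual-individual comparison pipeline with known ground
#' truth.
#'
#' @inheritParams simulate_encounter
#' @return As [simulate_encounter()], with ids `_a` and `_b`.
#' @export
simulate_individual_pair <- function(spec, scenario = sim_scenario(), seed = NULL,
                                     t0 = 0, id_prefix = "p0001") {
  stopifnot(inherits(spec, "ped_class_spec"), inherits(scenario, "ped_scenario"))
  if (!is.null(seed)) set.seed(seed)
  v_a <- draw_positive(scenario$desired_speed_mean, scenario$desired_speed_sd, 0.3)
  v_b <- draw_positive(scenario$desired_speed_mean, scenario$desired_speed_sd, 0.3)
  off_mag <- stats::runif(1L, scenario$lateral_offset_range[1],
                          min(scenario$lateral_offset_range[2], scenario$corridor_width / 2))
  offset <- sample(c(-1, 1), 1L) * off_mag
  intruded <- stats::runif(1L) < spec$intrusion_propensity

  dt_rec <- scenario$sampling_period
  dt <- dt_rec / 10
  duration <- scenario$corridor_length / (v_a + v_b)
  n_rec <- floor(duration / dt_rec)
  approach <- scenario$corridor_length / 2

  p <- rbind(c(0, 0), c(approach, offset))
  v_des <- rbind(c(v_a, 0), c(-v_b, 0))
  repel <- !intruded && spec$k_true > 0

  rec <- tryCatch(
    integrate_encounter_cpp(
      p0 = p, v_des = v_des, dyad = FALSE, rest_sep = 0, k_coh = 0,
      repel = repel, k = spec$k_true, beta = spec$beta_true,
      mob = 1, tau = scenario$relaxation_time,
      floor_r = scenario$force_floor, dt = dt, n_rec = n_rec, substeps = 10L
    ),
    error = function(e) ped_stop(conditionMessage(e), "integration_error")
  )
  times <- t0 + dt_rec * (0:n_rec)
  if (scenario$position_noise_sd > 0) {
    rec <- rec + stats::rnorm(length(rec), 0, scenario$position_noise_sd)
  }
  ids <- paste0(id_prefix, c("_a", "_b"))
  trajectories <- tibble::tibble(
    time = rep(times, times = 2L),
    id = rep(ids, each = n_rec + 1L),
    x = as.vector(rec[, 1:2]),
    y = as.vector(rec[, 3:4])
  )
  truth <- tibble::tibble(
    encounter_id = id_prefix, class = spec$label, d = NA_real_,
    k_true = spec$k_true, beta_true = spec$beta_true, offset = offset, intruded = intruded,
    separation0 = NA_real_, v_group = v_a, v_individual = v_b,
    t_start = t0, duration = n_rec * dt_rec
  )
  list(trajectories = trajectories, truth = truth)
}
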