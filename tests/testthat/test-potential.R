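test_that("the probed potential evaluator matches its closed form", {
  expect_equal(avoidance_potential(2, 2), 0)
  expect_equal(avoidance_potential(1, 0), 1)
  expect_equal(avoidance_potential(2, 1), 0.75)
  expect_true(is.na(avoidance_potential(0, 1)))
  # head-on limit is the only way to probe U' = 1; rb > 0 stays below it
  expect_true(all(avoidance_potential(seq(0.1, 5, by = 0.1), 0.05) < 1))
})

test_that("potential points come from non-empty bins with positive mean r0", {
  binned <- tibble::tibble(
    class = "c", bin_lo = c(0, 0.5, 1, 1.5), bin_hi = c(0.5, 1, 1.5, 2),
    bin_mid = c(0.25, 0.75, 1.25, 1.75),
    n = c(5L, 0L, 8L, 4L),
    mean_r0 = c(1.2, NA, 1.3, 1.5), sem_r0 = c(0.1, NA, 0.1, 0.2)
  )
  pts <- potential_points(binned)
  expect_equal(nrow(pts), 3L)  # the empty bin is dropped
  expect_equal(pts$U_prime, (pts$r0^2 - pts$rb_rep^2) / pts$r0^2)
  expect_equal(pts$negative, pts$U_prime < 0)
})

test_that("power-law fits are exact on noiseless data and flag degeneracy", {
  pts <- tibble::tibble(r0 = c(1, 2, 4), U_prime = 2 / c(1, 2, 4)^2)
  fit <- fit_power_law(pts)
  expect_equal(unname(fit$params["k"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit$params["beta"]), 2, tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-9)

  zero <- tibble::tibble(r0 = c(1, 2, 4), U_prime = c(0, 0, 0))
  fz <- fit_power_law(zero)
  expect_equal(unname(fz$params["k"]), 0)
  expect_match(fz$flag, "degenerate")

  two <- tibble::tibble(r0 = c(1, 2), U_prime = c(1, 0.5))
  expect_match(fit_power_law(two)$flag, "skipped")
})

test_that("power-law exponent is recovered under 1% noise (Monte Carlo)", {
  set.seed(11)
  r <- c(1, 1.5, 2, 3, 4)
  hits <- 0L
  for (i in 1:100) {
    u <- (2 / r^2) * (1 + stats::rnorm(length(r), 0, 0.01))
    f <- fit_power_law(tibble::tibble(r0 = r, U_prime = u))
    if (f$converged && f$params["beta"] > 1.8 && f$params["beta"] < 2.2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("exponential fits are exact and lose to the generating power law", {
  pts <- tibble::tibble(r0 = c(0.5, 1, 2), U_prime = exp(-c(0.5, 1, 2)))
  fe <- fit_exponential(pts)
  expect_equal(unname(fe$params["a"]), 1, tolerance = 1e-6)
  expect_equal(unname(fe$params["c"]), 1, tolerance = 1e-6)

  # model discrimination on power-law data (more points than parameters)
  r <- c(0.5, 1, 1.5, 2, 3, 4, 5)
  pl <- tibble::tibble(r0 = r, U_prime = 2 / r^2)
  expect_gt(fit_exponential(pl)$residual_norm,
            fit_power_law(pl)$residual_norm)

  expect_match(fit_exponential(pl[1, ])$flag, "skipped")
})

test_that("fits ignore point ordering", {
  set.seed(5)
  r <- c(0.8, 1.2, 1.7, 2.5, 3.5)
  pts <- tibble::tibble(r0 = r, U_prime = 1.5 / r^2.2 + stats::rnorm(5, 0, 0.01))
  f1 <- fit_power_law(pts)
  f2 <- fit_power_law(pts[sample(5), ])
  expect_equal(f1$params, f2$params, tolerance = 1e-9)
})

test_that("individual-individual encounters run through the meter pipeline", {
  spec <- class_spec("ii", k_true = 1.5, beta_true = 2,
                     intrusion_propensity = 0)
  sc <- sim_scenario(n_encounters = 1)
  set.seed(31)
  t0 <- 0
  traj <- list()
  for (e in 1:60) {
    enc <- simulate_individual_pair(spec, sc, t0 = t0,
                                    id_prefix = sprintf("p%04d", e))
    traj[[e]] <- enc$trajectories
    t0 <- t0 + enc$truth$duration + 10
  }
  traj <- dplyr::bind_rows(traj)
  res <- individual_individual_pipeline(traj, run_config())
  expect_s3_class(res, "ped_ii_analysis")
  expect_gt(nrow(res$observables), 30)
  # meters: scaled and metric columns coincide
  expect_equal(res$observables$rbar_0, res$observables$r_0)
  # probed potential decreases with distance: head bins above tail bins
  pts <- res$potential$points
  pts <- pts[order(pts$r0), ]
  expect_gt(mean(head(pts$U_prime, 3)), mean(tail(pts$U_prime, 3)))
})

test_that("swapping which individual is the target leaves r_0 and r_b unchanged", {
  a <- straight_traj("a", n = 200, x0 = 0, y0 = 0, vx = 1.2)
  b <- straight_traj("b", n = 200, x0 = 12, y0 = 1.1, vx = -1.2)
  mk_pseudo <- function(seg) {
    seg <- pedscatter:::ensure_velocity(seg)
    seg$separation <- NA_real_
    attr(seg, "group_id") <- seg$id[1]
    seg
  }
  cfg <- run_config()
  f_ab <- to_group_frame(mk_pseudo(a), b)
  f_ba <- to_group_frame(mk_pseudo(b), a)
  o_ab <- pedscatter:::encounter_observables(f_ab, W = 4)
  o_ba <- pedscatter:::encounter_observables(f_ba, W = 4)
  expect_equal(o_ab$r_0, o_ba$r_0, tolerance = 1e-9)
  expect_equal(o_ab$r_b, o_ba$r_b, tolerance = 1e-9)

  # straight-passing pair probes an essentially null potential
  expect_lt(abs(avoidance_potential(o_ab$r_0, o_ab$r_b)), 1e-9)
})

test_that("stronger simulated classes yield stronger fitted potentials", {
  specs <- list(
    weak = class_spec("weak", d = 0.75, k_true = 0.3, beta_true = 2,
                      intrusion_propensity = 0),
    strong = class_spec("strong", d = 0.75, k_true = 3, beta_true = 2,
                        intrusion_propensity = 0)
  )
  sc <- sim_scenario(n_encounters = 200)
  ds <- simulate_dataset(sc, specs, seed = 17)
  res <- run_pipeline(ds$trajectories, ds$annotations, run_config())
  # steeper-potential ordering: higher probed U' at small r0 ...
  pts <- res$potential$points
  u_small <- vapply(c("weak", "strong"), function(cl) {
    p <- pts[pts$class == cl, ]
    p <- p[order(p$r0), ]
    mean(head(p$U_prime, 3))
  }, numeric(1))
  expect_gt(u_small[["strong"]], u_small[["weak"]])
  # ... and a larger fitted strength coefficient
  pw <- res$potential$fits
  pw <- pw[pw$model == "power", ]
  expect_gt(pw$par_scale[pw$class == "strong"],
            pw$par_scale[pw$class == "weak"])
})
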