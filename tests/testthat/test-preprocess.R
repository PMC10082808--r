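test_that("atypical motion is removed and filtering is idempotent", {
  # standing still: speed 0 everywhere -> nothing survives
  still <- straight_traj("s", n = 60, vx = 0, vy = 0)
  expect_equal(nrow(filter_atypical(still)), 0L)

  # normal walk: one full segment
  walk <- straight_traj("w", n = 60, vx = 1.2)
  fw <- filter_atypical(walk)
  expect_equal(nrow(fw), 60L)
  expect_equal(length(unique(fw$segment_id)), 1L)

  # walk - stop - walk: two segments with a gap at the stop
  t <- 0.05 * (0:149)
  x <- c(1.2 * t[1:50],
         rep(1.2 * t[50], 50),
         1.2 * t[50] + 1.2 * (t[101:150] - t[101]))
  wsw <- tibble::tibble(time = t, id = "z", x = x, y = 0)
  fs <- filter_atypical(wsw)
  expect_equal(length(unique(fs$segment_id)), 2L)
  expect_lt(nrow(fs), 150L)

  # idempotence: velocities are carried, so refiltering changes nothing
  expect_identical(filter_atypical(fs), fs)
})

test_that("group tracks are midpoints with translation equivariance", {
  m1 <- straight_traj("m1", n = 20, x0 = 0, y0 = 1, vx = 1.2)
  m2 <- straight_traj("m2", n = 20, x0 = 0, y0 = -1, vx = 1.2)
  gt <- build_group_track(m1, m2, "g", "friends")
  expect_equal(gt$y, rep(0, 20))
  expect_equal(gt$separation, rep(2, 20))
  expect_equal(attr(gt, "class_label"), "friends")

  shift <- function(df) dplyr::mutate(df, x = x + 5, y = y + 5)
  gt2 <- build_group_track(shift(m1), shift(m2), "g", "friends")
  expect_equal(gt2$x, gt$x + 5)
  expect_equal(gt2$y, gt$y + 5)
  expect_equal(gt2$separation, gt$separation)

  # empty overlap -> skip signal
  late <- straight_traj("m2", n = 20, t0 = 100)
  expect_null(build_group_track(m1, late, "g", "friends"))
})

test_that("class interpersonal distance is the unweighted group mean", {
  g1 <- build_group_track(straight_traj("a", y0 = 0.4),
                          straight_traj("b", y0 = -0.4), "g1", "c")
  expect_equal(as.numeric(class_interpersonal_distance(list(g1), "c")), 0.8)

  g2 <- build_group_track(straight_traj("c", y0 = 0.3),
                          straight_traj("d", y0 = -0.3), "g2", "c")
  g3 <- build_group_track(straight_traj("e", y0 = 0.5),
                          straight_traj("f", y0 = -0.5), "g3", "c")
  d <- class_interpersonal_distance(list(g2, g3), "c")
  expect_equal(as.numeric(d), 0.8)
  expect_named(attr(d, "per_group"), c("g2", "g3"))
  expect_error(class_interpersonal_distance(list(g1), "missing"),
               class = "pedscatter_validation_error")
})

test_that("simulated dyads recover the generator interpersonal distance", {
  ds <- small_sim()
  filtered <- filter_atypical(ds$trajectories)
  ann <- ds$annotations
  per_group <- vapply(seq_len(nrow(ann)), function(i) {
    gt <- build_group_track(filtered[filtered$id == ann$member_id_1[i], ],
                            filtered[filtered$id == ann$member_id_2[i], ],
                            ann$group_id[i], ann$class_label[i])
    mean(gt$separation)
  }, numeric(1))
  # generator draws sep0 ~ N(d = 0.75, 0.1) per dyad
  sem <- 0.1 / sqrt(length(per_group))
  expect_lt(abs(mean(per_group) - 0.75), 4 * sem + 0.01)
})

test_that("frontal selection keeps opposing headings only", {
  gt <- build_group_track(straight_traj("m1", y0 = 0.4, n = 200),
                          straight_traj("m2", y0 = -0.4, n = 200), "g", "c")
  # co-moving individual: same heading, inside window -> excluded
  co <- straight_traj("co", n = 200, x0 = -1, y0 = 1, vx = 1.2)
  expect_equal(nrow(select_frontal_encounters(gt, co)), 0L)
  # exact head-on -> included with angle 180
  head_on <- straight_traj("ho", n = 200, x0 = 12, y0 = 0.5, vx = -1.2)
  sel <- select_frontal_encounters(gt, head_on)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$angle_at_entry, 180, tolerance = 1e-6)
  expect_false(sel$began_inside)
})

test_that("generator-intended frontal encounters are recalled", {
  spec <- class_spec("c", d = 0.75, d_sd = 0, k_true = 0.3,
                     intrusion_propensity = 0)
  sc <- sim_scenario(n_encounters = 20, position_noise_sd = 0)
  ds <- simulate_dataset(sc, list(c = spec), seed = 13)
  ex <- extract_encounters(ds$trajectories, ds$annotations, run_config())
  # every encounter whose lateral offset fits inside the window is found once
  expected <- ds$truth$encounter_id[abs(ds$truth$offset) < 3.5]
  found <- unique(sub("\\|.*", "", ex$observables$encounter_id))
  expect_true(all(expected %in% found))
  expect_equal(nrow(ex$observables), length(found))
})

test_that("the group frame maps the textbook example and preserves norms", {
  # group at (5,5) moving +y, individual at (5,6): frame position (1, 0)
  t5 <- 0:4 / 4
  gtrack <- tibble::tibble(time = t5, x = 5, y = 5 + t5,
                           vx = 0, vy = 1, separation = 1)
  attr(gtrack, "group_id") <- "g"
  ind <- tibble::tibble(time = t5, id = "i", x = 5, y = 6 + t5,
                        vx = 0, vy = 1)
  fr <- to_group_frame(gtrack, ind)
  expect_equal(fr$x[1], 1, tolerance = 1e-12)
  expect_equal(fr$y[1], 0, tolerance = 1e-12)

  # norms |r| and |v_i - v_g| are invariant under the transform
  ds <- small_sim()
  filtered <- filter_atypical(ds$trajectories)
  ann <- ds$annotations[1, ]
  gt <- build_group_track(filtered[filtered$id == ann$member_id_1, ],
                          filtered[filtered$id == ann$member_id_2, ],
                          ann$group_id, ann$class_label)
  iseg <- filtered[filtered$id == paste0(ann$group_id, "_i"), ]
  fr2 <- to_group_frame(gt, iseg)
  js <- pedscatter:::joint_series(gt, iseg)
  gspeed <- sqrt(js$gvx^2 + js$gvy^2)
  js <- js[gspeed > 1e-9, ]
  raw_r <- sqrt((js$ix - js$gx)^2 + (js$iy - js$gy)^2)
  raw_v <- sqrt((js$ivx - js$gvx)^2 + (js$ivy - js$gvy)^2)
  expect_equal(sqrt(fr2$x^2 + fr2$y^2), raw_r, tolerance = 1e-9)
  expect_equal(sqrt(fr2$vx^2 + fr2$vy^2), raw_v, tolerance = 1e-9)

  # stationary group throughout -> skip signal
  still <- tibble::tibble(time = t5, x = 0, y = 0, vx = 0, vy = 0,
                          separation = 1)
  expect_null(to_group_frame(still, ind))
})

test_that("group centers and r_b are equivariant under global rigid rotation", {
  ds <- small_sim()
  theta <- 0.7
  rot <- function(df) dplyr::mutate(df,
    x2 = cos(theta) * x - sin(theta) * y,
    y2 = sin(theta) * x + cos(theta) * y, x = x2, y = y2) |>
    dplyr::select(-x2, -y2)
  ex1 <- extract_encounters(ds$trajectories, ds$annotations, run_config())
  ex2 <- extract_encounters(rot(ds$trajectories), ds$annotations, run_config())
  o1 <- dplyr::arrange(ex1$observables, encounter_id)
  o2 <- dplyr::arrange(ex2$observables, encounter_id)
  shared <- intersect(o1$encounter_id, o2$encounter_id)
  # rotating the whole scene leaves every distance observable unchanged
  expect_gt(length(shared), 0.9 * nrow(o1))
  i1 <- match(shared, o1$encounter_id)
  i2 <- match(shared, o2$encounter_id)
  expect_equal(o1$r_b[i1], o2$r_b[i2], tolerance = 1e-9)
  expect_equal(o1$r_0[i1], o2$r_0[i2], tolerance = 1e-9)
})
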