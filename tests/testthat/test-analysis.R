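obs_tbl <- function(rb, r0, class = "c") {
  tibble::tibble(class = class, rbar_b = rb, rbar_0 = r0)
}

test_that("binning uses half-open 0.5-unit bins with mean and SEM", {
  b <- bin_pairs(obs_tbl(c(0.2, 0.4), c(1.0, 2.0)))
  first <- b[b$bin_lo == 0, ]
  expect_equal(first$n, 2L)
  expect_equal(first$mean_r0, 1.5)
  expect_equal(first$sem_r0, stats::sd(c(1, 2)) / sqrt(2))

  # a value exactly at an edge belongs to the upper bin
  b2 <- bin_pairs(obs_tbl(0.5, 1.0))
  expect_equal(b2$bin_lo[b2$n == 1L], 0.5)

  # empty bins are emitted with n = 0 and counts reconcile
  b3 <- bin_pairs(obs_tbl(c(0.1, 2.1), c(1, 2)))
  expect_true(any(b3$n == 0L))
  expect_equal(sum(b3$n), 2L)
})

test_that("per-bin counts across classes always sum to the total", {
  ds <- small_sim()
  res <- run_pipeline(ds$trajectories, ds$annotations, run_config())
  expect_equal(sum(res$binned$n), nrow(res$observables))
})

test_that("per-bin ANOVA matches the F distribution oracle", {
  # identical samples in both classes: F = 0, p = 1
  o <- obs_tbl(rep(0.2, 4), c(1, 2, 1, 2), class = c("a", "a", "b", "b"))
  a <- anova_per_bin(o)
  expect_equal(a$F, 0)
  expect_equal(a$p_value, 1)

  # hand-computed one-way ANOVA: groups {1,2,3} and {2,3,4}
  o2 <- obs_tbl(rep(0.1, 6), c(1, 2, 3, 2, 3, 4),
                class = rep(c("a", "b"), each = 3))
  a2 <- anova_per_bin(o2)
  # SSB = 1.5 (df 1), SSW = 4 (df 4) -> F = 1.5
  expect_equal(a2$F, 1.5, tolerance = 1e-12)
  expect_equal(a2$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # well-separated classes: overwhelming significance
  set.seed(1)
  o3 <- obs_tbl(rep(0.3, 100),
                c(stats::rnorm(50, 1, 0.1), stats::rnorm(50, 5, 0.1)),
                class = rep(c("a", "b"), each = 50))
  expect_lt(anova_per_bin(o3)$p_value, 1e-6)

  # single class -> missing with reason
  a4 <- anova_per_bin(obs_tbl(c(0.1, 0.2), c(1, 2)))
  expect_true(is.na(a4$p_value))
  expect_equal(a4$reason, "single class")
})

test_that("intrusion probabilities and Pearson chi-squared match hand values", {
  o <- obs_tbl(rep(0.2, 4), c(0.4, 0.8, 1.2, 1.6))
  it <- intrusion_table(o, thresholds = 1)
  expect_equal(it$probabilities$probability, 0.5)

  # identical intrusion patterns across classes: chi2 = 0, p = 1
  o2 <- obs_tbl(rep(0.2, 8), rep(c(0.5, 1.5), 4),
                class = rep(c("a", "b"), each = 4))
  t2 <- intrusion_table(o2, thresholds = 1)$tests
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_value, 1)

  # hand-built contingency table [[10,90],[40,60]]: chi2 = 24, df = 1
  r0_a <- c(rep(0.5, 10), rep(1.5, 90))
  r0_b <- c(rep(0.5, 40), rep(1.5, 60))
  o3 <- obs_tbl(rep(0.2, 200), c(r0_a, r0_b),
                class = rep(c("a", "b"), each = 100))
  t3 <- intrusion_table(o3, thresholds = 1)$tests
  expect_equal(t3$statistic, 24, tolerance = 1e-12)
  expect_equal(t3$df, 1)
  expect_equal(t3$p_value, stats::pchisq(24, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(t3$unreliable)
})

test_that("intrusion probability is monotone non-increasing in the threshold", {
  set.seed(2)
  o <- obs_tbl(stats::runif(300, 0, 3), stats::runif(300, 0, 3),
               class = sample(c("a", "b"), 300, TRUE))
  it <- intrusion_table(o, thresholds = c(1.0, 0.5))
  p <- it$probabilities
  wide <- tidyr::pivot_wider(p[, c("threshold", "class", "bin_lo", "probability")],
                             names_from = "threshold",
                             values_from = "probability")
  expect_true(all(wide[["0.5"]] <= wide[["1"]] + 1e-12))
  expect_true(all(p$probability >= 0 & p$probability <= 1))
})

test_that("the linear r_b calibration recovers environment bias", {
  set.seed(3)
  rb <- stats::runif(200, 0, 6)
  # ideal environment: identity correction
  ideal <- rb_linear_correction(obs_tbl(rb, rb))
  expect_equal(ideal$slope, 1, tolerance = 1e-9)
  expect_equal(ideal$intercept, 0, tolerance = 1e-9)
  expect_true(ideal$applied)

  # constructed bias r0 = 0.9 rb: corrected values shrink by 0.9
  biased <- rb_linear_correction(obs_tbl(rb, 0.9 * rb))
  expect_equal(biased$slope, 0.9, tolerance = 1e-9)
  expect_equal(biased$observables$rbar_b_corrected, 0.9 * rb,
               tolerance = 1e-9)

  # avoidance at small rb is left intact: calibration only sees rb >= 2
  r0 <- ifelse(rb < 1, pmax(rb, 1), rb)
  mixed <- rb_linear_correction(obs_tbl(rb, r0))
  expect_equal(mixed$slope, 1, tolerance = 1e-9)

  # too few calibration points: warning and identity
  expect_warning(
    few <- rb_linear_correction(obs_tbl(c(0.1, 0.2), c(0.1, 0.2))),
    "uncorrected"
  )
  expect_false(few$applied)
})

test_that("density maps normalize and relative maps cancel cell-wise", {
  one <- tibble::tibble(x = 0.31, y = -0.22)
  m <- density_map(one, cell = 0.1, half_width = 1)
  expect_equal(max(m$z), 1)
  expect_equal(sum(m$z == 1), 1L)
  expect_equal(sum(m$z != 0), 1L)

  set.seed(4)
  pos <- tibble::tibble(x = stats::runif(900, -3, 3),
                        y = stats::runif(900, -3, 3),
                        class = sample(c("a", "b", "c"), 900, TRUE))
  rel <- density_map(pos, cell = 0.5, half_width = 3, mode = "relative")
  total <- Reduce(`+`, lapply(rel, function(m) m$z))
  expect_lt(max(abs(total)), 1e-12)
  # each relative map is a probability difference: cells sum to ~0 too
  expect_lt(abs(sum(rel$a$z)), 1e-9)

  expect_error(density_map(one[0, ]), class = "pedscatter_validation_error")
  expect_error(density_map(one, mode = "relative"),
               class = "pedscatter_format_error")
})
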