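test_that("calibration hits the landmark targets to 1e-3 (grid oracle)", {
  for (cv in list(girls_curve(), boys_curve())) {
    tg <- if (cv$s == 1.2) girls_targets else boys_targets
    # independent oracle: dense grid search on the velocity curve
    grid <- seq(6, 20, by = 1e-4)
    v <- reference_velocity(cv, grid)
    interior_max <- which(diff(sign(diff(v))) < 0) + 1
    pk <- interior_max[which.max(v[interior_max])]
    expect_equal(grid[pk], tg[["aphv"]], tolerance = 2e-3)
    expect_equal(v[pk], tg[["phv"]], tolerance = 2e-3)
    interior_min <- which(diff(sign(diff(v))) > 0) + 1
    to <- max(interior_min[grid[interior_min] < grid[pk]])
    expect_equal(grid[to], tg[["atgv"]], tolerance = 2e-3)
    expect_equal(v[to], tg[["tgv"]], tolerance = 2e-3)
    # velocity stays positive and height strictly increases
    expect_true(all(v > 0))
    expect_true(all(diff(reference_height(cv, grid)) > 0))
  }
})

test_that("calibration rejects mis-ordered targets and is deterministic", {
  bad <- girls_targets; bad["tgv"] <- bad[["phv"]]
  expect_error(calibrate_reference(bad), class = "sitargrowth_config_error")
  bad2 <- girls_targets; bad2["atgv"] <- 12.5
  expect_error(calibrate_reference(bad2), class = "sitargrowth_config_error")
  cv1 <- calibrate_reference(girls_targets)
  cv2 <- calibrate_reference(girls_targets)
  expect_identical(cv1[c("c", "lambda", "A", "mu")],
                   cv2[c("c", "lambda", "A", "mu")])
})

test_that("true landmarks transform in closed form under the effects", {
  cv <- girls_curve()
  lm0 <- truth_landmarks(cv, c(alpha = 0, zeta = 0, gamma = 0))
  expect_equal(lm0$aphv, girls_targets[["aphv"]], tolerance = 1e-3)
  expect_equal(lm0$phv, girls_targets[["phv"]], tolerance = 1e-3)
  # a pure timing shift moves both ages by exactly +1
  lm1 <- truth_landmarks(cv, c(alpha = 0, zeta = 1, gamma = 0))
  expect_equal(lm1$aphv, lm0$aphv + 1, tolerance = 1e-12)
  expect_equal(lm1$atgv, lm0$atgv + 1, tolerance = 1e-12)
  expect_equal(lm1$phv, lm0$phv, tolerance = 1e-12)
  # intensity scaling against a numeric search oracle
  set.seed(19)
  for (k in 1:5) {
    ef <- c(alpha = rnorm(1, 0, 2), zeta = rnorm(1, 0, 0.7),
            gamma = rnorm(1, 0, 0.08))
    lm <- truth_landmarks(cv, ef)
    vf <- function(t) {
      w <- cv$mu + (t - cv$mu - ef[["zeta"]]) * exp(-ef[["gamma"]])
      reference_velocity(cv, w) * exp(-ef[["gamma"]])
    }
    pk <- find_peak(vf, c(7, 18))
    expect_equal(lm$aphv, pk$age, tolerance = 1e-6)
    expect_equal(lm$phv, pk$velocity, tolerance = 1e-6)
    expect_equal(lm$phv, girls_curve()$landmarks$phv * exp(-ef[["gamma"]]),
                 tolerance = 1e-6)
  }
})

test_that("a degenerate generator reproduces the reference curve exactly", {
  cv <- girls_curve()
  cfg <- generator_config(n_subjects = 5, sex = "F", seed = 1,
                          age_jitter_sd = 0, retention = 1,
                          sd_alpha = 0, sd_zeta = 0, sd_gamma = 0,
                          residual_sd = 0)
  sim <- simulate_cohort(cv, cfg)
  expect_equal(sim$cohort$stature, reference_height(cv, sim$cohort$age),
               tolerance = 1e-10)
  # noise-free heights are strictly increasing within subject
  for (i in unique(sim$cohort$id))
    expect_true(all(diff(sim$cohort$stature[sim$cohort$id == i]) > 0))
})

test_that("the generator is reproducible byte-for-byte from its seed", {
  cv <- girls_curve()
  cfg <- generator_config(n_subjects = 30, sex = "F", seed = 123)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(simulate_cohort(cv, cfg)$cohort, f1)
  write_long_csv(simulate_cohort(cv, cfg)$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("individual APHV spread matches the delta-method propagation", {
  cv <- girls_curve()
  cfg <- generator_config(n_subjects = 500, sex = "F", seed = 33)
  sim <- simulate_cohort(cv, cfg)
  tr <- sim$truth
  # APHV_i = mu + zeta_i + (aphv - mu) e^{gamma_i}: to first order its
  # variance is sd_zeta^2 + d^2 sd_gamma^2 + 2 d cov(zeta, gamma),
  # d = aphv - mu
  d <- tr$population_landmarks$aphv - cv$mu
  cov_zg <- 0.3 * cfg$sd_zeta * cfg$sd_gamma
  v_theory <- cfg$sd_zeta^2 + d^2 * cfg$sd_gamma^2 + 2 * d * cov_zg
  v_mc <- var(tr$subject_landmarks$aphv)
  expect_lt(abs(v_mc - v_theory) / v_theory, 0.10)
})

test_that("default dropout keeps counts in 4-11 and survives inclusion", {
  # the >= 90% retention claim is a rate of the generator, so it is
  # tested on the pooled subjects across seeds rather than per draw
  kept_total <- 0
  for (seed in c(11, 12, 55)) {
    sim <- simulate_cohort(girls_curve(),
                           generator_config(n_subjects = 100, sex = "F", seed = seed))
    counts <- table(sim$cohort$id)
    expect_true(all(counts >= 4 & counts <= 11))
    kept <- apply_inclusion_filter(sim$cohort)$cohort
    kept_total <- kept_total + length(unique(kept$id))
  }
  expect_gte(kept_total / 300, 0.9)
})

test_that("the truth ledger round-trips through JSON", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$curve$mu, sim$truth$curve$mu, tolerance = 1e-12)
  expect_equal(back$population_landmarks$aphv,
               sim$truth$population_landmarks$aphv, tolerance = 1e-12)
  expect_equal(nrow(back$effects), 24)
})
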