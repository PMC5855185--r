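test_that("degenerate models give the expected sensitivities", {
  m <- make_model(1:3, theta1 = c(2, 0, 0), theta2 = c(0.1, 0, 0))
  prof <- simulate_sensitivity(m, 1000, seed = 1)
  expect_equal(prof$raw[2:3], c(0, 0))
  expect_equal(prof$normalized, c(1, 0, 0))

  m0 <- make_model(1:4, theta1 = rep(0, 4), theta2 = rep(0, 4))
  expect_warning(p0 <- simulate_sensitivity(m0, 1000, seed = 1), "all-zero")
  expect_equal(p0$normalized, rep(0.25, 4))
})

test_that("Monte Carlo sensitivity converges to the closed-form variance", {
  grid <- list(c(2, 0), c(0, 0.3), c(1, 0.02), c(5, 0.5))
  for (i in seq_along(grid)) {
    a <- grid[[i]][1]; b <- grid[[i]][2]
    m <- make_model(1, theta1 = a, theta2 = b)
    prof <- simulate_sensitivity(m, 1e5, seed = 100 + i)
    v <- prof$raw[1]
    # Monte Carlo standard error of the variance estimator from the
    # sampled central moments: sqrt((mu4 - v^2) / n)
    mu4 <- prof$m4[1] - 4 * prof$m3[1] * prof$m1[1] +
      6 * prof$m2[1] * prof$m1[1]^2 - 3 * prof$m1[1]^4
    se <- sqrt((mu4 - v^2) / prof$n_random)
    expect_lt(abs(v - closed_form_sensitivity(a, b)), 3 * se)
  }
})

test_that("per-scale sensitivities conserve the additive output variance", {
  set.seed(9)
  m <- make_model(1:10, theta1 = runif(10, -1, 2), theta2 = runif(10, -0.02, 0.05))
  prof <- simulate_sensitivity(m, 2e4, seed = 5)
  expect_lt(abs(sum(prof$raw) - additive_output_variance(prof)), 1e-9)
  expect_lt(abs(sum(prof$normalized) - 1), 1e-9)
})

test_that("identical seeds reproduce profiles exactly", {
  m <- make_model(1:3, theta1 = c(1, 2, 3), theta2 = c(0.1, 0, 0.05))
  p1 <- simulate_sensitivity(m, 5e4, seed = 77)
  p2 <- simulate_sensitivity(m, 5e4, seed = 77)
  expect_identical(p1, p2)
})

test_that("convergence experiment obeys the difference algebra", {
  m <- make_model(1:5, theta1 = c(2, 1, 0.5, 3, 0.1),
                  theta2 = c(0.05, 0, 0.2, 0.01, 0))
  cv <- convergence_experiment(m, r_max = 5000, step = 100, seed = 13)
  expect_equal(cv$grid, seq(100, 5000, by = 100))
  expect_equal(dim(cv$d), c(49, 5))
  expect_true(all(cv$d >= 0))
  expect_equal(cv$d_integration, rowSums(cv$d))       # Eq-style conservation
  expect_equal(cv$d, abs(diff(cv$y)), ignore_attr = TRUE)
  expect_true(cv$chosen_n %in% cv$grid)

  # sensitivity estimates stabilize as the draw count grows
  cv2 <- convergence_experiment(m, r_max = 2e4, step = 100, seed = 14)
  k <- length(cv2$d_integration)
  tenth <- floor(k / 10)
  expect_gt(mean(cv2$d_integration[1:tenth]),
            mean(cv2$d_integration[(k - tenth + 1):k]))
})

test_that("per-minute pipeline yields one profile per segment, reproducibly", {
  cfg <- generator_config(duration_s = 120, task = "analysis",
                          channels = "emg", seed = 19)
  ds <- generate_dataset(cfg)
  norm <- normalize_mvc(ds$recording, ds$calibration)
  prof <- sensitivity_pipeline(norm, "emg", n_random = 5000, seed = 3)
  expect_length(prof, 2)
  expect_equal(prof[[1]]$segment_id, 1)
  expect_equal(prof[[2]]$segment_id, 2)

  prof2 <- sensitivity_pipeline(norm, "emg", n_random = 5000, seed = 3)
  expect_identical(lapply(prof, `[[`, "normalized"),
                   lapply(prof2, `[[`, "normalized"))

  # degenerate (zero-signal) segments are excluded with a message
  rec0 <- recording(cbind(emg = numeric(120 * 1000)),
                    force = rep(30, 120 * 1000), fs = 1000, normalized = TRUE)
  expect_message(p0 <- sensitivity_pipeline(rec0, "emg", n_random = 1000),
                 "degenerate")
  expect_length(p0, 0)
})

test_that("aggregation averages normalized profiles", {
  p1 <- structure(list(scales = 1:2, normalized = c(0.2, 0.8)),
                  class = "sensitivity_profile")
  p2 <- structure(list(scales = 1:2, normalized = c(0.4, 0.6)),
                  class = "sensitivity_profile")
  expect_equal(unname(aggregate_sensitivity(list(p1, p2))), c(0.3, 0.7))
  expect_equal(unname(aggregate_sensitivity(list(p1))), c(0.2, 0.8))
  expect_equal(sum(aggregate_sensitivity(list(p1, p2))), 1)

  p3 <- structure(list(scales = 2:3, normalized = c(0.5, 0.5)),
                  class = "sensitivity_profile")
  expect_error(aggregate_sensitivity(list(p1, p3)), "inconsistent")
})

test_that("noise-dominated scales draw higher sensitivity than force-coupled ones", {
  wins <- 0
  for (seed in 1:10) {
    cfg <- generator_config(duration_s = 120, task = "analysis",
                            drift_rate = 0.1, seed = seed)
    ds <- generate_dataset(cfg)
    norm <- normalize_mvc(ds$recording, ds$calibration)
    prof <- sensitivity_pipeline(norm, "emg", n_random = 2e4, seed = seed)
    ms <- aggregate_sensitivity(prof)
    coupled <- ds$truth$coupled_scales
    if (mean(ms[-coupled]) > mean(ms[coupled])) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
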