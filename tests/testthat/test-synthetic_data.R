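test_that("force profiles respect their task definitions", {
  cfg_s <- generator_config(duration_s = 30, task = "static",
                            static_level = 30, seed = 2)
  f_s <- generate_force_profile(cfg_s)
  expect_equal(mean(f_s), 30, tolerance = 1)
  expect_true(all(abs(f_s - 30) <= 2 + 1e-9))

  cfg_v <- generator_config(duration_s = 120, task = "force_varying", seed = 3)
  f_v <- generate_force_profile(cfg_v)
  expect_gte(min(f_v), 0)
  expect_lte(max(f_v), 80)
  expect_identical(f_v, generate_force_profile(cfg_v))  # seeded determinism

  cfg_a <- generator_config(duration_s = 120, task = "analysis", seed = 4)
  f_a <- generate_force_profile(cfg_a)
  expect_gte(min(f_a), 0)
  # per-minute peaks increase across the task
  m1 <- max(f_a[1:60000]); m2 <- max(f_a[60001:120000])
  expect_gt(m2, m1)

  expect_error(generator_config(task = "nonsense"))
})

test_that("synthesized SEMG is zero without sources and homogeneous in gain", {
  bd0 <- default_band_defs()
  bd0$g1 <- 0; bd0$g2 <- 0; bd0$base <- 0
  cfg0 <- generator_config(duration_s = 5, band_defs = bd0, noise_sd = 0,
                           seed = 6)
  expect_equal(synthesize_semg(rep(0, 5000), cfg0), rep(0, 5000))

  cfg1 <- generator_config(duration_s = 10, noise_sd = 0, seed = 7)
  bd2 <- default_band_defs(g1 = 2 * 0.01, g2 = 2 * 2e-5, base_amp = 2 * 0.05)
  cfg2 <- generator_config(duration_s = 10, band_defs = bd2, noise_sd = 0,
                           seed = 7)
  force <- rep(40, 10000)
  set.seed(7); x1 <- synthesize_semg(force, cfg1)
  set.seed(7); x2 <- synthesize_semg(force, cfg2)
  expect_lt(abs(sqrt(mean(x2^2)) / sqrt(mean(x1^2)) - 2), 0.02)
})

test_that("force-coupled band power grows with the force level", {
  bd <- default_band_defs()
  for (seed in 1:5) {
    pw <- vapply(c(10, 40, 70), function(lv) {
      cfg <- generator_config(duration_s = 20, task = "static",
                              static_level = lv, seed = seed)
      ds <- generate_dataset(cfg)
      b <- bandpass_filter(ds$recording$emg[, 1], 1000,
                           low = bd$low[3], high = bd$high[3])
      mean(b^2)
    }, numeric(1))
    expect_true(all(diff(pw) > 0))
  }
})

test_that("band intensities correlate with force only for coupled bands", {
  cfg <- generator_config(duration_s = 600, task = "force_varying", seed = 12)
  ds <- generate_dataset(cfg)
  expect_equal(n_samples(ds$recording), 600000)
  expect_equal(ds$truth$coupled_scales, 1:5)

  bd <- ds$truth$band_defs
  force_k <- colMeans(matrix(ds$truth$force_pct, nrow = 200))
  for (p in c(2, 4, 7, 10)) {
    b <- bandpass_filter(ds$recording$emg[, 1], 1000,
                         low = bd$low[p], high = bd$high[p])
    r <- cor(force_k, rms_envelope(b, 200))
    if (p %in% ds$truth$coupled_scales) {
      expect_gt(r, 0.5)
    } else {
      expect_lt(abs(r), 0.1)
    }
  }
})

test_that("datasets round-trip through CSV and carry a consistent calibration", {
  cfg <- generator_config(duration_s = 5, seed = 14)
  ds <- generate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(ds$recording, path)
  back <- read_recording(path, schema = list(emg = "emg", force = "force"),
                         fs = 1000)
  expect_equal(back$emg, ds$recording$emg, tolerance = 1e-10)
  expect_equal(back$force, ds$recording$force, tolerance = 1e-10)

  norm <- normalize_mvc(ds$recording, ds$calibration)
  expect_equal(norm$force, ds$truth$force_pct, tolerance = 1e-10)
  expect_lte(max(abs(norm$emg)), 1 + 1e-12)
})

test_that("drift-free end-to-end estimation is accurate with all ten scales", {
  res <- synthetic_force_study(seed = 42, duration_s = 180, n_random = 2e4)
  expect_lt(res$rmse_full, 5)
  expect_lt(res$rmse_selected, 5)
})
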