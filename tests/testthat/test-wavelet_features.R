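test_that("sampled db2 wavelet has the defining analytic properties", {
  tab <- db2_psi(10)
  dx <- 2^-10
  expect_lt(abs(sum(tab$psi) * dx), 1e-12)          # zero mean
  expect_lt(abs(sum(tab$x * tab$psi) * dx), 1e-12)  # vanishing first moment
  expect_equal(sum(tab$psi^2) * dx, 1, tolerance = 1e-3)  # unit energy
  expect_equal(range(tab$x), c(0, 3))               # compact support
})

test_that("cwt_db2 matches the literal double-sum on short signals", {
  expect_equal(cwt_db2(numeric(64), scales = 1:10)$c,
               matrix(0, 64, 10), ignore_attr = TRUE)

  # unit impulse: coefficient row is the sampled wavelet
  x <- numeric(101); x[51] <- 1
  for (p in c(2, 5)) {
    cw <- cwt_db2(x, scales = p)
    expect_lt(max(abs(cw$c[, 1] - brute_cwt(x, p))), 1e-10)
  }

  set.seed(3)
  x <- rnorm(256)
  for (en in c(TRUE, FALSE)) {
    cw <- cwt_db2(x, scales = c(1, 3, 7, 10), energy_norm = en)
    for (j in seq_along(cw$scales)) {
      expect_lt(max(abs(cw$c[, j] - brute_cwt(x, cw$scales[j], en))), 1e-8)
    }
  }

  expect_error(cwt_db2(numeric(0)), "empty")
  expect_error(cwt_db2(rnorm(10), scales = 0.5), "positive integers")
})

test_that("the wavelet acts as a matched filter for its own shape", {
  p <- 3
  w <- db2_kernel(p, energy_norm = FALSE)
  x <- numeric(200)
  at <- 80
  x[at + seq_along(w) - 1] <- w
  cw <- cwt_db2(x, scales = p, energy_norm = FALSE)
  ctr <- (3 * p) %/% 2
  expect_equal(which.max(abs(cw$c[, 1])), at + ctr)
})

test_that("pseudo-frequency mapping is the printed inverse-scale relation", {
  expect_equal(round(pseudo_frequency(5), 2), 145.45)
  expect_equal(round(pseudo_frequency(4), 2), 181.82)
  expect_equal(pseudo_frequency(10), 72.73, tolerance = 0.01)
  f <- pseudo_frequency(1:10)
  expect_true(all(diff(f) < 0))
  expect_equal(f * (1:10), rep(727.27, 10))
  expect_error(pseudo_frequency(0), ">= 1")
})

test_that("RMS intensity reduces frames correctly", {
  cw <- structure(list(c = matrix(2, 40, 2, dimnames = list(NULL, c("s1", "s2"))),
                       scales = 1:2, fs = 100, energy_norm = TRUE),
                  class = "cwt_coefficients")
  e <- rms_intensity(cw, 10)
  expect_equal(dim(e$e), c(4, 2))
  expect_true(all(e$e == 2))
  expect_equal(e$frame_rate, 10)

  cw$c[1:2, 1] <- c(3, 4)
  e2 <- rms_intensity(cw, 2)
  expect_equal(unname(e2$e[1, 1]), sqrt(12.5), tolerance = 1e-12)

  cw$c[] <- 0
  expect_true(all(rms_intensity(cw, 5)$e == 0))
  expect_error(rms_intensity(cw, 100), "exceeds")
  # K = floor(N / M): trailing partial frame dropped
  expect_equal(nrow(rms_intensity(cw, 7)$e), 5)
})

test_that("moving-average smoothing shrinks at the edges", {
  e <- make_feats(matrix(5, 20, 1), frame_rate = 5)
  expect_equal(smooth_moving_average(e, 600)$e, e$e)    # constant unchanged
  expect_equal(smooth_moving_average(e, 200)$e, e$e)    # w = 1 identity

  e2 <- make_feats(matrix(c(0, 3, 0), 3, 1), frame_rate = 15)
  sm <- smooth_moving_average(e2, 200)  # w = 3 at 15 frames/s
  expect_equal(as.numeric(sm$e), c(1.5, 1.0, 1.5))
})

test_that("extract_features aligns intensities and force at frame rate", {
  set.seed(7)
  n <- 60 * 1000
  rec <- recording(cbind(emg = rnorm(n, sd = 0.1)), force = runif(n, 0, 80),
                   fs = 1000, normalized = TRUE)
  fx <- extract_features(rec, "emg")
  expect_equal(dim(fx$features$e), c(300, 10))
  expect_length(fx$force, 300)

  rec0 <- recording(cbind(emg = numeric(2000)), force = runif(2000, 0, 80),
                    fs = 1000, normalized = TRUE)
  expect_true(all(extract_features(rec0, "emg")$features$e == 0))

  # positive homogeneity: doubling the signal doubles every intensity
  rec2 <- rec
  rec2$emg <- rec2$emg * 2
  fx2 <- extract_features(rec2, "emg")
  expect_equal(fx2$features$e, 2 * fx$features$e, tolerance = 1e-12)
})
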