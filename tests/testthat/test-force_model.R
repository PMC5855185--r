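test_that("OLS recovers generating coefficients on noiseless data", {
  set.seed(21)
  e <- matrix(runif(100, 0, 5), 50, 2)
  feats <- make_feats(e)
  force <- 2 * e[, 1] + 0.5 * e[, 1]^2 + 1.2 * e[, 2] + 0.05 * e[, 2]^2
  m <- fit_polynomial_model(feats, force)
  expect_equal(m$theta1, c(2, 1.2), tolerance = 1e-8)
  expect_equal(m$theta2, c(0.5, 0.05), tolerance = 1e-8)

  m0 <- fit_polynomial_model(feats, rep(0, 50))
  expect_true(all(abs(c(m0$theta1, m0$theta2)) < 1e-12))

  expect_error(fit_polynomial_model(feats, force, scales = integer(0)),
               "empty scale set")
  expect_error(fit_polynomial_model(feats, c(force[-1], NA)), "non-finite")
  expect_error(fit_polynomial_model(feats, force[-1]), "length")
})

test_that("coefficient error shrinks with sample size under noise", {
  theta <- c(2, 0.5)
  err_at <- function(n, reps = 20) {
    mean(vapply(seq_len(reps), function(r) {
      e <- matrix(runif(n, 0, 10), n, 1)
      force <- theta[1] * e[, 1] + theta[2] * e[, 1]^2 + rnorm(n)
      m <- fit_polynomial_model(make_feats(e), force)
      abs(m$theta1 - theta[1]) + abs(m$theta2 - theta[2])
    }, numeric(1)))
  }
  set.seed(31)
  expect_lt(err_at(500), err_at(50))
})

test_that("prediction evaluates the polynomial exactly and checks scales", {
  feats <- make_feats(matrix(c(10, 20), 2, 1))
  m_id <- make_model(1, theta1 = 1, theta2 = 0)
  expect_equal(predict_force(m_id, feats), c(10, 20))

  feats4 <- make_feats(matrix(4, 1, 1))
  m <- make_model(1, theta1 = 2, theta2 = 0.5)
  expect_equal(predict_force(m, feats4), 16)

  expect_equal(predict_force(m, make_feats(matrix(0, 5, 1))), rep(0, 5))

  m2 <- make_model(2, 1, 0)
  expect_error(predict_force(m2, feats), "lacks scale column")

  big <- make_model(1, 10, 1)
  expect_equal(predict_force(big, feats4, clip = TRUE), 56)
  expect_equal(predict_force(big, make_feats(matrix(20, 1, 1)), clip = TRUE),
               100)
})

test_that("rmse matches hand arithmetic and is symmetric", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(c(3, 4), c(0, 0)), rmse(c(0, 0), c(3, 4)))
  expect_error(rmse(1:3, 1:4), "equal length")

  wr <- windowed_rmse(rep(0, 10), rep(2, 10), width = 5)
  expect_equal(wr, c(2, 2))
})

test_that("training fit never loses to the zero predictor", {
  set.seed(41)
  for (r in 1:5) {
    e <- matrix(runif(60, 0, 5), 30, 2)
    force <- runif(30, 0, 80)
    feats <- make_feats(e)
    m <- fit_polynomial_model(feats, force)
    expect_lte(rmse(force, predict_force(m, feats)),
               rmse(force, rep(0, 30)) + 1e-12)
  }
})

test_that("rank-deficient designs warn and fall back to minimum norm", {
  e <- matrix(1, 30, 1)   # constant column: e and e^2 collinear
  force <- runif(30, 0, 80)
  expect_warning(m <- fit_polynomial_model(make_feats(e), force),
                 "rank-deficient")
  expect_true(all(is.finite(predict_force(m, make_feats(e)))))
})

test_that("models serialize to JSON and back", {
  m <- make_model(c(2, 3), theta1 = c(1.5, -0.2), theta2 = c(0.01, 0.3))
  path <- withr::local_tempfile(fileext = ".json")
  write_force_model(m, path)
  back <- read_force_model(path)
  expect_equal(back$scales, m$scales)
  expect_equal(back$theta1, m$theta1)
  expect_equal(back$theta2, m$theta2)
})
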