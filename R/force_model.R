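polynomial_design <- function(e, scales, intercept = FALSE) {
  cols <- paste0("s", scales)
  missing_cols <- setdiff(cols, colnames(e))
  if (length(missing_cols)) {
    stop("feature matrix lacks scale column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- cbind(e[, cols, drop = FALSE], e[, cols, drop = FALSE]^2)
  colnames(X) <- c(paste0("lin_", cols), paste0("quad_", cols))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

# Minimum-norm least squares via SVD; warns when the design is
# rank-deficient (e.g. a near-constant intensity column makes the linear
# and quadratic terms collinear).
minnorm_lsfit <- function(X, y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (r < ncol(X)) {
    warning(sprintf(
      "rank-deficient design (rank %d of %d columns); using the minimum-norm solution",
      r, ncol(X)))
  }
  idx <- seq_len(max(r, 1L))
  beta <- sv$v[, idx, drop = FALSE] %*%
    (crossprod(sv$u[, idx, drop = FALSE], y) / sv$d[idx])
  list(beta = as.numeric(beta), rank = r)
}

#' Fit the second-order polynomial SEMG-force model
#'
#' Ordinary least squares fit of
#' `F = sum_p (theta1_p * e(p) + theta2_p * e(p)^2)`
#' over the chosen wavelet scales, with no intercept term. Rank-deficient
#' designs are resolved by the minimum-norm solution (with a warning); no
#' regularization is applied.
#'
#' @param feats a `scale_features` object (or plain numeric matrix with
#'   `sP`-named columns).
#' @param force force at frame rate, %MVC, one value per feature frame.
#' @param scales integer subset of the feature scales to use as predictors.
#' @param intercept include an intercept term (default `FALSE`, matching
#'   the model's zero-input/zero-force form).
#' @return object of class `semg_force_model`: `scales`, `theta1`,
#'   `theta2`, optional `intercept`, and `fit_meta` (frame count, residual
#'   sum of squares, design rank).
#' @export
fit_polynomial_model <- function(feats, force, scales = NULL,
                                 intercept = FALSE) {
  e <- if (inherits(feats, "scale_features")) feats$e else as.matrix(feats)
  if (is.null(scales)) {
    scales <- if (inherits(feats, "scale_features")) feats$scales else
      as.integer(sub("^s", "", colnames(e)))
  }
  if (length(scales) == 0L) stop("empty scale set")
  if (!all(is.finite(e)) || !all(is.finite(force))) {
    stop("non-finite values in features or force")
  }
  if (length(force) != nrow(e)) {
    stop("force length must equal the feature frame count")
  }
  if (nrow(e) < 2 * length(scales)) {
    stop("need at least 2 frames per scale to fit the model")
  }
  X <- polynomial_design(e, scales, intercept)
  fit <- minnorm_lsfit(X, force)
  beta <- fit$beta
  off <- if (intercept) 1L else 0L
  P <- length(scales)
  resid <- force - as.numeric(X %*% beta)
  structure(
    list(scales = as.integer(scales),
         theta1 = beta[off + seq_len(P)],
         theta2 = beta[off + P + seq_len(P)],
         intercept = if (intercept) beta[1] else 0,
         fit_meta = list(n_frames = nrow(e), rss = sum(resid^2),
                         rank = fit$rank)),
    class = "semg_force_model"
  )
}

#' @export
print.semg_force_model <- function(x, ...) {
  cat(sprintf("<semg_force_model> scales {%s}, fitted on %d frames (RSS %.4g)\n",
              paste(x$scales, collapse = ","),
              x$fit_meta$n_frames, x$fit_meta$rss))
  tab <- rbind(theta1 = x$theta1, theta2 = x$theta2)
  colnames(tab) <- paste0("s", x$scales)
  print(signif(tab, 4))
  invisible(x)
}

#' Predict force from scale intensities
#'
#' Evaluates `F_hat = sum_p (theta1_p e(p) + theta2_p e(p)^2)` frame by
#' frame. Predictions are not clipped by default; physiologically the force
#' lies in \[0, 100\] %MVC and `clip = TRUE` enforces that range.
#'
#' @param model a `semg_force_model`.
#' @param feats `scale_features` (or matrix) containing at least the
#'   model's scales.
#' @param clip clip predictions to \[0, 100\] %MVC (default `FALSE`).
#' @return numeric vector of predicted force, %MVC.
#' @export
predict_force <- function(model, feats, clip = FALSE) {
  e <- if (inherits(feats, "scale_features")) feats$e else as.matrix(feats)
  X <- polynomial_design(e, model$scales, intercept = FALSE)
  pred <- as.numeric(X %*% c(model$theta1, model$theta2)) + model$intercept
  if (clip) pred <- pmin(pmax(pred, 0), 100)
  pred
}

#' Root mean square error between actual and estimated force
#'
#' `sqrt(mean((actual - estimated)^2))`, the performance index used
#' throughout; in %MVC when both series are on the %MVC scale.
#'
#' @param actual,estimated numeric series of equal length.
#' @return RMSE (numeric scalar, >= 0).
#' @export
rmse <- function(actual, estimated) {
  if (length(actual) != length(estimated)) {
    stop("actual and estimated series must have equal length")
  }
  if (length(actual) < 1L) stop("need at least one sample")
  sqrt(mean((actual - estimated)^2))
}

#' Windowed RMSE series
#'
#' RMSE over consecutive non-overlapping windows of `width` frames,
#' giving the time-varying error curve over a validation task. A trailing
#' partial window is included if at least half full.
#'
#' @param actual,estimated series of equal length.
#' @param width window width in frames (>= 1).
#' @return numeric vector of per-window RMSE values.
#' @export
windowed_rmse <- function(actual, estimated, width) {
  if (length(actual) != length(estimated)) {
    stop("actual and estimated series must have equal length")
  }
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1")
  n <- length(actual)
  full <- n %/% width
  starts <- seq_len(full) * width - width + 1L
  ends <- seq_len(full) * width
  if (n - full * width >= width / 2) {
    starts <- c(starts, full * width + 1L)
    ends <- c(ends, n)
  }
  vapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    rmse(actual[idx], estimated[idx])
  }, numeric(1))
}

#' Serialize a force model to JSON
#' @param model a `semg_force_model`.
#' @param path output file.
#' @export
write_force_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force model from JSON
#' @param path JSON file written by [write_force_model()].
#' @export
read_force_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$scales <- as.integer(m$scales)
  structure(m, class = "semg_force_model")
}
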