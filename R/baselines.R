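#' Frame-wise RMS envelope of a signal
#'
#' RMS amplitude over non-overlapping frames of `M` samples (the classical
#' SEMG amplitude estimate), used by the linear baseline.
#'
#' @param x numeric series.
#' @param M frame size in samples.
#' @return numeric vector of `floor(length(x)/M)` RMS values.
#' @export
rms_envelope <- function(x, M) {
  if (M < 1 || M > length(x)) stop("invalid frame size")
  K <- length(x) %/% M
  sqrt(colMeans(matrix(x[seq_len(K * M)]^2, nrow = M)))
}

#' Baseline A: linear RMS-envelope force model
#'
#' The classical amplitude-based estimator: the band-passed, MVC-normalized
#' SEMG is reduced to a smoothed RMS envelope at the pipeline's frame and
#' smoothing settings, and force is regressed linearly on the envelope
#' (no intercept by default, parallel to the polynomial model).
#'
#' @param rec a normalized `semg_recording` (band-pass filtering is assumed
#'   to have been applied before normalization).
#' @param channel EMG channel name.
#' @param frame frame size in samples (default 200).
#' @param smooth_ms moving-average window in ms (default 200).
#' @param intercept include an intercept (default `FALSE`).
#' @return object of class `linear_envelope_model` with `slope`,
#'   `intercept`, `frame` and `smooth_ms`.
#' @export
fit_method_a <- function(rec, channel, frame = 200, smooth_ms = 200,
                         intercept = FALSE) {
  stopifnot(inherits(rec, "semg_recording"))
  if (!channel %in% channels(rec)) stop("unknown channel: ", channel)
  env <- envelope_features(rec, channel, frame, smooth_ms)
  if (all(env$envelope == 0)) stop("constant-zero envelope; cannot fit")
  X <- if (intercept) cbind(1, env$envelope) else cbind(env$envelope)
  beta <- minnorm_lsfit(X, env$force)$beta
  structure(
    list(slope = if (intercept) beta[2] else beta[1],
         intercept = if (intercept) beta[1] else 0,
         frame = frame, smooth_ms = smooth_ms, channel = channel),
    class = "linear_envelope_model"
  )
}

# smoothed RMS envelope + frame-aligned force for one channel
envelope_features <- function(rec, channel, frame = 200, smooth_ms = 200) {
  env <- rms_envelope(rec$emg[, channel], frame)
  frame_rate <- rec$fs / frame
  w <- max(1L, round(smooth_ms * frame_rate / 1000))
  if (w > 1L) {
    env <- zoo::rollapply(env, width = w, FUN = mean, partial = TRUE,
                          align = "center")
  }
  K <- length(env)
  force <- colMeans(matrix(rec$force[seq_len(K * frame)], nrow = frame))
  list(envelope = env, force = force, frame_rate = frame_rate)
}

#' Predict force with the linear envelope model
#' @param object a `linear_envelope_model`.
#' @param envelope smoothed RMS envelope values (e.g. from the same
#'   settings as the fit).
#' @param ... unused.
#' @export
predict.linear_envelope_model <- function(object, envelope, ...) {
  object$intercept + object$slope * envelope
}

#' Baseline B: fixed scales-2-and-3 polynomial model
#'
#' The frequency-band baseline: the second-order polynomial force model
#' restricted to wavelet scales 2 and 3. Identical in every respect to
#' [fit_polynomial_model()] with `scales = c(2, 3)`.
#'
#' @param feats a `scale_features` containing scales 2 and 3.
#' @param force force at frame rate, %MVC.
#' @return a `semg_force_model` on scales {2, 3}.
#' @export
fit_method_b <- function(feats, force) {
  fit_polynomial_model(feats, force, scales = c(2L, 3L))
}
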