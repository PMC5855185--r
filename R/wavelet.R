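# db2 scaling filter (orthonormal, sum h = sqrt(2))
db2_scaling_filter <- function() {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}

# One dyadic refinement step of the two-scale relation
# phi(x) = sqrt(2) * sum_k h_k phi(2x - k), exact on dyadic grids.
refine_phi <- function(v, h) {
  nj <- length(v) - 1L          # top index = 3 * 2^j
  step <- nj %/% 3L             # 2^j
  n1 <- 2L * nj                 # top index at level j + 1
  out <- numeric(n1 + 1L)
  for (k in 0:3) {
    idx <- (0:n1) - k * step        # index into grid j for argument 2x - k
    ok <- idx >= 0L & idx <= nj
    out[ok] <- out[ok] + sqrt(2) * h[k + 1L] * v[idx[ok] + 1L]
  }
  out
}

the_psi_cache <- new.env(parent = emptyenv())

#' Sampled db2 wavelet function
#'
#' The Daubechies-2 wavelet has no closed form; its values are obtained
#' exactly on a dyadic grid by refining the two-scale relation from the
#' known values of the scaling function at the integers (cascade
#' algorithm). The wavelet is supported on \[0, 3\].
#'
#' @param level dyadic refinement level; the grid spacing is `2^-level`.
#' @return list with `x` (grid points over \[0, 3\]), `psi` (wavelet values)
#'   and `level`.
#' @export
db2_psi <- function(level = 10) {
  key <- as.character(level)
  if (!is.null(the_psi_cache[[key]])) return(the_psi_cache[[key]])
  h <- db2_scaling_filter()
  # exact values of the scaling function at the integers 0..3
  s3 <- sqrt(3)
  phi <- c(0, (1 + s3) / 2, (1 - s3) / 2, 0)
  for (j in seq_len(level)) phi <- refine_phi(phi, h)
  # wavelet via the quadrature-mirror filter g_k = (-1)^k h_{3-k}
  g <- c(h[4], -h[3], h[2], -h[1])
  top <- 3L * 2L^level
  psi <- numeric(top + 1L)
  for (k in 0:3) {
    idx <- 2L * (0:top) - k * 2L^level   # phi index for 2x - k
    ok <- idx >= 0L & idx <= top
    psi[ok] <- psi[ok] + sqrt(2) * g[k + 1L] * phi[idx[ok] + 1L]
  }
  res <- list(x = (0:top) / 2^level, psi = psi, level = level)
  the_psi_cache[[key]] <- res
  res
}

#' Discrete wavelet kernel at an integer scale
#'
#' Samples the db2 wavelet at spacing `1/p` over its support, i.e. the
#' dilated wavelet evaluated at integer sample offsets, giving a kernel of
#' `3p + 1` taps. With `energy_norm` the kernel is divided by `sqrt(p)`,
#' the customary CWT normalization that keeps intensities comparable
#' across scales.
#'
#' @param p positive integer scale.
#' @param energy_norm logical; apply the `1/sqrt(p)` factor (default `TRUE`).
#' @param level refinement level of the underlying wavelet table.
#' @return numeric vector of kernel taps.
#' @export
db2_kernel <- function(p, energy_norm = TRUE, level = 10) {
  tab <- db2_psi(level)
  m <- 0:(3L * p)
  w <- tab$psi[round(m * 2^level / p) + 1L]
  if (energy_norm) w <- w / sqrt(p)
  w
}

#' Continuous wavelet transform with the db2 wavelet at integer scales
#'
#' Computes, for each scale `p`, the correlation of the signal with the
#' dilated db2 wavelet sampled at the signal's rate:
#' `c_n(p) = sum_m x[n + m - s] psi(m / p)` with `s = floor(3p/2)`
#' ('same' alignment, centered on the wavelet support; db2 is real so the
#' conjugate is trivial). Boundaries are zero-padded and the output has one
#' row per input sample.
#'
#' @param x numeric signal (finite values).
#' @param scales positive integer scales (default 1:10).
#' @param fs sampling rate in Hz (metadata; the kernel dilation is in
#'   samples).
#' @param energy_norm apply `1/sqrt(p)` normalization (default `TRUE`; set
#'   `FALSE` for the literal unnormalized convolution sum).
#' @return object of class `cwt_coefficients`: list with matrix `c`
#'   (`length(x)` x `length(scales)`), `scales`, `fs`, `energy_norm`.
#' @export
cwt_db2 <- function(x, scales = 1:10, fs = 1000, energy_norm = TRUE) {
  if (length(x) == 0L) stop("empty signal")
  if (!all(is.finite(x))) stop("signal must be finite")
  if (any(scales < 1) || any(scales != round(scales))) {
    stop("scales must be positive integers")
  }
  scales <- as.integer(scales)
  N <- length(x)
  C <- matrix(0, N, length(scales),
              dimnames = list(NULL, paste0("s", scales)))
  for (j in seq_along(scales)) {
    p <- scales[j]
    w <- db2_kernel(p, energy_norm = energy_norm)
    L <- length(w)
    ctr <- (3L * p) %/% 2L
    xpad <- c(numeric(ctr), x, numeric(L - 1L - ctr))
    acc <- numeric(N)
    for (m in seq_len(L)) {
      if (w[m] != 0) acc <- acc + w[m] * xpad[(m - 1L) + seq_len(N)]
    }
    C[, j] <- acc
  }
  structure(list(c = C, scales = scales, fs = fs, energy_norm = energy_norm),
            class = "cwt_coefficients")
}

#' Pseudo-frequency of a wavelet scale
#'
#' Maps a wavelet scale to its nominal central frequency by the inverse
#' relation `f(p) = f1 / p`, with the scale-1 central frequency fixed at
#' 727.27 Hz for recordings sampled at 1000 Hz. Larger scales correspond to
#' lower frequency bands; `f(p) * p` is constant.
#'
#' @param p scale (>= 1), vectorized.
#' @param f1 central frequency of scale 1 in Hz.
#' @return central frequency in Hz.
#' @export
pseudo_frequency <- function(p, f1 = 727.27) {
  if (any(p < 1)) stop("scale must be >= 1")
  f1 / p
}

#' Frame-wise RMS intensity of wavelet coefficients
#'
#' Reduces per-sample wavelet coefficients to per-frame intensities:
#' `e[k, p] = sqrt(mean(c[n, p]^2))` over non-overlapping frames of `M`
#' samples (`K = floor(N / M)` frames; a trailing partial frame is
#' discarded).
#'
#' @param cw a `cwt_coefficients` object.
#' @param M frame size in samples (>= 1, <= signal length).
#' @return object of class `scale_features`: list with matrix `e` (`K` x
#'   `P`), `scales`, `frame_size`, `frame_rate` (Hz), `smoothing_ms`
#'   (0 until smoothed).
#' @export
rms_intensity <- function(cw, M) {
  stopifnot(inherits(cw, "cwt_coefficients"))
  N <- nrow(cw$c)
  if (M < 1 || M != round(M)) stop("M must be a positive integer")
  if (M > N) stop("frame size M exceeds signal length")
  K <- N %/% M
  e <- matrix(0, K, ncol(cw$c), dimnames = list(NULL, colnames(cw$c)))
  for (j in seq_len(ncol(cw$c))) {
    v <- matrix(cw$c[seq_len(K * M), j]^2, nrow = M)
    e[, j] <- sqrt(colMeans(v))
  }
  structure(list(e = e, scales = cw$scales, frame_size = M,
                 frame_rate = cw$fs / M, smoothing_ms = 0),
            class = "scale_features")
}

#' @export
print.scale_features <- function(x, ...) {
  cat(sprintf(
    "<scale_features> %d frames x %d scales @ %g frames/s (frame %d samples, smoothing %g ms)\n",
    nrow(x$e), ncol(x$e), x$frame_rate, x$frame_size, x$smoothing_ms))
  invisible(x)
}

#' Moving-average smoothing of scale intensities
#'
#' Centered moving average of each scale column over a window of
#' `window_ms` milliseconds (default 200 ms), with edge shrinking: partial
#' windows at the boundaries are averaged over the available frames. The
#' window in frames is `max(1, round(window_ms * frame_rate / 1000))`.
#'
#' @param feats a `scale_features` object.
#' @param window_ms smoothing window in milliseconds (> 0).
#' @return smoothed `scale_features`.
#' @export
smooth_moving_average <- function(feats, window_ms = 200) {
  stopifnot(inherits(feats, "scale_features"))
  if (window_ms <= 0) stop("window_ms must be > 0")
  w <- max(1L, round(window_ms * feats$frame_rate / 1000))
  out <- feats
  out$smoothing_ms <- window_ms
  if (w == 1L) return(out)
  out$e <- apply(feats$e, 2, function(col) {
    zoo::rollapply(col, width = w, FUN = mean, partial = TRUE,
                   align = "center")
  })
  dimnames(out$e) <- dimnames(feats$e)
  out
}

#' Extract smoothed wavelet-scale intensities and frame-aligned force
#'
#' Composition of [cwt_db2()], [rms_intensity()] and
#' [smooth_moving_average()] on one channel of a normalized recording.
#' Force is reduced to the frame rate by per-frame means so intensities
#' and force are index-aligned.
#'
#' @param rec a normalized `semg_recording` (force in %MVC).
#' @param channel channel name.
#' @param scales integer scales (default 1:10).
#' @param frame frame size `M` in samples (default 200, i.e. 200 ms at
#'   1000 Hz).
#' @param smooth_ms moving-average window in ms (default 200).
#' @param energy_norm passed to [cwt_db2()].
#' @return list with `features` (a `scale_features`) and `force` (%MVC at
#'   frame rate, length `K`).
#' @export
extract_features <- function(rec, channel, scales = 1:10, frame = 200,
                             smooth_ms = 200, energy_norm = TRUE) {
  stopifnot(inherits(rec, "semg_recording"))
  if (!channel %in% channels(rec)) stop("unknown channel: ", channel)
  cw <- cwt_db2(rec$emg[, channel], scales = scales, fs = rec$fs,
                energy_norm = energy_norm)
  feats <- smooth_moving_average(rms_intensity(cw, frame), smooth_ms)
  K <- nrow(feats$e)
  force_k <- colMeans(matrix(rec$force[seq_len(K * frame)], nrow = frame))
  list(features = feats, force = force_k)
}
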