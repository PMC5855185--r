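#' Monte Carlo sensitivity of each wavelet scale
#'
#' Variance-based global sensitivity of the fitted polynomial model: for
#' each scale `p`, `n_random` values `u ~ Uniform(lo, hi)` are drawn
#' independently, the scale's model term `g_p(u) = theta1_p u + theta2_p
#' u^2` is evaluated, and the raw sensitivity is the mean square deviation
#' of `g_p` about its mean (the term's output variance). Because the model
#' is additive across scales these are exactly the first-order variance
#' contributions; there are no interaction terms. Raw values are
#' normalized by their sum (step 5 of the procedure).
#'
#' @param model a `semg_force_model`.
#' @param n_random number of uniform draws per scale (>= 2; default
#'   100,000, the count at which the convergence experiment stabilizes).
#' @param lo,hi uniform input range; default (0, 100), intensities treated
#'   on the percent scale.
#' @param seed optional integer seed (set once for the whole call).
#' @param segment_id,subject_id optional provenance labels.
#' @return object of class `sensitivity_profile`: `scales`, `raw`,
#'   `normalized` (sums to 1), term moment means `m1`..`m4` (used by
#'   [additive_output_variance()] and for Monte Carlo standard errors),
#'   `n_random`, `seed` and provenance labels.
#' @export
simulate_sensitivity <- function(model, n_random = 1e5, lo = 0, hi = 100,
                                 seed = NULL, segment_id = NA,
                                 subject_id = NA) {
  stopifnot(inherits(model, "semg_force_model"))
  if (n_random < 2) stop("n_random must be >= 2")
  if (length(model$scales) < 1L) stop("model has no scales")
  if (!is.null(seed)) set.seed(seed)
  mom <- mc_term_moments(model$theta1, model$theta2, n_random, lo, hi)
  raw <- as.numeric(mom[2, ] - mom[1, ]^2)
  raw <- pmax(raw, 0)   # guard against negative rounding at zero variance
  total <- sum(raw)
  if (total > 0) {
    normalized <- raw / total
  } else {
    warning("all-zero model: normalized sensitivity set to uniform 1/P")
    normalized <- rep(1 / length(raw), length(raw))
  }
  structure(
    list(scales = model$scales, raw = raw, normalized = normalized,
         m1 = as.numeric(mom[1, ]), m2 = as.numeric(mom[2, ]),
         m3 = as.numeric(mom[3, ]), m4 = as.numeric(mom[4, ]),
         n_random = n_random, seed = seed,
         segment_id = segment_id, subject_id = subject_id),
    class = "sensitivity_profile"
  )
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> %d scales, n_random = %g\n",
              length(x$scales), x$n_random))
  v <- x$normalized
  names(v) <- paste0("s", x$scales)
  print(signif(v, 4))
  invisible(x)
}

#' Full-model output variance under the additive decomposition
#'
#' The polynomial model is additive across scales with independent uniform
#' inputs, so its output variance over the product of the per-scale
#' empirical draw distributions expands through the term moments:
#' `E[F^2] - E[F]^2` with `E[F] = sum_p m1_p` and
#' `E[F^2] = sum_p m2_p + sum_{p != q} m1_p m1_q`. Algebraically this
#' equals the sum of per-scale raw sensitivities; computing it through the
#' expanded moments provides an internal consistency check of the additive
#' variance decomposition (agreement to floating-point precision).
#'
#' @param profile a `sensitivity_profile`.
#' @return output variance of the full model on the profile's draws.
#' @export
additive_output_variance <- function(profile) {
  m1 <- profile$m1
  m2 <- profile$m2
  cross <- outer(m1, m1)
  diag(cross) <- 0
  sum(m2) + sum(cross) - sum(m1)^2
}

#' Convergence experiment over the number of random variables
#'
#' Recomputes the normalized sensitivity profile on a grid of draw counts
#' `r = step, 2*step, ..., r_max` (fresh independent draws at every grid
#' point), forms per-scale absolute first differences
#' `d_i(p) = |y_{i+1}(p) - y_i(p)|` and their sum over scales
#' `d_i(integration)`, and reports the draw count after which a
#' trailing-window mean of `d_integration` stays below a tolerance
#' (default: 1.5 times the mean over the last `window` grid points).
#'
#' @param model a `semg_force_model`.
#' @param r_max largest draw count (default 140,000).
#' @param step grid spacing (default 100); `r_max >= 2 * step`.
#' @param seed optional seed set once before the sweep.
#' @param lo,hi uniform input range.
#' @param window trailing-window length in grid points for the stopping
#'   rule (default 10).
#' @param tol_factor tolerance multiplier on the tail mean (default 1.5).
#' @return object of class `convergence_result`: `grid`, `y` (grid x
#'   scales normalized sensitivities), `d` (absolute differences), series
#'   `d_integration`, and `chosen_n`.
#' @export
convergence_experiment <- function(model, r_max = 140000, step = 100,
                                   seed = NULL, lo = 0, hi = 100,
                                   window = 10, tol_factor = 1.5) {
  stopifnot(inherits(model, "semg_force_model"))
  if (r_max < 2 * step) stop("r_max must be at least 2 * step")
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(step, r_max, by = step)
  P <- length(model$scales)
  y <- matrix(0, length(grid), P,
              dimnames = list(NULL, paste0("s", model$scales)))
  for (i in seq_along(grid)) {
    mom <- mc_term_moments(model$theta1, model$theta2, grid[i], lo, hi)
    raw <- pmax(as.numeric(mom[2, ] - mom[1, ]^2), 0)
    total <- sum(raw)
    y[i, ] <- if (total > 0) raw / total else rep(1 / P, P)
  }
  d <- abs(diff(y))
  d_int <- rowSums(d)
  # stopping rule: smallest r after which every trailing-window mean of
  # d_integration stays below tol
  tol <- mean(tail(d_int, window)) * tol_factor
  wm <- zoo::rollapply(d_int, width = window, FUN = mean, align = "left",
                       partial = TRUE)
  bad <- which(wm >= tol)
  chosen_idx <- if (length(bad)) min(max(bad) + 1L, length(grid)) else 1L
  structure(
    list(grid = grid, y = y, d = d, d_integration = d_int,
         chosen_n = grid[chosen_idx], window = window,
         tol = tol, seed = seed),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf(
    "<convergence_result> grid %g..%g (%d points); chosen n_random = %g\n",
    min(x$grid), max(x$grid), length(x$grid), x$chosen_n))
  invisible(x)
}

#' Per-minute sensitivity profiles for a set of recordings
#'
#' For every recording and every minute-long segment: extract smoothed
#' wavelet-scale intensities, fit the full polynomial model on all scales,
#' and run the Monte Carlo sensitivity simulation. Segments whose
#' features are degenerate (a constant intensity column) or whose fit
#' fails are flagged and excluded with a message.
#'
#' @param recordings list of normalized `semg_recording`s (analysis task).
#' @param channel EMG channel to analyze.
#' @param scales integer scales (default 1:10).
#' @param frame,smooth_ms feature extraction settings (see
#'   [extract_features()]).
#' @param segment_s segment length in seconds (default 60).
#' @param n_random draws per scale for each profile (default 100,000).
#' @param seed optional seed, set once; segments then consume one common
#'   reproducible stream.
#' @return list of `sensitivity_profile` objects (one per retained
#'   segment), each labelled with `subject_id` and `segment_id`.
#' @export
sensitivity_pipeline <- function(recordings, channel, scales = 1:10,
                                 frame = 200, smooth_ms = 200,
                                 segment_s = 60, n_random = 1e5,
                                 seed = NULL) {
  if (inherits(recordings, "semg_recording")) recordings <- list(recordings)
  if (!is.null(seed)) set.seed(seed)
  profiles <- list()
  for (rec in recordings) {
    if (!isTRUE(rec$normalized)) {
      stop("recordings must be MVC-normalized (force in %MVC)")
    }
    segs <- segment_minutes(rec, segment_s)
    for (i in seq_along(segs)) {
      fx <- extract_features(segs[[i]], channel, scales = scales,
                             frame = frame, smooth_ms = smooth_ms)
      sds <- apply(fx$features$e, 2, stats::sd)
      if (any(sds == 0)) {
        message(sprintf(
          "subject %s segment %d: degenerate features (constant scale column); excluded",
          rec$subject_id, i))
        next
      }
      model <- tryCatch(
        fit_polynomial_model(fx$features, fx$force, scales),
        error = function(e) NULL)
      if (is.null(model)) {
        message(sprintf("subject %s segment %d: model fit failed; excluded",
                        rec$subject_id, i))
        next
      }
      prof <- simulate_sensitivity(model, n_random = n_random,
                                   segment_id = i,
                                   subject_id = rec$subject_id)
      profiles[[length(profiles) + 1L]] <- prof
    }
  }
  profiles
}

#' Mean sensitivity across profiles
#'
#' Arithmetic mean of the normalized per-scale sensitivities over all
#' segments and subjects; the quantity the scale ranking is built on.
#'
#' @param profiles non-empty list of `sensitivity_profile`s sharing one
#'   scale set.
#' @return named numeric vector of mean normalized sensitivities (sums
#'   to 1).
#' @export
aggregate_sensitivity <- function(profiles) {
  if (inherits(profiles, "sensitivity_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("need at least one profile")
  ref <- profiles[[1]]$scales
  for (p in profiles) {
    if (!identical(p$scales, ref)) stop("inconsistent scale sets")
  }
  m <- rowMeans(vapply(profiles, function(p) p$normalized,
                       numeric(length(ref))))
  names(m) <- paste0("s", ref)
  m
}
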