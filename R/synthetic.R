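#' Default synthetic band definitions
#'
#' One band-limited noise carrier per wavelet scale, centered at the
#' scale's pseudo-frequency with band edges at the midpoints between
#' adjacent centers. Centers are clipped to `0.46 * fs` and the top edge
#' to `0.49 * fs` so every carrier is realizable below the Nyquist
#' frequency (the scale-1 pseudo-frequency exceeds Nyquist at 1000 Hz).
#' Scales in `coupled` carry a force-dependent amplitude
#' `g1 * F + g2 * F^2`; the remaining scales carry a constant low-level
#' baseline amplitude, emulating bands dominated by motion artifact and
#' fatigue-related noise rather than force.
#'
#' @param fs sampling rate in Hz.
#' @param scales integer scales (default 1:10).
#' @param f1 scale-1 pseudo-frequency in Hz.
#' @param coupled scales whose amplitude follows force (default 1:5, the
#'   high-frequency bands).
#' @param g1 linear amplitude gain per %MVC (default 0.01).
#' @param g2 quadratic amplitude gain per %MVC^2 (default 2e-5).
#' @param base_amp baseline amplitude of non-coupled bands (default 0.05).
#' @return data.frame with columns scale, center, low, high, g1, g2, base.
#' @export
default_band_defs <- function(fs = 1000, scales = 1:10, f1 = 727.27,
                              coupled = 1:5, g1 = 0.01, g2 = 2e-5,
                              base_amp = 0.05) {
  ctr <- pmin(pseudo_frequency(scales, f1), 0.46 * fs)
  P <- length(scales)
  low <- c((ctr[-P] + ctr[-1]) / 2, ctr[P] - (ctr[P - 1] - ctr[P]) / 2)
  high <- c(min(ctr[1] + (ctr[1] - ctr[2]) / 2, 0.49 * fs),
            (ctr[-P] + ctr[-1]) / 2)
  is_c <- scales %in% coupled
  data.frame(scale = scales, center = ctr, low = low, high = high,
             g1 = ifelse(is_c, g1, 0), g2 = ifelse(is_c, g2, 0),
             base = ifelse(is_c, 0, base_amp))
}

#' Synthetic-data generator configuration
#'
#' Defines the emulated gripping task and signal structure: a 10-min
#' force-varying task (force 0-80 %MVC) by default, static tasks at
#' 20/30/50/70 %MVC, per-band amplitude gains tied to the wavelet-scale
#' pseudo-frequencies, optional fatigue-like low-frequency drift whose
#' amplitude grows linearly over time, and broadband measurement noise.
#' Randomness uses R's default Mersenne-Twister generator; a fixed `seed`
#' makes every generated series reproducible.
#'
#' @param fs sampling rate in Hz (default 1000).
#' @param duration_s recording length in seconds (default 600).
#' @param task `"force_varying"`, `"static"` or `"analysis"`.
#' @param static_level target level for static tasks, %MVC (default 30).
#' @param static_levels the standard set of static levels, %MVC.
#' @param force_range force range for the force-varying task, %MVC.
#' @param band_defs band definition table (see [default_band_defs()]).
#' @param drift_rate amplitude growth of the fatigue-like low-frequency
#'   noise, in normalized amplitude units per minute (default 0 = no
#'   drift): the non-force-coupled band amplitudes and a sub-20 Hz
#'   motion-artifact carrier both grow linearly in time. The realized
#'   slope of each synthesized channel is `drift_rate` times a random
#'   session factor (uniform on 0.25-1.75), reflecting the between-session
#'   variability of fatigue progression.
#' @param drift_band frequency band of the motion-artifact carrier in Hz.
#' @param tilt_rate spectral tilt: fractional decay of the force-coupled
#'   (high-frequency) band gains per minute (default 0 = stable gains).
#'   Emulates the fatigue-driven power shift away from high frequencies
#'   that makes the SEMG-force relationship unstable over time.
#' @param unstable_gain_sd typical magnitude of a session-specific random
#'   linear force gain added to each non-force-coupled band (default 0).
#'   Models the unreliable coupling of the low-frequency scales to force:
#'   within one session those bands do co-vary with force (through motor
#'   unit rotation, artifact from force-dependent limb shake, fatigue
#'   state), but the coupling does not replicate across sessions. Each
#'   band's realized gain is drawn once per synthesized channel as
#'   `+- unstable_gain_sd * Uniform(0.5, 1.5)` with random sign.
#' @param noise_sd standard deviation of broadband white noise.
#' @param mvc_force_kg maximal grip force used to express the recording in
#'   kg (default 40).
#' @param channels channel name(s) to synthesize (independent noise per
#'   channel).
#' @param seed optional integer seed.
#' @return list of class `semg_simconfig`.
#' @export
generator_config <- function(fs = 1000, duration_s = 600,
                             task = c("force_varying", "static", "analysis"),
                             static_level = 30,
                             static_levels = c(20, 30, 50, 70),
                             force_range = c(0, 80),
                             band_defs = default_band_defs(fs),
                             drift_rate = 0, drift_band = c(1, 20),
                             tilt_rate = 0, unstable_gain_sd = 0,
                             noise_sd = 0.02,
                             mvc_force_kg = 40, channels = "emg",
                             seed = NULL) {
  task <- match.arg(task)
  stopifnot(fs > 0, duration_s > 0, all(is.finite(band_defs$g1)),
            all(is.finite(band_defs$g2)))
  if (fs <= 2 * max(band_defs$high)) {
    stop("fs must exceed twice the highest band edge")
  }
  structure(
    list(fs = fs, duration_s = duration_s, task = task,
         static_level = static_level, static_levels = static_levels,
         force_range = force_range, band_defs = band_defs,
         drift_rate = drift_rate, drift_band = drift_band,
         tilt_rate = tilt_rate, unstable_gain_sd = unstable_gain_sd,
         noise_sd = noise_sd, mvc_force_kg = mvc_force_kg,
         channels = channels, seed = seed),
    class = "semg_simconfig"
  )
}

fold_into <- function(y, lo, hi) {
  r <- hi - lo
  z <- (y - lo) %% (2 * r)
  lo + r - abs(z - r)
}

#' Generate a force profile
#'
#' Task-dependent target force series at the configured sampling rate:
#' * `force_varying`: a smooth random walk (1-Hz knots folded into the
#'   force range, interpolated and low-pass smoothed), clipped to range;
#' * `static`: the target level plus a slow jitter bounded by +-2 %MVC;
#' * `analysis`: per-minute triangular squeeze-release ramps with peaks
#'   increasing from 30 to 80 %MVC across minutes.
#'
#' @param cfg a `semg_simconfig`; `cfg$seed`, if set, seeds the generator.
#' @return numeric force series in %MVC, length `fs * duration_s`.
#' @export
generate_force_profile <- function(cfg) {
  stopifnot(inherits(cfg, "semg_simconfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  N <- round(cfg$duration_s * fs)
  if (cfg$task == "static") {
    z <- rnorm(N)
    bf <- signal::butter(2, min(0.5, 0.4 * fs / 2) / (fs / 2), type = "low")
    lp <- as.numeric(signal::filtfilt(bf, z))
    jitter <- 2 * lp / max(abs(lp))
    return(cfg$static_level + jitter)
  }
  if (cfg$task == "force_varying") {
    lo <- cfg$force_range[1]
    hi <- cfg$force_range[2]
    nk <- ceiling(cfg$duration_s) + 1L
    walk <- (lo + hi) / 2 + c(0, cumsum(rnorm(nk - 1L, 0, 8)))
    knots <- fold_into(walk, lo, hi)
    f <- approx(x = seq_len(nk) - 1L, y = knots,
                xout = (seq_len(N) - 1L) / fs, rule = 2)$y
    bf <- signal::butter(2, min(1, 0.4 * fs / 2) / (fs / 2), type = "low")
    f <- as.numeric(signal::filtfilt(bf, f))
    return(pmin(pmax(f, lo), hi))
  }
  # analysis: per-minute ramps of increasing peak
  n_min <- max(1L, ceiling(cfg$duration_s / 60))
  peaks <- if (n_min == 1L) 80 else seq(30, 80, length.out = n_min)
  len <- round(60 * fs)
  tri <- unlist(lapply(peaks, function(pk) {
    up <- seq(0, pk, length.out = floor(len / 2))
    dn <- seq(pk, 0, length.out = len - floor(len / 2))
    c(up, dn)
  }))
  f <- tri[seq_len(N)] + rnorm(N, 0, 0.3)
  pmax(f, 0)
}

bandlimited_noise <- function(N, fs, low, high, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- as.numeric(signal::filtfilt(bf, rnorm(N)))
  z / stats::sd(z)
}

#' Synthesize an SEMG signal from a force profile
#'
#' Sum of band-limited Gaussian noise carriers (unit RMS), each modulated
#' by the force-dependent amplitude `base + g1 * F + g2 * F^2` of its band
#' (so the quadratic polynomial family is the correct inverse model for
#' the force-coupled bands), plus fatigue-like drift, plus broadband white
#' noise. Drift has two facets, both controlled by `cfg$drift_rate` and
#' both growing linearly in time: the amplitude of the non-force-coupled
#' (low-frequency) bands increases by `drift_rate` per minute, emulating
#' the fatigue-driven growth of low-frequency SEMG power, and a sub-20 Hz
#' motion-artifact carrier grows at the same rate.
#'
#' @param force force series in %MVC, sampled at `cfg$fs`.
#' @param cfg a `semg_simconfig`.
#' @return numeric SEMG series in normalized amplitude units.
#' @export
synthesize_semg <- function(force, cfg) {
  stopifnot(inherits(cfg, "semg_simconfig"))
  N <- length(force)
  fs <- cfg$fs
  t_min <- (seq_len(N) - 1L) / fs / 60
  out <- if (cfg$noise_sd > 0) rnorm(N, 0, cfg$noise_sd) else numeric(N)
  tilt <- if (cfg$tilt_rate > 0) pmax(1 - cfg$tilt_rate * t_min, 0.1) else 1
  drift_slope <- if (cfg$drift_rate > 0) {
    cfg$drift_rate * runif(1, 0.25, 1.75)
  } else 0
  for (i in seq_len(nrow(cfg$band_defs))) {
    bd <- cfg$band_defs[i, ]
    coupled <- bd$g1 != 0 || bd$g2 != 0
    amp <- bd$base + (bd$g1 * force + bd$g2 * force^2) * tilt
    if (!coupled) {
      if (cfg$unstable_gain_sd > 0) {
        h <- sample(c(-1, 1), 1) * runif(1, 0.5, 1.5) * cfg$unstable_gain_sd
        amp <- amp + h * force
      }
      if (drift_slope > 0) amp <- amp + drift_slope * t_min
    }
    if (all(amp == 0)) next
    out <- out + amp * bandlimited_noise(N, fs, bd$low, bd$high)
  }
  if (drift_slope > 0) {
    carrier <- bandlimited_noise(N, fs, cfg$drift_band[1], cfg$drift_band[2],
                                 order = 2)
    out <- out + (drift_slope * t_min) * carrier
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Seeds the generator, builds the force profile, synthesizes one SEMG
#' channel per configured channel name (independent noise realizations),
#' and packages everything as a raw recording in kg together with an MVC
#' calibration consistent with the generator's maximal output and a truth
#' object describing the generating structure.
#'
#' @param cfg a `semg_simconfig`.
#' @return list with `recording` (a `semg_recording`, force in kg),
#'   `calibration` (an `mvc_calibration`) and `truth` (force in %MVC,
#'   coupled scales, band definitions, drift and noise settings).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "semg_simconfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  force_pct <- generate_force_profile(cfg)
  emg <- vapply(cfg$channels, function(ch) synthesize_semg(force_pct, cfg),
                numeric(length(force_pct)))
  emg <- matrix(emg, ncol = length(cfg$channels),
                dimnames = list(NULL, cfg$channels))
  max_emg <- apply(abs(emg), 2, max)
  max_emg[max_emg == 0] <- 1
  rec <- recording(emg, force_pct / 100 * cfg$mvc_force_kg, fs = cfg$fs,
                   subject_id = "synthetic", task = cfg$task)
  cal <- mvc_calibration(cfg$mvc_force_kg, max_emg)
  truth <- list(
    force_pct = force_pct,
    coupled_scales = cfg$band_defs$scale[cfg$band_defs$g1 != 0 |
                                           cfg$band_defs$g2 != 0],
    band_defs = cfg$band_defs,
    drift_rate = cfg$drift_rate, noise_sd = cfg$noise_sd
  )
  list(recording = rec, calibration = cal, truth = truth)
}
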