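# Independent oracles and small constructors shared across tests.

# Literal double-sum CWT: c_n = sum_{n'} x_{n'} psi((n' - n + ctr) / p),
# with psi looked up on the dyadic table. Independent of the package's
# padded tap-convolution implementation.
brute_cwt <- function(x, p, energy_norm = TRUE, level = 10) {
  tab <- db2_psi(level)
  N <- length(x)
  ctr <- (3L * p) %/% 2L
  out <- numeric(N)
  for (n in seq_len(N)) {
    np <- seq_len(N)
    arg <- (np - n + ctr) / p
    ok <- arg >= 0 & arg <= 3
    out[n] <- sum(x[ok] * tab$psi[round(arg[ok] * 2^level) + 1L])
  }
  if (energy_norm) out / sqrt(p) else out
}

# Var(a*U + b*U^2) for U ~ Uniform(0, B), from the moments
# E[U^k] = B^k / (k + 1).
closed_form_sensitivity <- function(a, b, B = 100) {
  a^2 * B^2 / 12 + b^2 * 4 * B^4 / 45 + 2 * a * b * B^3 / 12
}

# scale_features object from a bare intensity matrix
make_feats <- function(e, scales = NULL, frame_rate = 5, frame_size = 200) {
  if (is.null(scales)) scales <- seq_len(ncol(e))
  colnames(e) <- paste0("s", scales)
  structure(list(e = e, scales = as.integer(scales),
                 frame_size = frame_size, frame_rate = frame_rate,
                 smoothing_ms = 0),
            class = "scale_features")
}

make_model <- function(scales, theta1, theta2) {
  structure(list(scales = as.integer(scales), theta1 = theta1,
                 theta2 = theta2, intercept = 0,
                 fit_meta = list(n_frames = NA, rss = NA, rank = NA)),
            class = "semg_force_model")
}

# mean power of a series after trimming filter transients
trimmed_power <- function(x, trim = 500) {
  mean(x[(trim + 1):(length(x) - trim)]^2)
}
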