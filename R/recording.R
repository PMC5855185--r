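#' Construct an SEMG/force recording
#'
#' A recording bundles one or more surface-EMG channels with the
#' synchronously sampled handgrip force and the common sampling rate.
#' All series must have the same length and contain only finite values.
#'
#' @param emg numeric vector or matrix (one column per channel) of SEMG
#'   amplitudes in mV. Column names identify channels; a bare vector gets
#'   the channel name `"emg"`.
#' @param force numeric vector of handgrip force. Raw recordings are in kg;
#'   after [normalize_mvc()] the series is on the %MVC (0-100) scale.
#' @param fs sampling rate in Hz, shared by all series.
#' @param subject_id optional subject label.
#' @param task one of `"analysis"`, `"static"`, `"force_varying"`.
#' @param normalized logical; `TRUE` once the recording has been normalized
#'   by MVC calibration (EMG as fraction of maximal amplitude, force in %MVC).
#' @return An object of class `semg_recording`.
#' @seealso [read_recording()], [normalize_mvc()], [segment_minutes()]
#' @export
recording <- function(emg, force, fs, subject_id = NA_character_,
                      task = c("analysis", "static", "force_varying"),
                      normalized = FALSE) {
  task <- match.arg(task)
  if (is.null(dim(emg))) {
    emg <- matrix(emg, ncol = 1, dimnames = list(NULL, "emg"))
  }
  emg <- as.matrix(emg)
  if (is.null(colnames(emg))) {
    colnames(emg) <- paste0("emg", seq_len(ncol(emg)))
  }
  force <- as.numeric(force)
  if (nrow(emg) != length(force)) {
    stop("emg and force series must have equal length")
  }
  if (nrow(emg) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (!all(is.finite(emg))) stop("emg values must be finite")
  if (!all(is.finite(force))) stop("force values must be finite")
  structure(
    list(emg = emg, force = force, fs = fs,
         subject_id = subject_id, task = task, normalized = normalized),
    class = "semg_recording"
  )
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> %d samples @ %g Hz (%.1f s), channels: %s\n",
    n_samples(x), x$fs, n_samples(x) / x$fs,
    paste(channels(x), collapse = ", ")
  ))
  cat(sprintf("  task: %s | subject: %s | force units: %s\n",
              x$task, x$subject_id,
              if (isTRUE(x$normalized)) "%MVC" else "kg"))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `semg_recording`.
#' @export
n_samples <- function(rec) nrow(rec$emg)

#' Channel names of a recording
#' @param rec a `semg_recording`.
#' @export
channels <- function(rec) colnames(rec$emg)

#' MVC calibration values
#'
#' Maximal-voluntary-contraction calibration: the subject's maximal grip
#' force (kg) and maximal SEMG amplitude (mV) per channel, obtained from
#' repeated MVC trials and averaged. Used to express recordings on the
#' normalized %MVC / fraction-of-maximum scale.
#'
#' @param max_force maximal grip force in kg (> 0).
#' @param max_emg maximal SEMG amplitude in mV: a single positive number, or
#'   a named vector with one entry per channel.
#' @return An object of class `mvc_calibration`.
#' @export
mvc_calibration <- function(max_force, max_emg) {
  if (!is.numeric(max_force) || length(max_force) != 1L ||
      !is.finite(max_force) || max_force <= 0) {
    stop("max_force must be a single positive number")
  }
  if (!is.numeric(max_emg) || any(!is.finite(max_emg)) || any(max_emg <= 0)) {
    stop("max_emg must be positive")
  }
  structure(list(max_force = max_force, max_emg = max_emg),
            class = "mvc_calibration")
}

#' Read a recording from a delimited text file
#'
#' Reads a comma-separated file with a header row (`.` decimal separator),
#' one row per sample, and maps columns to EMG channels and force through
#' `schema`.
#'
#' @param path path to the CSV file.
#' @param schema named list with elements `emg` (character vector of EMG
#'   column names; names of that vector, if any, become channel names) and
#'   `force` (force column name). A `time` element is accepted and ignored
#'   for data purposes (time is implicit in the sample index).
#' @param fs sampling rate in Hz (CSV files carry no rate metadata).
#' @param subject_id,task,normalized passed to [recording()].
#' @return A `semg_recording`.
#' @export
read_recording <- function(path, schema = list(emg = "emg", force = "force"),
                           fs = 1000, subject_id = NA_character_,
                           task = "analysis", normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  need <- c(schema$emg, schema$force)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(as.character(v)))
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                     col, bad[1]))
      }
      df[[col]] <- vn
    }
    if (anyNA(df[[col]])) {
      stop(sprintf("parse error: missing value in column '%s' at row %d",
                   col, which(is.na(df[[col]]))[1]))
    }
  }
  emg <- as.matrix(df[schema$emg])
  ch <- names(schema$emg)
  colnames(emg) <- if (!is.null(ch) && all(nzchar(ch))) ch else schema$emg
  recording(emg, df[[schema$force]], fs = fs, subject_id = subject_id,
            task = task, normalized = normalized)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: writes `time_s`, one column per EMG
#' channel, and `force`.
#'
#' @param rec a `semg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = (seq_len(n_samples(rec)) - 1) / rec$fs,
                   check.names = FALSE)
  for (ch in channels(rec)) df[[ch]] <- rec$emg[, ch]
  df$force <- rec$force
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the filtered SEMG keeps zero phase lag
#' relative to the force channel. Defaults match the 15-450 Hz SEMG
#' acquisition band.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (of the underlying one-pass design).
#' @return filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 15, high = 450, order = 4) {
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) {
    stop(sprintf("Nyquist violation: high = %g Hz >= fs/2 = %g Hz",
                 high, fs / 2))
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Normalize a recording by MVC calibration
#'
#' Converts force from kg to %MVC (`100 * force / max_force`) and each EMG
#' channel to a fraction of its maximal amplitude. All model fitting and
#' RMSE reporting downstream operates on the %MVC (0-100) scale.
#'
#' @param rec a raw `semg_recording` (force in kg).
#' @param cal an [mvc_calibration()].
#' @return a `semg_recording` with `normalized = TRUE`.
#' @export
normalize_mvc <- function(rec, cal) {
  stopifnot(inherits(rec, "semg_recording"), inherits(cal, "mvc_calibration"))
  max_emg <- cal$max_emg
  if (length(max_emg) == 1L) {
    max_emg <- rep(max_emg, ncol(rec$emg))
    names(max_emg) <- channels(rec)
  }
  if (!all(channels(rec) %in% names(max_emg))) {
    stop("max_emg must provide a value for every channel")
  }
  emg <- sweep(rec$emg, 2, max_emg[channels(rec)], "/")
  recording(emg, 100 * rec$force / cal$max_force, fs = rec$fs,
            subject_id = rec$subject_id, task = rec$task, normalized = TRUE)
}

#' Undo MVC normalization
#'
#' Round-trip companion of [normalize_mvc()]; mainly useful for checks.
#' @param rec a normalized `semg_recording`.
#' @param cal the calibration used for normalization.
#' @export
denormalize_mvc <- function(rec, cal) {
  stopifnot(isTRUE(rec$normalized))
  max_emg <- cal$max_emg
  if (length(max_emg) == 1L) {
    max_emg <- rep(max_emg, ncol(rec$emg))
    names(max_emg) <- channels(rec)
  }
  emg <- sweep(rec$emg, 2, max_emg[channels(rec)], "*")
  recording(emg, rec$force * cal$max_force / 100, fs = rec$fs,
            subject_id = rec$subject_id, task = rec$task, normalized = FALSE)
}

subset_recording <- function(rec, idx) {
  recording(rec$emg[idx, , drop = FALSE], rec$force[idx], fs = rec$fs,
            subject_id = rec$subject_id, task = rec$task,
            normalized = rec$normalized)
}

#' Split a recording into consecutive segments
#'
#' Cuts a recording into non-overlapping segments of `segment_s` seconds
#' (per-minute segmentation of the force-varying analysis task by default).
#' A trailing partial segment shorter than half a segment is dropped;
#' otherwise it is kept as a final (shorter) segment.
#'
#' @param rec a `semg_recording`.
#' @param segment_s segment length in seconds (> 0).
#' @return list of `semg_recording` segments.
#' @export
segment_minutes <- function(rec, segment_s = 60) {
  if (!is.numeric(segment_s) || segment_s <= 0) stop("segment_s must be > 0")
  N <- n_samples(rec)
  len <- floor(segment_s * rec$fs)
  if (len > N) {
    warning("segment longer than recording; returning a single segment")
    return(list(rec))
  }
  full <- N %/% len
  tail_len <- N - full * len
  segs <- lapply(seq_len(full), function(i) {
    subset_recording(rec, ((i - 1) * len + 1):(i * len))
  })
  if (tail_len >= len / 2) {
    segs <- c(segs, list(subset_recording(rec, (full * len + 1):N)))
  }
  segs
}
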