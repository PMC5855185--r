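#' Rank wavelet scales by mean sensitivity
#'
#' Arranges the ten scales in ascending order of mean sensitivity; ties are
#' broken in favor of the smaller scale number.
#'
#' @param mean_sensitivity numeric vector of ten finite per-scale values,
#'   ordered by scale number 1..10 (names are ignored).
#' @return integer permutation of 1..10, ascending sensitivity.
#' @export
rank_scales <- function(mean_sensitivity) {
  if (length(mean_sensitivity) != 10L) {
    stop("expected sensitivity values for exactly ten scales")
  }
  if (!all(is.finite(mean_sensitivity))) stop("sensitivities must be finite")
  order(mean_sensitivity, seq_along(mean_sensitivity))
}

#' Build the ten nested wavelet scale combinations
#'
#' Sequence combination analysis keeps low-sensitivity scales and
#' eliminates the most sensitive remaining scale in turn: combination I is
#' all ten scales, combination II drops the most sensitive one, ..., and
#' combination X is the single least sensitive scale. Combination k
#' therefore has `11 - k` scales and each combination is nested in its
#' predecessor.
#'
#' @param ranking permutation of 1..10 in ascending sensitivity order
#'   (from [rank_scales()]).
#' @return list of ten objects of class `scale_combination`, each with
#'   `serial` (Roman numeral I..X), `ordinal` (1..10) and `scales`
#'   (ascending scale numbers).
#' @export
generate_combinations <- function(ranking) {
  if (!identical(sort(as.integer(ranking)), 1:10)) {
    stop("ranking must be a permutation of 1..10")
  }
  ranking <- as.integer(ranking)
  lapply(1:10, function(k) {
    structure(
      list(serial = as.character(utils::as.roman(k)), ordinal = k,
           scales = sort(ranking[seq_len(11L - k)])),
      class = "scale_combination"
    )
  })
}

#' @export
print.scale_combination <- function(x, ...) {
  cat(sprintf("<scale_combination> %s: {%s}\n", x$serial,
              paste(x$scales, collapse = ",")))
  invisible(x)
}

#' Evaluate the ten combinations by validation RMSE
#'
#' For every combination the polynomial model is refit on the training
#' features restricted to that combination's scales, force is predicted on
#' the validation features, and both the overall RMSE and a windowed RMSE
#' series (time-varying error curve, default 10-s windows) are computed.
#' A combination whose fit fails or predicts non-finite values is flagged
#' and excluded from selection.
#'
#' @param combos list of `scale_combination`s (from
#'   [generate_combinations()]).
#' @param train,validation lists with elements `features` (a
#'   `scale_features`) and `force` (%MVC at frame rate), index-aligned.
#' @param window_s window for the RMSE time series, seconds (default 10).
#' @return object of class `selection_report`: `table` (one row per
#'   combination: serial, size, scales, mean/overall/min/max RMSE,
#'   flag), `windowed` (list of RMSE series), `models` (list of fitted
#'   models) and `window_s`.
#' @export
evaluate_combinations <- function(combos, train, validation, window_s = 10) {
  frame_rate <- train$features$frame_rate
  width <- max(1L, round(window_s * frame_rate))
  rows <- list()
  models <- list()
  wrs <- list()
  for (cmb in combos) {
    model <- tryCatch(
      suppressWarnings(
        fit_polynomial_model(train$features, train$force, cmb$scales)),
      error = function(e) NULL)
    flagged <- is.null(model)
    wr <- rep(NA_real_, 0)
    overall <- NA_real_
    if (!flagged) {
      pred <- predict_force(model, validation$features)
      if (!all(is.finite(pred))) {
        flagged <- TRUE
      } else {
        overall <- rmse(validation$force, pred)
        wr <- windowed_rmse(validation$force, pred, width)
      }
    }
    rows[[cmb$serial]] <- data.frame(
      serial = cmb$serial, ordinal = cmb$ordinal,
      n_scales = length(cmb$scales),
      scales = paste(cmb$scales, collapse = ","),
      rmse_mean = if (flagged) NA_real_ else mean(wr),
      rmse_overall = overall,
      rmse_min = if (flagged) NA_real_ else min(wr),
      rmse_max = if (flagged) NA_real_ else max(wr),
      flagged = flagged,
      stringsAsFactors = FALSE
    )
    models[[cmb$serial]] <- model
    wrs[[cmb$serial]] <- wr
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         windowed = wrs, models = models, combos = combos,
         window_s = window_s),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d combinations (windowed RMSE, %g-s windows)\n",
              nrow(x$table), x$window_s))
  print(x$table[, c("serial", "scales", "rmse_mean", "rmse_overall",
                    "rmse_min", "rmse_max", "flagged")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the best wavelet scale combination
#'
#' Picks the combination with the smallest mean windowed RMSE among the
#' non-flagged entries; ties go to the combination with fewer scales
#' (parsimony).
#'
#' @param report a `selection_report`.
#' @return the chosen `scale_combination`.
#' @export
select_combination <- function(report) {
  tab <- report$table
  ok <- which(!tab$flagged)
  if (length(ok) == 0L) stop("all combinations are flagged")
  best <- ok[order(tab$rmse_mean[ok], tab$n_scales[ok])][1]
  report$combos[[which(vapply(report$combos, function(cmb)
    cmb$serial == tab$serial[best], logical(1)))]]
}
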