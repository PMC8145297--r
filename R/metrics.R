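#' Per-well kinetic metrics
#'
#' Computes the curve metrics for one well: `rfu_initial` (the reading at
#' the starting point, the single t0 read), `rfu_max` (maximum reading over
#' the analysis window, t0 included), their ratio, whether the well crossed
#' the positivity threshold within the window, the lag phase (earliest
#' measured timepoint at or above threshold -- no interpolation, matching
#' the hourly read schedule), and whether any reading sits at instrument
#' saturation.
#'
#' @param rfu Numeric fluorescence series aligned to `times_h`.
#' @param times_h Read-time grid (hours).
#' @param threshold Positivity threshold (RFU), > 0.
#' @param window_h Analysis window in hours (default 40): metrics use reads
#'   with `time <= window_h` even when the run is longer.
#' @param saturation_rfu Instrument ceiling used for the saturated flag.
#' @return A one-row tibble with columns `rfu_initial`, `rfu_max`,
#'   `rfu_ratio`, `crossed`, `lag_h`, `saturated`, `window_h` and
#'   `ratio_undefined` (`TRUE` when `rfu_initial` is 0, in which case
#'   `rfu_ratio` is `NA` rather than an error).
#' @examples
#' compute_metrics(rep(1000, 41), 0:40, threshold = 20000)
#' @export
compute_metrics <- function(rfu, times_h, threshold,
                            window_h = DEFAULT_WINDOW_H,
                            saturation_rfu = DEFAULT_SATURATION_RFU) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  if (!is.numeric(window_h) || length(window_h) != 1 || window_h <= 0) {
    abort("`window_h` must be a single positive number.")
  }
  if (length(rfu) != length(times_h)) {
    abort("`rfu` and `times_h` must have the same length.")
  }
  if (anyNA(rfu)) abort("Fluorescence series contains missing values.")

  in_window <- times_h <= window_h
  rfu_initial <- rfu[1]
  rfu_max <- max(rfu[in_window])
  ratio_undefined <- rfu_initial == 0
  rfu_ratio <- if (ratio_undefined) NA_real_ else rfu_max / rfu_initial
  above <- in_window & rfu >= threshold
  crossed <- any(above)
  lag_h <- if (crossed) min(times_h[above]) else NA_real_
  tibble::tibble(
    rfu_initial = rfu_initial, rfu_max = rfu_max, rfu_ratio = rfu_ratio,
    crossed = crossed, lag_h = lag_h,
    saturated = any(rfu == saturation_rfu),
    window_h = window_h, ratio_undefined = ratio_undefined
  )
}

#' Kinetic metrics for every non-excluded well of a plate
#'
#' @param plate A [plate_run()].
#' @param threshold Positivity threshold in RFU (typically
#'   `plate_threshold(plate, rules)$threshold_rfu`).
#' @param window_h Analysis window; defaults to the plate's own.
#' @return A tibble with one row per non-excluded well: well identity and
#'   sample mapping columns plus the [compute_metrics()] columns.
#' @export
well_metrics <- function(plate, threshold, window_h = plate$analysis_window_h) {
  stopifnot(inherits(plate, "plate_run"))
  meta <- plate$well_meta[!plate$well_meta$excluded, ]
  rows <- lapply(meta$well_id, function(w) {
    compute_metrics(plate$rfu[w, ], plate$times_h, threshold,
                    window_h = window_h,
                    saturation_rfu = plate$saturation_rfu)
  })
  dplyr::bind_cols(
    meta[, c("well_id", "sample_id", "dilution_exponent", "replicate_index",
             "is_control")],
    dplyr::bind_rows(rows)
  )
}
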