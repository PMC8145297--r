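#' Validate a read-time grid
#'
#' The read schedule of a plate run: nominally one read per hour, but
#' irregular spacing is representable. A grid must be strictly increasing,
#' start at or after 0 h, and contain at least 6 reads (five baseline reads
#' for the threshold plus at least one post-baseline read).
#'
#' @param times_h Numeric vector of read times, in hours.
#' @return The validated grid, invisibly as a plain numeric vector.
#' @export
validate_time_grid <- function(times_h) {
  if (!is.numeric(times_h) || length(times_h) < 6) {
    abort("A time grid needs at least 6 read times (5 baseline reads + 1).")
  }
  if (anyNA(times_h)) abort("Time grid contains missing values.")
  if (times_h[1] < 0) abort("Time grid must start at or after 0 h.")
  if (any(diff(times_h) <= 0)) abort("Time grid must be strictly increasing.")
  invisible(as.numeric(times_h))
}

#' Construct a validated RT-QuIC plate run
#'
#' The canonical in-memory representation of one plate: a read-time grid, a
#' wells x times fluorescence matrix, per-well metadata mapping wells to
#' samples/dilutions/replicates, and the instrument constants. All
#' downstream analysis consumes this object (plus a [rule_config()]); no
#' analysis function reads files directly.
#'
#' @param plate_id Single string identifying the plate.
#' @param times_h Read times in hours; see [validate_time_grid()].
#' @param rfu Numeric matrix of fluorescence readings (RFU), one row per
#'   well (rownames are well ids, e.g. `"A1"`), one column per read time.
#' @param well_meta Data frame with one row per well and columns `well_id`,
#'   `sample_id`, `subject_id`, `age_months`, `genotype`, `tissue`,
#'   `dilution_exponent` (integer <= 0; the dilution is 10^exponent relative
#'   to tissue, so -2 means 1% tissue homogenate), `replicate_index`,
#'   `is_control`. An optional logical `excluded` column marks wells dropped
#'   from analysis (default all `FALSE`).
#' @param saturation_rfu Instrument saturation ceiling in RFU. Readings at
#'   this value are retained and flagged saturated, never dropped:
#'   saturation still evidences positivity.
#' @param analysis_window_h Analysis window in hours; kinetic metrics are
#'   taken over `[0, analysis_window_h]`. If the run is shorter than the
#'   window the plate is flagged truncated.
#' @param clip_to_saturation If `TRUE`, readings above `saturation_rfu` are
#'   clipped down to it instead of raising an error.
#'
#' @return An object of class `plate_run` with fields `plate_id`, `times_h`,
#'   `rfu`, `well_meta` (a tibble), `saturation_rfu`, `analysis_window_h`
#'   and `truncated`.
#' @export
plate_run <- function(plate_id, times_h, rfu, well_meta,
                      saturation_rfu = DEFAULT_SATURATION_RFU,
                      analysis_window_h = DEFAULT_WINDOW_H,
                      clip_to_saturation = FALSE) {
  if (!is.character(plate_id) || length(plate_id) != 1 || is.na(plate_id)) {
    abort("`plate_id` must be a single string.")
  }
  times_h <- as.numeric(times_h)
  validate_time_grid(times_h)
  if (!is.matrix(rfu) || !is.numeric(rfu)) abort("`rfu` must be a numeric matrix.")
  if (ncol(rfu) != length(times_h)) {
    abort(sprintf("`rfu` has %d columns but the time grid has %d reads.",
                  ncol(rfu), length(times_h)))
  }
  if (is.null(rownames(rfu))) abort("`rfu` must have well ids as rownames.")
  colnames(rfu) <- NULL
  if (anyDuplicated(rownames(rfu))) abort("Duplicate well ids in `rfu` rownames.")
  if (!is.numeric(saturation_rfu) || length(saturation_rfu) != 1 || saturation_rfu <= 0) {
    abort("`saturation_rfu` must be a single positive number.")
  }
  if (!is.numeric(analysis_window_h) || length(analysis_window_h) != 1 ||
      analysis_window_h <= 0) {
    abort("`analysis_window_h` must be a single positive number.")
  }

  well_meta <- tibble::as_tibble(well_meta)
  required <- c("well_id", "sample_id", "subject_id", "age_months", "genotype",
                "tissue", "dilution_exponent", "replicate_index", "is_control")
  missing_cols <- setdiff(required, names(well_meta))
  if (length(missing_cols) > 0) {
    abort(paste0("`well_meta` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!("excluded" %in% names(well_meta))) well_meta$excluded <- FALSE
  well_meta$well_id <- as.character(well_meta$well_id)
  well_meta$dilution_exponent <- as.integer(well_meta$dilution_exponent)
  well_meta$replicate_index <- as.integer(well_meta$replicate_index)
  well_meta$is_control <- as.logical(well_meta$is_control)
  well_meta$excluded <- as.logical(well_meta$excluded)

  if (anyDuplicated(well_meta$well_id)) {
    abort("Duplicate well ids in `well_meta`.")
  }
  orphans <- setdiff(rownames(rfu), well_meta$well_id)
  if (length(orphans) > 0) {
    abort(paste0("Well(s) present in curves but absent from samplesheet: ",
                 paste(sort(orphans), collapse = ", ")))
  }
  unread <- setdiff(well_meta$well_id, rownames(rfu))
  if (length(unread) > 0) {
    abort(paste0("Well(s) in samplesheet with no fluorescence data: ",
                 paste(sort(unread), collapse = ", ")))
  }
  # align metadata rows with the matrix
  well_meta <- well_meta[match(rownames(rfu), well_meta$well_id), ]

  if (any(!is.finite(well_meta$dilution_exponent)) ||
      any(well_meta$dilution_exponent > 0)) {
    abort("`dilution_exponent` must be an integer <= 0 (10^exponent of tissue).")
  }
  key <- paste(well_meta$sample_id, well_meta$dilution_exponent,
               well_meta$replicate_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- well_meta$well_id[duplicated(key) | duplicated(key, fromLast = TRUE)]
    abort(paste0("Duplicate (sample, dilution, replicate) for wells: ",
                 paste(sort(dup), collapse = ", ")))
  }

  active <- !well_meta$excluded
  vals <- rfu[active, , drop = FALSE]
  if (anyNA(vals)) {
    bad <- rownames(vals)[apply(is.na(vals), 1, any)]
    abort(paste0("Missing fluorescence values in non-excluded well(s): ",
                 paste(sort(bad), collapse = ", ")))
  }
  if (any(vals < 0)) abort("Negative fluorescence values are not allowed.")
  if (any(vals > saturation_rfu)) {
    if (clip_to_saturation) {
      rfu[rfu > saturation_rfu] <- saturation_rfu
    } else {
      bad <- rownames(vals)[apply(vals > saturation_rfu, 1, any)]
      abort(paste0("Readings above saturation (", saturation_rfu,
                   " RFU) in well(s): ", paste(sort(bad), collapse = ", "),
                   ". Use clip_to_saturation/clip_on_read to clip."))
    }
  }

  structure(
    list(
      plate_id = plate_id,
      times_h = times_h,
      rfu = rfu,
      well_meta = well_meta,
      saturation_rfu = as.numeric(saturation_rfu),
      analysis_window_h = as.numeric(analysis_window_h),
      truncated = analysis_window_h > max(times_h)
    ),
    class = "plate_run"
  )
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf("<plate_run> %s: %d wells x %d reads (%g-%g h)\n",
              x$plate_id, nrow(x$rfu), length(x$times_h),
              min(x$times_h), max(x$times_h)))
  cat(sprintf("  %d samples, %d control wells, %d excluded wells\n",
              length(unique(x$well_meta$sample_id)),
              sum(x$well_meta$is_control), sum(x$well_meta$excluded)))
  cat(sprintf("  saturation %g RFU; analysis window %g h%s\n",
              x$saturation_rfu, x$analysis_window_h,
              if (x$truncated) " (run truncated before window end)" else ""))
  invisible(x)
}

#' Number of wells on a plate
#' @param plate A `plate_run`.
#' @return Integer count of wells.
#' @export
n_wells <- function(plate) {
  stopifnot(inherits(plate, "plate_run"))
  nrow(plate$rfu)
}

#' Default 96-well plate coordinates
#'
#' Row-major coordinates A1, A2, ..., H12 for assigning simulated wells.
#'
#' @param n Number of coordinates wanted (<= 96).
#' @return Character vector of well ids.
#' @export
plate_coordinates <- function(n = 96) {
  if (n > 96) abort("A 96-well plate has at most 96 wells.")
  all_ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  all_ids[seq_len(n)]
}
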