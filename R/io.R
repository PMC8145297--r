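#' Read an RT-QuIC plate from long-format curves and a samplesheet
#'
#' The canonical curve format is long CSV with columns
#' `plate_id, well_id, time_h, rfu` (header required, UTF-8, "." decimal);
#' long format is unambiguous for irregular read grids. The samplesheet maps
#' wells to samples with columns `well_id, sample_id, subject_id,
#' age_months, genotype, tissue, dilution_exponent, replicate_index,
#' is_control` (optional: `excluded`, `homogenate_percent`).
#'
#' The read grid is the sorted union of observed times and must be
#' identical across wells; ragged grids are a structural error naming the
#' offending wells. Wells present in the curves but absent from the
#' samplesheet are an error.
#'
#' @param curves Path to the long-format curves CSV.
#' @param samplesheet Path to the samplesheet CSV.
#' @param plate_id Plate to extract when the curves file holds several;
#'   with a single plate it may be omitted.
#' @param clip_on_read Clip readings above saturation instead of erroring.
#' @param saturation_rfu,analysis_window_h Instrument constants; see
#'   [plate_run()].
#' @return A validated [plate_run()].
#' @export
read_plate <- function(curves, samplesheet, plate_id = NULL,
                       clip_on_read = FALSE,
                       saturation_rfu = DEFAULT_SATURATION_RFU,
                       analysis_window_h = DEFAULT_WINDOW_H) {
  plates <- read_plates(curves, samplesheet, clip_on_read = clip_on_read,
                        saturation_rfu = saturation_rfu,
                        analysis_window_h = analysis_window_h)
  if (is.null(plate_id)) {
    if (length(plates) != 1) {
      abort(paste0("Curves file contains ", length(plates),
                   " plates; pass `plate_id` to select one."))
    }
    return(plates[[1]])
  }
  if (!plate_id %in% names(plates)) {
    abort(paste0("Plate '", plate_id, "' not found in curves file."))
  }
  plates[[plate_id]]
}

#' Read all plates from a long-format curves file
#'
#' @inheritParams read_plate
#' @return A named list of [plate_run()] objects, one per `plate_id`.
#' @export
read_plates <- function(curves, samplesheet, clip_on_read = FALSE,
                        saturation_rfu = DEFAULT_SATURATION_RFU,
                        analysis_window_h = DEFAULT_WINDOW_H) {
  # read numerics as text and convert via strtod: the fast CSV double
  # parser can be off by one ulp, which would break bit-exact round-trips
  curve_df <- readr::read_csv(
    curves,
    col_types = readr::cols(
      plate_id = readr::col_character(),
      well_id = readr::col_character(),
      time_h = readr::col_character(),
      rfu = readr::col_character()
    )
  )
  curve_df$time_h <- as.numeric(curve_df$time_h)
  curve_df$rfu <- as.numeric(curve_df$rfu)
  need <- c("plate_id", "well_id", "time_h", "rfu")
  missing_cols <- setdiff(need, names(curve_df))
  if (length(missing_cols) > 0) {
    abort(paste0("Curves file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  meta <- read_samplesheet(samplesheet)

  by_plate <- split(curve_df, curve_df$plate_id)
  plates <- lapply(names(by_plate), function(pid) {
    df <- by_plate[[pid]]
    dupe <- df[duplicated(df[, c("well_id", "time_h")]), ]
    if (nrow(dupe) > 0) {
      abort(paste0("Duplicate (well, time) reading(s) on plate ", pid, ": ",
                   paste(unique(dupe$well_id), collapse = ", ")))
    }
    grid <- sort(unique(df$time_h))
    counts <- table(df$well_id)
    ragged <- names(counts)[counts != length(grid)]
    # a well can also be ragged with the right count but wrong times
    if (length(ragged) == 0) {
      ok <- vapply(split(df$time_h, df$well_id),
                   function(t) identical(sort(t), grid), logical(1))
      ragged <- names(ok)[!ok]
    }
    if (length(ragged) > 0) {
      abort(paste0("Ragged time grid on plate ", pid,
                   "; well(s) not matching the common grid: ",
                   paste(sort(ragged), collapse = ", ")))
    }
    wide <- tidyr::pivot_wider(df[, c("well_id", "time_h", "rfu")],
                               names_from = "time_h", values_from = "rfu")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    rownames(mat) <- wide$well_id
    mat <- mat[, order(as.numeric(colnames(mat))), drop = FALSE]
    sheet <- meta
    if ("plate_id" %in% names(sheet)) {
      sheet <- sheet[sheet$plate_id == pid, names(sheet) != "plate_id"]
    }
    sheet <- sheet[sheet$well_id %in% rownames(mat), ]
    plate_run(pid, grid, mat, sheet,
              saturation_rfu = saturation_rfu,
              analysis_window_h = analysis_window_h,
              clip_to_saturation = clip_on_read)
  })
  setNames(plates, names(by_plate))
}

#' Read a samplesheet CSV
#' @param path Path to the samplesheet.
#' @return A tibble of well metadata.
#' @export
read_samplesheet <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(
    well_id = readr::col_character(),
    sample_id = readr::col_character(),
    subject_id = readr::col_character(),
    genotype = readr::col_character(),
    tissue = readr::col_character(),
    age_months = readr::col_integer(),
    dilution_exponent = readr::col_integer(),
    replicate_index = readr::col_integer(),
    is_control = readr::col_logical(),
    .default = readr::col_guess()
  ))
  need <- c("well_id", "sample_id", "subject_id", "age_months", "genotype",
            "tissue", "dilution_exponent", "replicate_index", "is_control")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("Samplesheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  meta
}

#' Read wide-format curves (convenience dialect)
#'
#' Wide format has a `time_h` column and one column per well. A `plate_id`
#' must be supplied since the format carries none.
#'
#' @param curves Path to the wide-format CSV.
#' @param samplesheet Path to the samplesheet CSV.
#' @param plate_id Plate identifier to assign.
#' @inheritParams read_plate
#' @return A validated [plate_run()].
#' @export
read_plate_wide <- function(curves, samplesheet, plate_id,
                            clip_on_read = FALSE,
                            saturation_rfu = DEFAULT_SATURATION_RFU,
                            analysis_window_h = DEFAULT_WINDOW_H) {
  df <- readr::read_csv(curves, col_types = readr::cols(
    time_h = readr::col_double(), .default = readr::col_double()
  ))
  if (!"time_h" %in% names(df)) abort("Wide curves need a `time_h` column.")
  long <- tidyr::pivot_longer(df, -"time_h",
                              names_to = "well_id", values_to = "rfu")
  long$plate_id <- plate_id
  tmp <- withr_tempfile()
  on.exit(unlink(tmp), add = TRUE)
  readr::write_csv(long[, c("plate_id", "well_id", "time_h", "rfu")], tmp)
  read_plate(tmp, samplesheet, plate_id = plate_id, clip_on_read = clip_on_read,
             saturation_rfu = saturation_rfu,
             analysis_window_h = analysis_window_h)
}

withr_tempfile <- function() tempfile(fileext = ".csv")

#' Write a plate run back to long curves + samplesheet CSVs
#'
#' Numeric fields round-trip bit-exactly through [read_plate()].
#'
#' @param plate A [plate_run()].
#' @param curves,samplesheet Output paths.
#' @return Invisibly, the curve tibble written.
#' @export
write_plate <- function(plate, curves, samplesheet) {
  stopifnot(inherits(plate, "plate_run"))
  long <- tibble::tibble(
    plate_id = plate$plate_id,
    well_id = rep(rownames(plate$rfu), each = length(plate$times_h)),
    time_h = rep(plate$times_h, times = nrow(plate$rfu)),
    rfu = as.vector(t(plate$rfu))
  )
  # 17 significant digits so doubles round-trip bit-exactly through CSV
  out <- long
  out$time_h <- sprintf("%.17g", out$time_h)
  out$rfu <- sprintf("%.17g", out$rfu)
  readr::write_csv(out, curves)
  readr::write_csv(plate$well_meta, samplesheet)
  invisible(long)
}

#' Serialize / parse endpoint dilutions
#'
#' Endpoints print as `"1e-5"`-style dilution literals; not-detectable
#' endpoints print as the literal `"ND"`, never an empty cell.
#'
#' @param exponent Integer dilution exponent(s); `NA` means not detectable.
#' @return `format_endpoint()`: character; `parse_endpoint()`: integer with
#'   `NA` for `"ND"`.
#' @export
format_endpoint <- function(exponent) {
  ifelse(is.na(exponent), "ND", sprintf("1e%d", as.integer(exponent)))
}

#' @rdname format_endpoint
#' @param x Character endpoint literals (`"ND"` or `"1e-5"` style).
#' @export
parse_endpoint <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  num <- grepl("^1e-?[0-9]+$", x)
  out[num] <- as.integer(sub("^1e", "", x[num]))
  bad <- !num & toupper(x) != "ND"
  if (any(bad)) {
    abort(paste0("Unparseable endpoint literal(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Write per-well metrics and per-sample calls to one CSV
#'
#' One row per well (record_type `"well"`) carrying the kinetic metrics and
#' one row per sample x dilution (record_type `"sample"`) carrying the call;
#' the file round-trips losslessly through [read_calls()]. Threshold
#' provenance is carried on every row.
#'
#' @param calls A `plate_calls` object from [call_plate()], or a list with
#'   elements `threshold`, `well_metrics` and `sample_calls`.
#' @param path Output CSV path.
#' @return Invisibly, the combined tibble written.
#' @export
write_calls <- function(calls, path) {
  wm <- calls$well_metrics
  sc <- calls$sample_calls
  if (is.null(wm) || is.null(sc) || nrow(wm) == 0 || nrow(sc) == 0) {
    abort("`calls` must contain non-empty well metrics and sample calls.")
  }
  thr <- calls$threshold
  well_rows <- tibble::tibble(
    record_type = "well",
    plate_id = thr$plate_id,
    well_id = wm$well_id,
    sample_id = wm$sample_id,
    dilution_exponent = wm$dilution_exponent,
    replicate_index = wm$replicate_index,
    rfu_initial = wm$rfu_initial,
    rfu_max = wm$rfu_max,
    rfu_ratio = wm$rfu_ratio,
    crossed = wm$crossed,
    lag_h = wm$lag_h,
    saturated = wm$saturated,
    n_positive_wells = NA_integer_,
    n_replicates = NA_integer_,
    call = NA_character_,
    spontaneous_flag = NA,
    threshold_rfu = thr$threshold_rfu,
    window_h = wm$window_h
  )
  sample_rows <- tibble::tibble(
    record_type = "sample",
    plate_id = thr$plate_id,
    well_id = NA_character_,
    sample_id = sc$sample_id,
    dilution_exponent = sc$dilution_exponent,
    replicate_index = NA_integer_,
    rfu_initial = NA_real_,
    rfu_max = NA_real_,
    rfu_ratio = NA_real_,
    crossed = NA,
    lag_h = NA_real_,
    saturated = NA,
    n_positive_wells = sc$n_positive_wells,
    n_replicates = sc$n_replicates,
    call = sc$call,
    spontaneous_flag = sc$spontaneous_flag,
    threshold_rfu = thr$threshold_rfu,
    window_h = NA_real_
  )
  out <- dplyr::bind_rows(well_rows, sample_rows)
  readr::write_csv(out, path, na = "")
  invisible(out)
}

#' Read back a calls CSV written by [write_calls()]
#'
#' @param path Path to the calls CSV.
#' @return A list with tibbles `well_metrics` and `sample_calls`, and the
#'   scalar `threshold_rfu`.
#' @export
read_calls <- function(path) {
  df <- readr::read_csv(path, na = "", col_types = readr::cols(
    record_type = readr::col_character(),
    plate_id = readr::col_character(),
    well_id = readr::col_character(),
    sample_id = readr::col_character(),
    dilution_exponent = readr::col_integer(),
    replicate_index = readr::col_integer(),
    rfu_initial = readr::col_double(),
    rfu_max = readr::col_double(),
    rfu_ratio = readr::col_double(),
    crossed = readr::col_logical(),
    lag_h = readr::col_double(),
    saturated = readr::col_logical(),
    n_positive_wells = readr::col_integer(),
    n_replicates = readr::col_integer(),
    call = readr::col_character(),
    spontaneous_flag = readr::col_logical(),
    threshold_rfu = readr::col_double(),
    window_h = readr::col_double()
  ))
  wm <- df[df$record_type == "well",
           c("plate_id", "well_id", "sample_id", "dilution_exponent",
             "replicate_index", "rfu_initial", "rfu_max", "rfu_ratio",
             "crossed", "lag_h", "saturated", "threshold_rfu", "window_h")]
  sc <- df[df$record_type == "sample",
           c("plate_id", "sample_id", "dilution_exponent", "n_replicates",
             "n_positive_wells", "call", "spontaneous_flag", "threshold_rfu")]
  list(well_metrics = tibble::as_tibble(wm),
       sample_calls = tibble::as_tibble(sc),
       threshold_rfu = df$threshold_rfu[1])
}
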