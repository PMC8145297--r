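#' Summarize a cohort of titrated samples
#'
#' Collapses per-sample endpoint dilutions into the canonical cohort
#' layout -- one record per subject x tissue x age, endpoints printed as
#' dilution literals with ND preserved -- plus the derived statistics used
#' to compare tissues: positive counts per age x tissue among transgenic
#' subjects, the earliest age at which each tissue is positive, and, for
#' each subject assayed in both tissues, which tissue has the more dilute
#' endpoint (using the [seeding_rank()] total order, in which ND ranks
#' below a 10^-3 endpoint). Non-carrier controls with a positive endpoint
#' trigger a contamination warning.
#'
#' @param records Tibble with one row per subject x tissue: columns
#'   `subject_id`, `age_months`, `genotype` (`"transgenic"` /
#'   `"non_carrier"` vocabulary with free extension), `tissue`, and
#'   `endpoint_exponent` (integer, `NA` = ND). Extra columns are ignored.
#' @return An object of class `cohort_summary`: a list with
#'   * `cohort`: the records, one row per subject x tissue, with an
#'     `endpoint` literal column (`"1e-5"` style, `"ND"` preserved);
#'   * `positive_counts`: per age x tissue `n_positive` / `n_total`
#'     (transgenic subjects only);
#'   * `earliest_positive_age`: per tissue, earliest age (months) with any
#'     transgenic positive (`NA` if none);
#'   * `tissue_comparison`: per subject with both tissues, which tissue
#'     has the more dilute endpoint (`"brain"`, `"colon"`, or `"equal"`);
#'   * `control_warning`: `TRUE` when any non-transgenic record is
#'     positive.
#' @export
summarize_cohort <- function(records) {
  need <- c("subject_id", "age_months", "genotype", "tissue",
            "endpoint_exponent")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort records missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("Cohort records must cover at least 1 subject.")
  records <- tibble::as_tibble(records)[, union(need, names(records))]
  records$endpoint_exponent <- as.integer(records$endpoint_exponent)

  key <- paste(records$subject_id, records$tissue, records$age_months,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(records$subject_id[duplicated(key)])
    conflicting <- !all(tapply(records$endpoint_exponent, key, function(v)
      length(unique(v)) == 1))
    if (conflicting) {
      abort(paste0("Conflicting duplicate records for subject(s): ",
                   paste(dup, collapse = ", ")))
    }
    records <- records[!duplicated(key), ]
  }

  records$endpoint <- format_endpoint(records$endpoint_exponent)
  records <- dplyr::arrange(records, .data$age_months, .data$subject_id,
                            .data$tissue)

  tg <- records[records$genotype == "transgenic", ]
  positive_counts <- dplyr::summarise(
    dplyr::group_by(tg, .data$age_months, .data$tissue),
    n_positive = sum(!is.na(.data$endpoint_exponent)),
    n_total = dplyr::n(), .groups = "drop")

  pos_rows <- tg[!is.na(tg$endpoint_exponent), ]
  earliest <- if (nrow(pos_rows) == 0) {
    tibble::tibble(tissue = character(),
                   earliest_positive_age_months = integer())
  } else {
    dplyr::summarise(dplyr::group_by(pos_rows, .data$tissue),
                     earliest_positive_age_months = min(.data$age_months),
                     .groups = "drop")
  }
  all_tissues <- unique(records$tissue)
  earliest <- dplyr::left_join(tibble::tibble(tissue = all_tissues), earliest,
                               by = "tissue")

  # per-subject brain vs colon comparison where both assayed; pivot the
  # endpoint literals so "assayed but ND" stays distinct from "not assayed"
  wide <- tidyr::pivot_wider(
    records[, c("subject_id", "age_months", "genotype", "tissue", "endpoint")],
    names_from = "tissue", values_from = "endpoint")
  tissue_comparison <- NULL
  if (all(c("brain", "colon") %in% names(wide))) {
    both <- wide[!is.na(wide$brain) & !is.na(wide$colon),
                 c("subject_id", "age_months", "genotype", "brain", "colon")]
    eb <- parse_endpoint(both$brain)
    ec <- parse_endpoint(both$colon)
    rb <- seeding_rank(eb)
    rc <- seeding_rank(ec)
    both$more_dilute_tissue <- dplyr::case_when(
      rb > rc ~ "brain", rc > rb ~ "colon", .default = "equal")
    both$fold_difference <- ifelse(is.na(eb) | is.na(ec), NA_real_,
                                   10^abs(eb - ec))
    tissue_comparison <- tibble::as_tibble(both)
  }

  controls <- records[records$genotype != "transgenic", ]
  control_warning <- any(!is.na(controls$endpoint_exponent))
  if (control_warning) {
    warn(paste0("Non-carrier control(s) with a positive endpoint: ",
                paste(unique(controls$subject_id[
                  !is.na(controls$endpoint_exponent)]), collapse = ", "),
                " -- possible contamination or spontaneous seeding."))
  }

  structure(
    list(cohort = records, positive_counts = positive_counts,
         earliest_positive_age = earliest,
         tissue_comparison = tissue_comparison,
         control_warning = control_warning),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$positive_counts, n = Inf)
  cat("Earliest positive age (months) per tissue:\n")
  print(x$earliest_positive_age, n = Inf)
  if (x$control_warning) cat("WARNING: positive non-carrier control(s)\n")
  invisible(x)
}

#' Example G2-3 mouse cohort endpoint data
#'
#' Endpoint-dilution records for a cohort of G2-3 transgenic mice
#' (human A53T alpha-synuclein) and non-carrier controls assayed by
#' alpha-synuclein RT-QuIC in brain (brainstem/midbrain) and distal colon
#' at 1, 3, 6 and 12 months of age. At 1 month only colon was assayed.
#' `endpoint` is the most dilute positive dilution (`"ND"` = not
#' detectable at 10^-3); `tested_to` records the most dilute exponent
#' actually tested where known (some series were not tested beyond their
#' endpoint).
#'
#' @return A tibble with columns `subject_id`, `age_months`, `genotype`,
#'   `tissue`, `endpoint`, `endpoint_exponent` (parsed, `NA` = ND) and
#'   `tested_to`.
#' @export
g2_3_cohort <- function() {
  path <- system.file("extdata", "g2_3_cohort.csv", package = "rtquic",
                      mustWork = TRUE)
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    age_months = readr::col_integer(),
    genotype = readr::col_character(),
    tissue = readr::col_character(),
    endpoint = readr::col_character(),
    tested_to = readr::col_integer()
  ))
  df$endpoint_exponent <- parse_endpoint(df$endpoint)
  df
}
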