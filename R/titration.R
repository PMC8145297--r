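#' Seeding-activity rank of an endpoint dilution
#'
#' Total order used for all endpoint comparisons:
#' `ND < 10^-3 < 10^-4 < ...` -- a more dilute endpoint means more seeding
#' activity. Positive endpoints map to `-exponent` (so 10^-8 ranks 8) and
#' ND sits exactly one step below the least dilute tested level (rank 2,
#' one below 10^-3). ND is never treated as zero or as a titre.
#'
#' @param exponent Integer endpoint exponent(s); `NA` means ND.
#' @return Numeric rank(s).
#' @export
seeding_rank <- function(exponent) {
  ifelse(is.na(exponent), 2, -as.numeric(exponent))
}

#' Endpoint dilution of one sample's titration series
#'
#' The endpoint is the most dilute (most negative) exponent with a positive
#' call; ND (not detectable) when no tested exponent is positive. Series
#' that are non-monotone -- a positive call more dilute than some negative
#' call -- are allowed and flagged rather than truncated at the first
#' negative, because low dilutions (10^-3) can be weakened by reaction
#' inhibitors; `inhibited_low_dilution_flag` marks the specific pattern of
#' a negative at -3 with a positive at a more dilute exponent.
#'
#' @param calls Tibble with one row per tested dilution of a single sample:
#'   columns `dilution_exponent` and `call` (`"positive"`/`"negative"`),
#'   plus optionally `sample_id`.
#' @return A one-row tibble: `sample_id` (if supplied), `endpoint_exponent`
#'   (integer, `NA` = ND), `nd`, `monotone`,
#'   `inhibited_low_dilution_flag`, `min_exponent_tested`,
#'   `max_exponent_tested`.
#' @examples
#' endpoint_dilution(tibble::tibble(
#'   dilution_exponent = -3:-5,
#'   call = c("positive", "positive", "negative")))
#' @export
endpoint_dilution <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) abort("Empty call map.")
  if (!all(c("dilution_exponent", "call") %in% names(calls))) {
    abort("`calls` needs columns `dilution_exponent` and `call`.")
  }
  if (!all(calls$call %in% c("positive", "negative"))) {
    abort("Calls must be 'positive' or 'negative'.")
  }
  if (anyDuplicated(calls$dilution_exponent)) {
    abort("Duplicate dilution exponents in call map.")
  }
  e <- as.integer(calls$dilution_exponent)
  pos <- calls$call == "positive"
  endpoint <- if (any(pos)) min(e[pos]) else NA_integer_
  # non-monotone: some positive call is more dilute than some negative call
  monotone <- !(any(pos) && any(!pos) && min(e[pos]) < max(e[!pos]))
  inhibited <- (-3L %in% e) && !pos[match(-3L, e)] && any(pos & e < -3L)
  out <- tibble::tibble(
    endpoint_exponent = endpoint,
    nd = is.na(endpoint),
    monotone = monotone,
    inhibited_low_dilution_flag = inhibited,
    min_exponent_tested = min(e),
    max_exponent_tested = max(e)
  )
  if ("sample_id" %in% names(calls)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = calls$sample_id[1]), out)
  }
  out
}

#' Titrate every sample in a table of calls
#'
#' @param sample_calls Tibble of per-sample x dilution calls (e.g. the
#'   `sample_calls` element of [call_plate()]).
#' @return One [endpoint_dilution()] row per sample.
#' @export
titrate_calls <- function(sample_calls) {
  groups <- split(sample_calls, sample_calls$sample_id)
  dplyr::bind_rows(lapply(groups, endpoint_dilution))
}

#' Fold difference in seeding level between two titrated samples
#'
#' Endpoint dilutions are semi-quantitative: a sample whose endpoint is k
#' ten-fold dilution steps more dilute carries 10^k times more seeding
#' activity. Returns the factor by which `a`'s seeding level exceeds `b`'s
#' (> 1 when `a`'s endpoint is the more dilute). When either endpoint is
#' ND the fold is undefined and flagged, never a number.
#'
#' @param a,b One-row titration tibbles (from [endpoint_dilution()]) or
#'   bare integer endpoint exponents (`NA` = ND).
#' @return A one-row tibble: `fold` (numeric, `NA` when undefined) and
#'   `defined` (logical).
#' @examples
#' fold_difference(-8L, -5L) # 1000: a exceeds b a thousand-fold
#' @export
fold_difference <- function(a, b) {
  get_e <- function(x) {
    if (is.data.frame(x)) x$endpoint_exponent[1] else as.integer(x[1])
  }
  ea <- get_e(a)
  eb <- get_e(b)
  if (is.na(ea) || is.na(eb)) {
    return(tibble::tibble(fold = NA_real_, defined = FALSE))
  }
  tibble::tibble(fold = 10^(eb - ea), defined = TRUE)
}
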