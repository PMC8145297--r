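#' Per-plate positivity threshold
#'
#' The ThT fluorescence threshold of a plate is the mean of the pooled
#' first `n_baseline_reads` measurements of every non-excluded well
#' (controls included by default -- they are seeded reactions like any
#' other) plus `sd_multiplier` times the sample standard deviation of that
#' same pooled set. One pooled mean and one pooled SD are computed over all
#' well x baseline-read values; the SD uses the n-1 denominator.
#'
#' @param plate A [plate_run()].
#' @param rules A [rule_config()].
#' @return An object of class `threshold_result`: `plate_id`,
#'   `threshold_rfu`, `n_baseline_reads`, `sd_multiplier`,
#'   `n_wells_pooled`, `pooled_mean`, `pooled_sd`.
#' @export
plate_threshold <- function(plate, rules = rule_config()) {
  stopifnot(inherits(plate, "plate_run"), inherits(rules, "rule_config"))
  keep <- !plate$well_meta$excluded
  if (!rules$include_controls_in_threshold) {
    keep <- keep & !plate$well_meta$is_control
  }
  wells <- plate$well_meta$well_id[keep]
  if (length(wells) < 2) {
    abort("Threshold needs at least 2 pooled wells.")
  }
  if (length(plate$times_h) < rules$n_baseline_reads) {
    abort(sprintf("Threshold needs %d baseline reads but the run has %d.",
                  rules$n_baseline_reads, length(plate$times_h)))
  }
  baseline <- plate$rfu[wells, seq_len(rules$n_baseline_reads), drop = FALSE]
  pooled <- as.vector(baseline)
  m <- mean(pooled)
  s <- sd(pooled)
  structure(
    list(plate_id = plate$plate_id,
         threshold_rfu = m + rules$sd_multiplier * s,
         n_baseline_reads = rules$n_baseline_reads,
         sd_multiplier = rules$sd_multiplier,
         n_wells_pooled = length(wells),
         pooled_mean = m, pooled_sd = s),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> plate %s: %.1f RFU (mean %.1f + %g x SD %.1f; %d wells x %d reads)\n",
    x$plate_id, x$threshold_rfu, x$pooled_mean, x$sd_multiplier, x$pooled_sd,
    x$n_wells_pooled, x$n_baseline_reads))
  invisible(x)
}

#' Call one sample x dilution group from its replicate wells
#'
#' A sample is positive at a dilution when at least
#' `min_positive_replicates` of its replicate wells crossed the plate
#' threshold (default: 2 of 4). A group in which exactly one well crossed
#' is called negative but flagged as a possible spontaneous positive --
#' the audit trail for occasional single-well responses in otherwise
#' negative samples.
#'
#' @param wells Tibble of [well_metrics()] rows for one sample x dilution
#'   group (all rows must share `sample_id` and `dilution_exponent`).
#' @param rules A [rule_config()].
#' @return A one-row tibble: `sample_id`, `dilution_exponent`,
#'   `n_replicates`, `n_positive_wells`, `call` (`"positive"` /
#'   `"negative"`), `spontaneous_flag`.
#' @export
call_sample <- function(wells, rules = rule_config()) {
  if (nrow(wells) == 0) abort("Empty replicate group.")
  if (length(unique(wells$sample_id)) != 1 ||
      length(unique(wells$dilution_exponent)) != 1) {
    abort("All wells in a group must share sample_id and dilution_exponent.")
  }
  n <- nrow(wells)
  if (n < rules$min_positive_replicates) {
    abort(sprintf(
      "Group %s @ 10^%d has %d replicate(s); rule needs at least %d to be satisfiable.",
      wells$sample_id[1], wells$dilution_exponent[1], n,
      rules$min_positive_replicates))
  }
  n_pos <- sum(wells$crossed)
  tibble::tibble(
    sample_id = wells$sample_id[1],
    dilution_exponent = wells$dilution_exponent[1],
    n_replicates = n,
    n_positive_wells = n_pos,
    call = if (n_pos >= rules$min_positive_replicates) "positive" else "negative",
    spontaneous_flag = n_pos == 1L
  )
}

#' Threshold, metrics and calls for a whole plate
#'
#' Computes the plate's own threshold, per-well kinetic metrics against it,
#' and one call per sample x dilution group. Deterministic: re-calling the
#' same plate reproduces identical output.
#'
#' @param plate A [plate_run()].
#' @param rules A [rule_config()].
#' @return An object of class `plate_calls`: a list with `threshold`
#'   (a `threshold_result`), `well_metrics` (tibble) and `sample_calls`
#'   (tibble, one row per sample x dilution).
#' @export
call_plate <- function(plate, rules = rule_config()) {
  thr <- plate_threshold(plate, rules)
  wm <- well_metrics(plate, thr$threshold_rfu)
  groups <- split(wm, paste(wm$sample_id, wm$dilution_exponent, sep = "\r"))
  sc <- dplyr::bind_rows(lapply(groups, call_sample, rules = rules))
  sc <- dplyr::arrange(sc, .data$sample_id, dplyr::desc(.data$dilution_exponent))
  structure(list(threshold = thr, well_metrics = wm, sample_calls = sc),
            class = "plate_calls")
}

#' @export
print.plate_calls <- function(x, ...) {
  print(x$threshold)
  n_pos <- sum(x$sample_calls$call == "positive")
  cat(sprintf("  %d wells -> %d sample x dilution calls (%d positive, %d flagged spontaneous)\n",
              nrow(x$well_metrics), nrow(x$sample_calls), n_pos,
              sum(x$sample_calls$spontaneous_flag)))
  invisible(x)
}
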