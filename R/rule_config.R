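#' Analysis rule configuration
#'
#' Bundles the parameters of the positivity-calling procedure: how the
#' per-plate ThT fluorescence threshold is formed (baseline reads pooled
#' across wells, mean plus a multiple of the pooled standard deviation) and
#' how replicate wells are aggregated into a sample call.
#'
#' The defaults encode the standard protocol: threshold = mean of the first
#' five measurements of all wells + 10 SD; a sample is positive when at
#' least two of its four replicate wells cross that threshold.
#'
#' @param n_baseline_reads Number of initial reads per well pooled into the
#'   threshold estimate. Default 5.
#' @param sd_multiplier Multiple of the pooled standard deviation added to
#'   the pooled baseline mean. Default 10.
#' @param min_positive_replicates Minimum number of threshold-crossing wells
#'   for a positive sample call. Default 2.
#' @param expected_replicates Nominal replicate wells per sample x dilution.
#'   Default 4 (quadruplicates).
#' @param include_controls_in_threshold Should non-carrier control wells be
#'   pooled into the threshold? Default `TRUE`: controls are seeded
#'   reactions like any other and the threshold uses all wells on the plate.
#' @param lag_convention How the lag phase is read off the curve. The single
#'   supported value is `"first_at_or_above"`: the earliest measured
#'   timepoint whose reading is at or above threshold, no interpolation.
#'
#' @return An object of class `rule_config`.
#' @examples
#' rule_config()
#' rule_config(sd_multiplier = 5)
#' @export
rule_config <- function(n_baseline_reads = 5,
                        sd_multiplier = 10,
                        min_positive_replicates = 2,
                        expected_replicates = 4,
                        include_controls_in_threshold = TRUE,
                        lag_convention = "first_at_or_above") {
  if (!is.numeric(n_baseline_reads) || length(n_baseline_reads) != 1 ||
      n_baseline_reads != round(n_baseline_reads) || n_baseline_reads < 2) {
    abort("`n_baseline_reads` must be a single integer >= 2.")
  }
  if (!is.numeric(sd_multiplier) || length(sd_multiplier) != 1 ||
      !is.finite(sd_multiplier) || sd_multiplier <= 0) {
    abort("`sd_multiplier` must be a single positive number.")
  }
  if (!is.numeric(min_positive_replicates) || length(min_positive_replicates) != 1 ||
      min_positive_replicates != round(min_positive_replicates) ||
      min_positive_replicates < 1) {
    abort("`min_positive_replicates` must be a single integer >= 1.")
  }
  if (!is.numeric(expected_replicates) || length(expected_replicates) != 1 ||
      expected_replicates != round(expected_replicates) ||
      expected_replicates < min_positive_replicates) {
    abort("`expected_replicates` must be an integer >= `min_positive_replicates`.")
  }
  lag_convention <- match.arg(lag_convention, "first_at_or_above")
  structure(
    list(
      n_baseline_reads = as.integer(n_baseline_reads),
      sd_multiplier = as.numeric(sd_multiplier),
      min_positive_replicates = as.integer(min_positive_replicates),
      expected_replicates = as.integer(expected_replicates),
      include_controls_in_threshold = isTRUE(include_controls_in_threshold),
      lag_convention = lag_convention
    ),
    class = "rule_config"
  )
}

#' Read a rule configuration from YAML or JSON
#'
#' Unknown keys are an error so that typos in rule files never silently
#' fall back to defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file whose keys
#'   are a subset of the [rule_config()] arguments.
#' @return A `rule_config`.
#' @export
read_rule_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(rule_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown rule config field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(rule_config, raw)
}

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config>\n")
  cat(sprintf("  threshold: mean of first %d reads of all wells + %g SD\n",
              x$n_baseline_reads, x$sd_multiplier))
  cat(sprintf("  call: positive iff >= %d of %d replicates cross\n",
              x$min_positive_replicates, x$expected_replicates))
  cat(sprintf("  controls pooled into threshold: %s\n",
              x$include_controls_in_threshold))
  cat(sprintf("  lag convention: %s\n", x$lag_convention))
  invisible(x)
}
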