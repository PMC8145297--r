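# In-code fixtures and independent oracles shared across tests.

# Minimal samplesheet for n wells named A1, A2, ... (one sample per
# quadruplicate block by default).
toy_meta <- function(well_ids, sample_id = "S1", dilution_exponent = -3L,
                     is_control = FALSE) {
  tibble::tibble(
    well_id = well_ids,
    sample_id = sample_id,
    subject_id = sample_id,
    age_months = 12L,
    genotype = "transgenic",
    tissue = "brain",
    dilution_exponent = as.integer(dilution_exponent),
    replicate_index = seq_along(well_ids),
    is_control = is_control
  )
}

# Plate whose wells each hold a constant fluorescence level.
constant_plate <- function(levels, n_reads = 6, times_h = NULL,
                           plate_id = "toy") {
  times_h <- times_h %||% seq(0, n_reads - 1)
  ids <- rtquic::plate_coordinates(length(levels))
  rfu <- matrix(rep(levels, each = length(times_h)),
                nrow = length(levels), byrow = TRUE,
                dimnames = list(ids, NULL))
  rtquic::plate_run(plate_id, times_h, rfu, toy_meta(ids))
}

# Plate from an explicit wells x times matrix.
matrix_plate <- function(rfu, times_h = seq(0, ncol(rfu) - 1),
                         plate_id = "toy", meta = NULL) {
  if (is.null(rownames(rfu))) {
    rownames(rfu) <- rtquic::plate_coordinates(nrow(rfu))
  }
  meta <- meta %||% toy_meta(rownames(rfu))
  rtquic::plate_run(plate_id, times_h, rfu, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force threshold oracle: literally enumerates and pools
# the baseline readings well by well, read by read.
brute_force_threshold <- function(plate, n_baseline_reads = 5,
                                  sd_multiplier = 10) {
  pooled <- c()
  for (w in rownames(plate$rfu)) {
    if (plate$well_meta$excluded[plate$well_meta$well_id == w]) next
    for (k in seq_len(n_baseline_reads)) {
      pooled <- c(pooled, plate$rfu[w, k])
    }
  }
  m <- sum(pooled) / length(pooled)
  s <- sqrt(sum((pooled - m)^2) / (length(pooled) - 1))
  m + sd_multiplier * s
}

# Well-metrics stub for replicate-calling tests: only the fields
# call_sample() consumes.
crossing_group <- function(crossed, sample_id = "S1", exponent = -3L) {
  tibble::tibble(
    sample_id = sample_id,
    dilution_exponent = as.integer(exponent),
    crossed = as.logical(crossed)
  )
}

# Call map for titration tests from a signs vector, e.g. c(`-3` = TRUE).
call_map <- function(exponents, positive, sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id,
    dilution_exponent = as.integer(exponents),
    call = ifelse(positive, "positive", "negative")
  )
}
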