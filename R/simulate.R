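# Deterministic per-well RNG substreams: each well draws from its own seed
# derived by hashing (master seed, plate, sample, dilution, replicate), so
# adding or removing a well never perturbs any other well's draws.

# 31-ary polynomial string hash mod 2^31 - 1; doubles stay exact (< 2^53).
hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b + 1) %% 2147483647
  h
}

#' Per-well RNG substream seed
#'
#' Derives the deterministic seed of one well's private RNG substream by
#' hashing the master seed together with the well's identity
#' (plate, sample, dilution exponent, replicate). Because each well owns
#' its substream, adding or removing wells never changes any other well's
#' simulated data.
#'
#' @param seed Master integer seed.
#' @param plate_id,sample_id,dilution_exponent,replicate_index Well
#'   identity.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
well_seed <- function(seed, plate_id, sample_id, dilution_exponent,
                      replicate_index) {
  hash31(paste(seed, plate_id, sample_id, dilution_exponent, replicate_index,
               sep = "\x1f"))
}

# Run code under a local RNG seed, restoring global RNG state afterwards.
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Gaussian draw clamped at +/- clamp standard deviations. Used so baseline,
# plateau and lag-jitter draws stay inside the bands the generator is
# calibrated to; tails beyond ~2 sd are not part of the emulated phenology.
rnorm_clamped <- function(n, mean, sd, clamp) {
  pmin(pmax(rnorm(n, mean, sd), mean - clamp * sd), mean + clamp * sd)
}

#' Kinetic parameters of the synthetic ThT curve model
#'
#' Converted wells follow a logistic (sigmoidal) fluorescence curve
#' `F(t) = B + (P - B) / (1 + exp(-(t - T_lag) / tau)) + noise`, with the
#' lag midpoint `T_lag = lag_intercept_h + lag_slope_h_per_log10 *
#' max(0, -log10(dose)) + jitter`; unconverted wells stay at baseline plus
#' read noise. Defaults are calibrated to the two instrument anchors
#' (plate thresholds around 15,000-25,000 RFU; saturation at 260,000 RFU)
#' and to typical lag bands (strong doses cross threshold at 14-20 h;
#' near-endpoint wells up to ~26-34 h); they are calibration choices, not
#' measured values.
#'
#' @param baseline_rfu_mean,baseline_rfu_sd Per-well baseline level (RFU):
#'   mean and between-well SD.
#' @param plateau_rfu_mean,plateau_rfu_sd Converted-well plateau (RFU).
#' @param growth_tau_h Logistic time constant (hours).
#' @param lag_intercept_h Lag midpoint at unit or greater effective dose
#'   (hours).
#' @param lag_slope_h_per_log10 Added lag per decade of dose below 1
#'   (hours/decade).
#' @param lag_jitter_sd_h Well-to-well lag jitter SD (hours); draws clamped
#'   at 2 SD.
#' @param read_noise_sd_rfu Per-read measurement noise SD (RFU).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(baseline_rfu_mean = 4000,
                           baseline_rfu_sd = 1500,
                           plateau_rfu_mean = 180000,
                           plateau_rfu_sd = 20000,
                           growth_tau_h = 1.5,
                           lag_intercept_h = 20,
                           lag_slope_h_per_log10 = 5.5,
                           lag_jitter_sd_h = 0.9,
                           read_noise_sd_rfu = 800) {
  p <- list(baseline_rfu_mean = baseline_rfu_mean,
            baseline_rfu_sd = baseline_rfu_sd,
            plateau_rfu_mean = plateau_rfu_mean,
            plateau_rfu_sd = plateau_rfu_sd,
            growth_tau_h = growth_tau_h,
            lag_intercept_h = lag_intercept_h,
            lag_slope_h_per_log10 = lag_slope_h_per_log10,
            lag_jitter_sd_h = lag_jitter_sd_h,
            read_noise_sd_rfu = read_noise_sd_rfu)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  # jitter and noise may be zero (noiseless limit)
  bad <- setdiff(bad, c("lag_jitter_sd_h", "read_noise_sd_rfu")[
    c(p$lag_jitter_sd_h == 0, p$read_noise_sd_rfu == 0)])
  if (length(bad) > 0) {
    abort(paste0("Kinetic parameter(s) must be positive numbers: ",
                 paste(bad, collapse = ", ")))
  }
  if (p$plateau_rfu_mean <= p$baseline_rfu_mean) {
    abort("`plateau_rfu_mean` must exceed `baseline_rfu_mean`.")
  }
  structure(p, class = "kinetic_params")
}

#' Ground-truth description of one simulated sample
#'
#' `log10_titre` is the log10 seeding dose per reaction at dilution 10^0,
#' so the effective dose at dilution exponent `e` is
#' `10^(log10_titre + e)`. A titre of `-Inf` describes an unseeded sample
#' (e.g. a non-carrier control) that converts only spontaneously.
#' Inhibition at low dilutions (typically 10^-3, where tissue inhibitors
#' are not yet diluted out) is modelled as attenuation of both the
#' effective dose and the plateau.
#'
#' @param sample_id Unique sample label (e.g. `"12M-#2-brain"`).
#' @param log10_titre Log10 seeding dose at dilution 10^0; `-Inf` for
#'   unseeded.
#' @param subject_id,age_months,genotype,tissue Sample metadata carried
#'   into the samplesheet.
#' @param is_control Is this a non-carrier control sample?
#' @param p_spontaneous Per-well probability of a spontaneous (unseeded)
#'   positive over the run; must be in \[0, 0.05\].
#' @param inhibition_exponents Dilution exponents subject to inhibition
#'   (default `-3`).
#' @param inhibition_dose_factor,inhibition_plateau_factor Multipliers in
#'   (0, 1\] applied at inhibited exponents.
#' @return An object of class `sample_truth`.
#' @export
sample_truth <- function(sample_id, log10_titre,
                         subject_id = sample_id,
                         age_months = NA_integer_,
                         genotype = if (is_control) "non_carrier" else "transgenic",
                         tissue = "brain",
                         is_control = FALSE,
                         p_spontaneous = 0.01,
                         inhibition_exponents = -3L,
                         inhibition_dose_factor = 1,
                         inhibition_plateau_factor = 1) {
  if (!is.character(sample_id) || length(sample_id) != 1) {
    abort("`sample_id` must be a single string.")
  }
  if (!is.numeric(log10_titre) || length(log10_titre) != 1 || is.na(log10_titre)) {
    abort("`log10_titre` must be a number (or -Inf for unseeded).")
  }
  if (p_spontaneous < 0 || p_spontaneous > 0.05) {
    abort("`p_spontaneous` must lie in [0, 0.05].")
  }
  if (inhibition_dose_factor <= 0 || inhibition_dose_factor > 1 ||
      inhibition_plateau_factor <= 0 || inhibition_plateau_factor > 1) {
    abort("Inhibition factors must lie in (0, 1].")
  }
  structure(
    list(sample_id = sample_id, log10_titre = log10_titre,
         subject_id = subject_id, age_months = as.integer(age_months),
         genotype = genotype, tissue = tissue, is_control = isTRUE(is_control),
         p_spontaneous = p_spontaneous,
         inhibition_exponents = as.integer(inhibition_exponents),
         inhibition_dose_factor = inhibition_dose_factor,
         inhibition_plateau_factor = inhibition_plateau_factor),
    class = "sample_truth"
  )
}

#' Effective seeding dose of a sample at a dilution exponent
#'
#' @param truth A [sample_truth()].
#' @param dilution_exponent Integer dilution exponent (<= 0).
#' @return Non-negative effective dose, inhibition-scaled where applicable.
#' @export
effective_dose <- function(truth, dilution_exponent) {
  d <- 10^(truth$log10_titre + dilution_exponent)
  if (dilution_exponent %in% truth$inhibition_exponents) {
    d <- d * truth$inhibition_dose_factor
  }
  d
}

#' Single-hit conversion probability
#'
#' Under a single-hit Poisson nucleation model a well seeded with an
#' effective dose `d` of seeding units converts with probability
#' `1 - exp(-d)`: the probability that at least one seeding unit landed in
#' the reaction. This minimal model reproduces partial-well positivity
#' (2-3 of 4 wells) near the endpoint dilution.
#'
#' @param effective_dose Non-negative effective dose (dimensionless).
#' @return Conversion probability in \[0, 1); 0 at dose 0, monotone
#'   increasing.
#' @examples
#' conversion_probability(0)
#' conversion_probability(1) # 1 - exp(-1) ~ 0.632
#' @export
conversion_probability <- function(effective_dose) {
  if (any(!is.finite(effective_dose) & !is.infinite(effective_dose)) ||
      any(effective_dose < 0)) {
    abort("`effective_dose` must be non-negative.")
  }
  1 - exp(-effective_dose)
}

#' Simulate one well
#'
#' Draws conversion (Bernoulli with the single-hit probability of the
#' inhibition-scaled dose; unseeded wells convert only spontaneously with
#' `p_spontaneous`), then generates the fluorescence series: a logistic
#' rise from baseline to plateau around the lag midpoint for converted
#' wells, flat baseline otherwise, plus Gaussian read noise, clipped to
#' `[0, saturation_rfu]`. Spontaneous positives use the same curve with a
#' lag midpoint drawn uniformly in the final third of the run. All draws
#' come from a dedicated per-well substream, so results are reproducible
#' well by well.
#'
#' @param truth A [sample_truth()].
#' @param dilution_exponent Integer dilution exponent.
#' @param kinetic A [kinetic_params()].
#' @param times_h Read-time grid (hours), >= 6 reads.
#' @param seed Integer seed for this well's substream (see
#'   [simulate_plate()] for how per-well seeds are derived).
#' @param saturation_rfu Instrument ceiling (RFU).
#' @return A list with `rfu` (numeric vector along `times_h`), `converted`,
#'   `seed_converted`, `spontaneous` and `true_lag_h` (the logistic lag
#'   midpoint, `NA` if unconverted).
#' @export
simulate_well <- function(truth, dilution_exponent, kinetic, times_h, seed,
                          saturation_rfu = DEFAULT_SATURATION_RFU) {
  if (length(times_h) < 6) abort("Time grid needs at least 6 reads.")
  d <- effective_dose(truth, dilution_exponent)
  p_conv <- conversion_probability(d)
  run_end <- max(times_h)
  with_local_seed(seed, {
    # fixed draw order so every branch consumes the same stream layout
    u_conv <- runif(1)
    u_spont <- runif(1)
    baseline <- rnorm_clamped(1, kinetic$baseline_rfu_mean,
                              kinetic$baseline_rfu_sd, 2.5)
    baseline <- max(baseline, 100)
    plateau <- rnorm_clamped(1, kinetic$plateau_rfu_mean,
                             kinetic$plateau_rfu_sd, 2.5)
    jitter <- if (kinetic$lag_jitter_sd_h > 0) {
      rnorm_clamped(1, 0, kinetic$lag_jitter_sd_h, 2)
    } else {
      runif(1) * 0 # consume one draw to keep the layout fixed
    }
    u_lag_spont <- runif(1)
    noise <- if (kinetic$read_noise_sd_rfu > 0) {
      rnorm(length(times_h), 0, kinetic$read_noise_sd_rfu)
    } else {
      rep(0, length(times_h))
    }

    seed_converted <- u_conv < p_conv
    spontaneous <- !seed_converted && u_spont < truth$p_spontaneous
    converted <- seed_converted || spontaneous

    if (seed_converted) {
      t_lag <- kinetic$lag_intercept_h +
        kinetic$lag_slope_h_per_log10 * max(0, -log10(d)) + jitter
    } else if (spontaneous) {
      t_lag <- run_end * (2 / 3 + u_lag_spont / 3)
    } else {
      t_lag <- NA_real_
    }

    plateau_eff <- plateau
    if (converted && dilution_exponent %in% truth$inhibition_exponents) {
      plateau_eff <- plateau * truth$inhibition_plateau_factor
    }

    f <- if (converted) {
      baseline + (plateau_eff - baseline) /
        (1 + exp(-(times_h - t_lag) / kinetic$growth_tau_h))
    } else {
      rep(baseline, length(times_h))
    }
    rfu <- pmin(pmax(f + noise, 0), saturation_rfu)
    list(rfu = rfu, converted = converted, seed_converted = seed_converted,
         spontaneous = spontaneous, true_lag_h = t_lag)
  })
}

#' Simulation configuration for one plate
#'
#' @param plate_id Plate label.
#' @param samples List of [sample_truth()] objects (unique sample ids).
#' @param dilution_exponents Either a single integer vector applied to all
#'   samples or a named list (by sample id) of integer vectors; each series
#'   must be contiguous in steps of -1 (serial ten-fold dilutions).
#' @param kinetic A [kinetic_params()].
#' @param replicates Replicate wells per sample x dilution (default 4).
#' @param run_length_h Run length in hours (default 40).
#' @param read_interval_h Read spacing in hours (default 1).
#' @param seed Integer RNG seed (mandatory).
#' @param saturation_rfu,analysis_window_h Instrument constants.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(plate_id, samples, dilution_exponents,
                       kinetic = kinetic_params(), replicates = 4,
                       run_length_h = 40, read_interval_h = 1, seed,
                       saturation_rfu = DEFAULT_SATURATION_RFU,
                       analysis_window_h = DEFAULT_WINDOW_H) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  if (!all(vapply(samples, inherits, logical(1), "sample_truth"))) {
    abort("`samples` must be a list of sample_truth objects.")
  }
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!is.list(dilution_exponents)) {
    dilution_exponents <- setNames(rep(list(as.integer(dilution_exponents)),
                                       length(ids)), ids)
  }
  missing_dil <- setdiff(ids, names(dilution_exponents))
  if (length(missing_dil) > 0) {
    abort(paste0("No dilution series for sample(s): ",
                 paste(missing_dil, collapse = ", ")))
  }
  for (id in ids) {
    e <- as.integer(dilution_exponents[[id]])
    if (length(e) == 0 || any(e > 0) ||
        (length(e) > 1 && any(diff(e) != -1L))) {
      abort(paste0("Dilution series for ", id,
                   " must be contiguous exponent steps of -1 (e.g. -3,-4,-5)."))
    }
    dilution_exponents[[id]] <- e
  }
  n_wells_needed <- replicates *
    sum(vapply(dilution_exponents[ids], length, integer(1)))
  if (n_wells_needed > 96) {
    abort(sprintf("Configuration needs %d wells; a 96-well plate holds 96.",
                  n_wells_needed))
  }
  structure(
    list(plate_id = plate_id, samples = samples,
         dilution_exponents = dilution_exponents,
         kinetic = kinetic, replicates = as.integer(replicates),
         run_length_h = run_length_h, read_interval_h = read_interval_h,
         seed = as.integer(seed), saturation_rfu = saturation_rfu,
         analysis_window_h = analysis_window_h),
    class = "sim_config"
  )
}

#' Analytic endpoint dilution of a simulated sample
#'
#' The most dilute exponent at which the sample is expected to be called
#' positive: the smallest (most negative) exponent `e` in the tested series
#' with `P(at least min_positive_replicates of n wells convert) >= 0.5`,
#' where per-well conversion combines the single-hit probability of the
#' inhibition-scaled dose with the spontaneous rate. `NA` (not detectable)
#' when no tested exponent qualifies.
#'
#' @param truth A [sample_truth()].
#' @param exponents Integer vector of tested dilution exponents.
#' @param replicates Wells per dilution.
#' @param min_positive_replicates Positivity rule minimum (default 2).
#' @return Integer exponent or `NA` (ND).
#' @export
analytic_endpoint <- function(truth, exponents, replicates = 4,
                              min_positive_replicates = 2) {
  p_well <- vapply(exponents, function(e) {
    p <- conversion_probability(effective_dose(truth, e))
    1 - (1 - p) * (1 - truth$p_spontaneous)
  }, numeric(1))
  p_pos <- 1 - pbinom(min_positive_replicates - 1, replicates, p_well)
  ok <- exponents[p_pos >= 0.5]
  if (length(ok) == 0) NA_integer_ else as.integer(min(ok))
}

#' Simulate a whole plate with known ground truth
#'
#' Wells are laid out row-major (A1, A2, ...) in sample order. Output is
#' deterministic given the config seed, and each well draws from its own
#' substream keyed by (plate, sample, dilution, replicate).
#'
#' @param config A [sim_config()].
#' @param rules A [rule_config()]; used only to compute the analytic
#'   endpoint recorded in the sample truth table.
#' @return A list with `plate` (a [plate_run()]), `well_truth` (tibble:
#'   per-well effective dose, conversion status and true lag midpoint) and
#'   `sample_truth` (tibble: per-sample titre and analytic endpoint).
#' @export
simulate_plate <- function(config, rules = rule_config()) {
  stopifnot(inherits(config, "sim_config"))
  times_h <- seq(0, config$run_length_h, by = config$read_interval_h)
  layout <- dplyr::bind_rows(lapply(config$samples, function(tr) {
    tidyr::expand_grid(
      sample_id = tr$sample_id,
      dilution_exponent = config$dilution_exponents[[tr$sample_id]],
      replicate_index = seq_len(config$replicates)
    )
  }))
  layout$well_id <- plate_coordinates(nrow(layout))

  truth_by_id <- setNames(config$samples,
                          vapply(config$samples, `[[`, character(1), "sample_id"))
  rfu <- matrix(NA_real_, nrow = nrow(layout), ncol = length(times_h),
                dimnames = list(layout$well_id, NULL))
  wt <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    tr <- truth_by_id[[layout$sample_id[i]]]
    e <- layout$dilution_exponent[i]
    ws <- well_seed(config$seed, config$plate_id, tr$sample_id, e,
                    layout$replicate_index[i])
    sim <- simulate_well(tr, e, config$kinetic, times_h, ws,
                         saturation_rfu = config$saturation_rfu)
    rfu[i, ] <- sim$rfu
    wt[[i]] <- tibble::tibble(
      well_id = layout$well_id[i], sample_id = tr$sample_id,
      dilution_exponent = e, replicate_index = layout$replicate_index[i],
      effective_dose = effective_dose(tr, e),
      converted = sim$converted, seed_converted = sim$seed_converted,
      spontaneous = sim$spontaneous, true_lag_h = sim$true_lag_h
    )
  }
  well_truth <- dplyr::bind_rows(wt)

  meta <- dplyr::left_join(
    layout,
    dplyr::bind_rows(lapply(config$samples, function(tr) {
      tibble::tibble(sample_id = tr$sample_id, subject_id = tr$subject_id,
                     age_months = tr$age_months, genotype = tr$genotype,
                     tissue = tr$tissue, is_control = tr$is_control)
    })),
    by = "sample_id"
  )

  sample_tbl <- dplyr::bind_rows(lapply(config$samples, function(tr) {
    tibble::tibble(
      sample_id = tr$sample_id,
      log10_titre = tr$log10_titre,
      is_control = tr$is_control,
      analytic_endpoint = analytic_endpoint(
        tr, config$dilution_exponents[[tr$sample_id]],
        replicates = config$replicates,
        min_positive_replicates = rules$min_positive_replicates)
    )
  }))

  plate <- plate_run(config$plate_id, times_h, rfu, meta,
                     saturation_rfu = config$saturation_rfu,
                     analysis_window_h = config$analysis_window_h)
  list(plate = plate, well_truth = well_truth, sample_truth = sample_tbl)
}
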