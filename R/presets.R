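# Titre convention for presets: for an uninhibited sample, log10_titre = k
# puts unit effective dose at dilution 10^-k, where the 2-of-4 rule is met
# with probability ~0.86 and fails (~0.05) one dilution further -- so the
# analytic endpoint is -k. Colon samples carry inhibition at 10^-3 (dose
# x0.35, plateau x0.6); a colon endpoint of -3 under inhibition needs titre
# 3.4 so that -3 wells convert with probability ~0.59, reproducing
# partial-well (2-3 of 4) positivity at the least dilute step.
COLON_INHIBITION_DOSE <- 0.35
COLON_INHIBITION_PLATEAU <- 0.6

preset_sample <- function(subject, age, tissue, titre, is_control = FALSE) {
  sample_truth(
    sample_id = paste0(subject, "-", tissue),
    log10_titre = titre,
    subject_id = subject,
    age_months = age,
    tissue = tissue,
    is_control = is_control,
    inhibition_dose_factor = if (tissue == "colon") COLON_INHIBITION_DOSE else 1,
    inhibition_plateau_factor = if (tissue == "colon") COLON_INHIBITION_PLATEAU else 1
  )
}

#' Built-in cohort-style simulation presets
#'
#' One preset plate per age group of a G2-3 transgenic mouse cohort (three
#' transgenic subjects plus a non-carrier control), with per-sample titres
#' chosen so the analytic endpoint pattern matches the canonical study
#' design: colon seeding activity from 3 months (endpoints -3 to -4),
#' brain activity from 6 months in one subject (-3), and both tissues
#' positive at 12 months (brain up to -8 in one subject, colons all -5).
#' At 1 month only colons are assayed and all are negative. Brain series
#' run to 10^-5 (10^-8 for the strong 12-month brain); colon series to
#' 10^-5 (10^-4 at 1 and 3 months); controls are seeded at 10^-3 only.
#'
#' @param age One of `"12m"`, `"6m"`, `"3m"`, `"1m"`.
#' @param seed Integer RNG seed for the plate.
#' @param kinetic A [kinetic_params()].
#' @return A [sim_config()] for one plate.
#' @export
sim_preset <- function(age = c("12m", "6m", "3m", "1m"), seed,
                       kinetic = kinetic_params()) {
  age <- match.arg(age)
  a <- switch(age, "12m" = 12L, "6m" = 6L, "3m" = 3L, "1m" = 1L)
  pre <- toupper(age)
  sub <- function(i) paste0(pre, "-#", i)
  con <- paste0(pre, "-Con")

  if (age == "1m") {
    samples <- c(
      lapply(1:3, function(i) preset_sample(sub(i), a, "colon", -Inf)),
      list(preset_sample(con, a, "colon", -Inf, is_control = TRUE))
    )
    dil <- setNames(rep(list(c(-3L, -4L)), 4),
                    vapply(samples, `[[`, character(1), "sample_id"))
    return(sim_config(paste0("sim-", age), samples, dil, kinetic = kinetic,
                      seed = seed))
  }

  spec <- switch(age,
    "3m" = list(brain = c(-Inf, -Inf, -Inf), colon = c(4, 3.4, 3.4),
                brain_dil = list(-3:-5, -3:-5, -3:-5),
                colon_dil = list(-3:-5, -3:-4, -3:-4)),
    "6m" = list(brain = c(-Inf, 3, -Inf), colon = c(5, 5, 3.4),
                brain_dil = list(-3:-5, -3:-5, -3:-5),
                colon_dil = list(-3:-5, -3:-5, -3:-5)),
    "12m" = list(brain = c(5, 8, 5), colon = c(5, 5, 5),
                 brain_dil = list(-3:-5, -3:-8, -3:-5),
                 colon_dil = list(-3:-5, -3:-5, -3:-5))
  )
  samples <- list()
  dil <- list()
  for (i in 1:3) {
    sb <- preset_sample(sub(i), a, "brain", spec$brain[i])
    sc <- preset_sample(sub(i), a, "colon", spec$colon[i])
    samples <- c(samples, list(sb, sc))
    dil[[sb$sample_id]] <- as.integer(spec$brain_dil[[i]])
    dil[[sc$sample_id]] <- as.integer(spec$colon_dil[[i]])
  }
  for (tis in c("brain", "colon")) {
    sctrl <- preset_sample(con, a, tis, -Inf, is_control = TRUE)
    samples <- c(samples, list(sctrl))
    dil[[sctrl$sample_id]] <- -3L
  }
  sim_config(paste0("sim-", age), samples, dil, kinetic = kinetic, seed = seed)
}

#' Simulate a full four-age cohort
#'
#' Runs [sim_preset()] for every age group with per-plate seeds derived
#' from `seed`, returning the plates and pooled truth tables.
#'
#' @param seed Master integer seed.
#' @param ages Subset of the preset ages to simulate.
#' @param kinetic A [kinetic_params()].
#' @return A list with `plates` (named list of [plate_run()]), `well_truth`
#'   and `sample_truth` (pooled tibbles with a `plate_id` column).
#' @export
simulate_cohort <- function(seed, ages = c("12m", "6m", "3m", "1m"),
                            kinetic = kinetic_params()) {
  sims <- lapply(seq_along(ages), function(i) {
    simulate_plate(sim_preset(ages[i], seed = (seed + i) %% 2147483647,
                              kinetic = kinetic))
  })
  names(sims) <- ages
  list(
    plates = lapply(sims, `[[`, "plate"),
    well_truth = dplyr::bind_rows(lapply(sims, function(s)
      dplyr::mutate(s$well_truth, plate_id = s$plate$plate_id, .before = 1))),
    sample_truth = dplyr::bind_rows(lapply(sims, function(s)
      dplyr::mutate(s$sample_truth, plate_id = s$plate$plate_id, .before = 1)))
  )
}
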