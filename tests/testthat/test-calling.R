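test_that("plate threshold matches hand computation and brute-force oracle", {
  # all wells constant: SD = 0, threshold equals the constant
  p_const <- constant_plate(rep(1000, 4))
  thr <- plate_threshold(p_const)
  expect_equal(thr$threshold_rfu, 1000)
  expect_equal(thr$pooled_sd, 0)

  # two wells, first five reads all-100 and all-200: pooled set of ten
  # values; mean 150, sample SD sqrt(25000/9), threshold 677.046...
  p2 <- constant_plate(c(100, 200))
  thr2 <- plate_threshold(p2)
  expect_equal(thr2$pooled_mean, 150)
  expect_equal(thr2$pooled_sd, sqrt(25000 / 9))
  expect_equal(thr2$threshold_rfu, 150 + 10 * sqrt(25000 / 9),
               tolerance = 1e-12)
  expect_equal(thr2$threshold_rfu, 677.05, tolerance = 1e-5)
  expect_equal(thr2$n_wells_pooled, 2L)

  # brute-force equivalence on random small plates (<= 8 wells x 6 reads)
  set.seed(77)
  for (i in 1:20) {
    nw <- sample(2:8, 1)
    rfu <- matrix(runif(nw * 6, 100, 30000), nrow = nw,
                  dimnames = list(plate_coordinates(nw), NULL))
    plate <- matrix_plate(rfu)
    got <- plate_threshold(plate)
    want <- brute_force_threshold(plate)
    expect_equal(got$threshold_rfu, want, tolerance = 1e-9)
    # formula identity: threshold - mean == multiplier x SD exactly
    expect_equal(got$threshold_rfu - got$pooled_mean,
                 got$sd_multiplier * got$pooled_sd, tolerance = 1e-9)
  }
})

test_that("threshold respects exclusions, control pooling and preconditions", {
  p <- constant_plate(c(100, 100, 100, 900))
  p$well_meta$excluded[4] <- TRUE
  thr <- plate_threshold(p)
  expect_equal(thr$threshold_rfu, 100)
  expect_equal(thr$n_wells_pooled, 3L)

  pc <- constant_plate(c(100, 100, 500, 500))
  pc$well_meta$is_control[3:4] <- TRUE
  pc$well_meta$sample_id[3:4] <- "ctrl"
  pc$well_meta$subject_id[3:4] <- "ctrl"
  thr_with <- plate_threshold(pc)
  thr_without <- plate_threshold(
    pc, rule_config(include_controls_in_threshold = FALSE))
  expect_gt(thr_with$threshold_rfu, thr_without$threshold_rfu)
  expect_equal(thr_without$threshold_rfu, 100)

  one_well <- constant_plate(100)
  expect_error(plate_threshold(one_well), "at least 2")
  p6 <- constant_plate(c(100, 100))
  expect_error(plate_threshold(p6, rule_config(n_baseline_reads = 7)),
               "baseline reads")
})

test_that("every replicate crossing pattern is called by the 2-of-4 rule", {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (i in seq_len(nrow(patterns))) {
    crossed <- unlist(patterns[i, ])
    call <- call_sample(crossing_group(crossed))
    n_pos <- sum(crossed)
    expect_equal(call$n_positive_wells, n_pos)
    expect_identical(call$call,
                     if (n_pos >= 2) "positive" else "negative")
    expect_identical(call$spontaneous_flag, n_pos == 1)
    # a flagged spontaneous group is always negative under default rules
    if (call$spontaneous_flag) expect_identical(call$call, "negative")
  }
})

test_that("call_sample validates its replicate group", {
  expect_error(call_sample(crossing_group(logical(0))), "Empty")
  mixed <- dplyr::bind_rows(crossing_group(TRUE, sample_id = "A"),
                            crossing_group(TRUE, sample_id = "B"))
  expect_error(call_sample(mixed), "share")
  expect_error(call_sample(crossing_group(TRUE)), "satisfiable")
})

test_that("calling is monotone in the rule parameters", {
  sim <- simulate_plate(sim_preset("6m", seed = 13))
  plate <- sim$plate

  mults <- c(5, 10, 20, 40)
  n_pos_wells <- vapply(mults, function(m) {
    pc <- call_plate(plate, rule_config(sd_multiplier = m))
    sum(pc$well_metrics$crossed)
  }, numeric(1))
  expect_true(all(diff(n_pos_wells) <= 0))

  pc2 <- call_plate(plate, rule_config(min_positive_replicates = 2))
  pc1 <- call_plate(plate, rule_config(min_positive_replicates = 1))
  was_pos <- pc2$sample_calls$call == "positive"
  still_pos <- pc1$sample_calls$call[was_pos] == "positive"
  expect_true(all(still_pos))
})

test_that("call_plate is deterministic and flat plates are all-negative", {
  flat <- constant_plate(rep(1000, 8), n_reads = 10)
  # flat plate has SD ~ 0 so threshold ~ the constant and every well
  # "crosses"; add small distinct levels so the threshold sits above all
  lv <- seq(1000, 1140, by = 20)
  flat <- constant_plate(lv, n_reads = 10)
  pc <- call_plate(flat)
  expect_true(all(pc$sample_calls$call == "negative"))
  expect_equal(sum(pc$well_metrics$crossed), 0)

  sim <- simulate_plate(sim_preset("12m", seed = 8))
  a <- call_plate(sim$plate)
  b <- call_plate(sim$plate)
  expect_identical(a$threshold$threshold_rfu, b$threshold$threshold_rfu)
  expect_identical(a$sample_calls, b$sample_calls)
  expect_identical(a$well_metrics, b$well_metrics)
})

test_that("calls recover the generator's ground-truth 2-of-4 status", {
  agree <- c()
  spont_only <- TRUE
  for (s in 1:3) {
    co <- simulate_cohort(s)
    for (age in names(co$plates)) {
      plate <- co$plates[[age]]
      pc <- call_plate(plate)
      truth <- co$well_truth[co$well_truth$plate_id == plate$plate_id, ]
      tg <- dplyr::summarise(
        dplyr::group_by(truth, sample_id, dilution_exponent),
        truth_pos = sum(converted) >= 2, .groups = "drop")
      m <- dplyr::left_join(pc$sample_calls, tg,
                            by = c("sample_id", "dilution_exponent"))
      ok <- (m$call == "positive") == m$truth_pos
      agree <- c(agree, ok)
    }
  }
  expect_gte(length(agree), 200)
  expect_gte(mean(agree), 0.99)
})
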