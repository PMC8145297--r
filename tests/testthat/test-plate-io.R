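test_that("a plate round-trips bit-exactly through write_plate/read_plate", {
  set.seed(42)
  rfu <- matrix(runif(8 * 7, 500, 5000), nrow = 8,
                dimnames = list(plate_coordinates(8), NULL))
  meta <- toy_meta(plate_coordinates(8))
  meta$sample_id <- rep(c("S1", "S2"), each = 4)
  meta$subject_id <- meta$sample_id
  meta$replicate_index <- rep(1:4, 2)
  plate <- plate_run("p1", c(0, 1, 2, 3.5, 4, 5, 6), rfu, meta)

  curves <- tempfile(fileext = ".csv")
  sheet <- tempfile(fileext = ".csv")
  write_plate(plate, curves, sheet)
  back <- read_plate(curves, sheet)

  expect_identical(back$plate_id, plate$plate_id)
  expect_identical(back$times_h, plate$times_h)
  expect_identical(back$rfu[rownames(plate$rfu), ], plate$rfu,
                   ignore_attr = FALSE)
  expect_equal(back$well_meta[order(back$well_meta$well_id), ],
               plate$well_meta[order(plate$well_meta$well_id), ])
})

test_that("structural problems in curve files are named errors", {
  meta <- toy_meta(c("A1", "A2", "B7"))
  sheet <- tempfile(fileext = ".csv")
  curves <- tempfile(fileext = ".csv")

  # well present in curves but missing from the samplesheet
  readr::write_csv(meta[meta$well_id != "B7", ], sheet)
  grid <- tidyr::expand_grid(well_id = c("A1", "A2", "B7"), time_h = 0:5)
  grid$plate_id <- "p1"
  grid$rfu <- 1000
  readr::write_csv(grid[, c("plate_id", "well_id", "time_h", "rfu")], curves)
  expect_error(read_plate(curves, sheet), "B7")

  # ragged grid: one well short of the common time set
  readr::write_csv(meta, sheet)
  ragged <- grid[!(grid$well_id == "A1" & grid$time_h == 5), ]
  readr::write_csv(ragged[, c("plate_id", "well_id", "time_h", "rfu")], curves)
  expect_error(read_plate(curves, sheet), "A1")

  # duplicated (well, time) reading
  dup <- rbind(grid, grid[1, ])
  readr::write_csv(dup[, c("plate_id", "well_id", "time_h", "rfu")], curves)
  expect_error(read_plate(curves, sheet), "Duplicate")
})

test_that("readings above saturation error unless clipping is requested", {
  meta <- toy_meta(c("A1", "A2"))
  sheet <- tempfile(fileext = ".csv")
  curves <- tempfile(fileext = ".csv")
  readr::write_csv(meta, sheet)
  grid <- tidyr::expand_grid(well_id = c("A1", "A2"), time_h = 0:5)
  grid$plate_id <- "p1"
  grid$rfu <- ifelse(grid$well_id == "A1" & grid$time_h == 5, 300000, 1000)
  readr::write_csv(grid[, c("plate_id", "well_id", "time_h", "rfu")], curves)

  expect_error(read_plate(curves, sheet), "saturation")
  clipped <- read_plate(curves, sheet, clip_on_read = TRUE)
  expect_equal(unname(clipped$rfu["A1", 6]), 260000)
})

test_that("the wide-format dialect reads the same plate as long format", {
  sim <- simulate_plate(sim_preset("1m", seed = 7))
  curves <- tempfile(fileext = ".csv")
  sheet <- tempfile(fileext = ".csv")
  write_plate(sim$plate, curves, sheet)

  wide <- tidyr::pivot_wider(
    readr::read_csv(curves, show_col_types = FALSE)[, -1],
    names_from = "well_id", values_from = "rfu")
  wide_path <- tempfile(fileext = ".csv")
  readr::write_csv(wide, wide_path)

  p_wide <- read_plate_wide(wide_path, sheet, plate_id = sim$plate$plate_id)
  p_long <- read_plate(curves, sheet)
  expect_equal(p_wide$rfu[rownames(p_long$rfu), ], p_long$rfu)
  expect_identical(p_wide$times_h, p_long$times_h)
})

test_that("calls round-trip losslessly and empty calls are rejected", {
  sim <- simulate_plate(sim_preset("3m", seed = 3))
  pc <- call_plate(sim$plate)
  path <- tempfile(fileext = ".csv")
  write_calls(pc, path)
  back <- read_calls(path)

  expect_equal(back$sample_calls$sample_id, pc$sample_calls$sample_id)
  expect_equal(back$sample_calls$n_positive_wells,
               pc$sample_calls$n_positive_wells)
  expect_equal(back$sample_calls$call, pc$sample_calls$call)
  expect_equal(back$sample_calls$spontaneous_flag,
               pc$sample_calls$spontaneous_flag)
  expect_equal(back$well_metrics$rfu_ratio, pc$well_metrics$rfu_ratio)
  expect_equal(back$well_metrics$lag_h, pc$well_metrics$lag_h)
  expect_equal(back$threshold_rfu, pc$threshold$threshold_rfu)

  expect_error(write_calls(list(well_metrics = NULL, sample_calls = NULL),
                           tempfile()), "non-empty")
})

test_that("ND endpoints serialize as the literal 'ND', never an empty cell", {
  expect_identical(format_endpoint(c(-5L, NA, -8L)), c("1e-5", "ND", "1e-8"))
  expect_identical(parse_endpoint(c("1e-5", "ND", "1e-8")), c(-5L, NA, -8L))
  expect_error(parse_endpoint("none"), "Unparseable")

  tit <- titrate_calls(call_map(-3:-4, c(FALSE, FALSE)))
  tit$endpoint <- format_endpoint(tit$endpoint_exponent)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tit[, c("sample_id", "endpoint")], path, na = "")
  expect_match(readLines(path)[2], "ND")
})

test_that("time grid and well metadata invariants are enforced", {
  expect_error(validate_time_grid(c(0, 1, 2)), "at least 6")
  expect_error(validate_time_grid(c(0, 1, 1, 2, 3, 4)), "increasing")
  expect_error(validate_time_grid(c(-1, 0, 1, 2, 3, 4)), "after 0")

  rfu <- matrix(1000, 2, 6, dimnames = list(c("A1", "A2"), NULL))
  meta <- toy_meta(c("A1", "A2"))
  meta$dilution_exponent <- c(1L, -3L) # positive exponent forbidden
  expect_error(plate_run("p", 0:5, rfu, meta), "exponent")

  meta <- toy_meta(c("A1", "A2"))
  meta$replicate_index <- c(1L, 1L) # duplicate (sample, dilution, replicate)
  expect_error(plate_run("p", 0:5, rfu, meta), "Duplicate")
})
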