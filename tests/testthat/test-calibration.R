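fake_records <- function(rt, di, mds = seq(60, by = 5, length.out = length(rt))) {
  structure(data.frame(date = as.Date("2025-05-01") + seq_along(rt) - 1L,
                       mxsd_um = 6000 + cumsum(di), mnsd_um = 5900,
                       mds_um = mds, di_um = di, rt_h = rt,
                       n_valid = 48L),
            class = c("indicator_records", "data.frame"))
}

test_that("growth arrest requires both failed recovery and non-positive DI", {
  rt <- c(5, 5, 6, 5, 24, 5, 24)
  di <- c(NA, 20, 18, 15, 2, 10, -5)
  a <- detect_growth_arrest(fake_records(rt, di))
  expect_true(a$arrest)
  expect_equal(a$row, 7L)  # rt = 24 with di = +2 on day 5 is not arrest

  none <- detect_growth_arrest(fake_records(c(5, 24, 5), c(NA, 4, 6)))
  expect_false(none$arrest)
  expect_true(is.na(none$date))

  expect_error(detect_growth_arrest(fake_records(24, -1)), "2 consecutive")
})

test_that("arrest threshold is the arithmetic mean of per-replicate arrest MDS", {
  reps <- lapply(c(84.57, 99.7, 117.17), function(m)
    fake_records(c(5, 24), c(NA, -1), mds = c(50, m)))
  names(reps) <- paste0("r", 1:3)
  cal <- calibrate_arrest_threshold(reps)
  expect_equal(cal$mean_arrest_mds_um, 100.48)
  expect_equal(nrow(cal$per_replicate), 3L)

  single <- calibrate_arrest_threshold(reps[1])
  expect_equal(single$mean_arrest_mds_um, 84.57)

  healthy <- list(a = fake_records(c(5, 5), c(NA, 10)))
  expect_error(calibrate_arrest_threshold(healthy), "no replicate")
  expect_error(calibrate_arrest_threshold(list()), "no replicate")
})

test_that("SPC baseline: mean + 1 sigma UCL and its capture fraction", {
  # affine-standardised sample with exact mean 51.5 and sd 21.7
  set.seed(15)
  z <- rnorm(200)
  x <- 51.5 + 21.7 * (z - mean(z)) / sd(z)
  spc <- spc_baseline(x)
  expect_equal(spc$mean_mds, 51.5)
  expect_equal(spc$sd_mds, 21.7)
  expect_equal(spc$ucl, 73.2)

  const <- spc_baseline(rep(50, 10L))
  expect_equal(const$sd_mds, 0)
  expect_equal(const$ucl, 50)
  expect_equal(const$capture_fraction, 1)

  # Gaussian capture of a 1-sigma limit is about pnorm(1) = 0.841
  set.seed(16)
  big <- spc_baseline(rnorm(1e4, 50, 10))
  expect_equal(big$capture_fraction, 0.841, tolerance = 0.01)

  expect_error(spc_baseline(5), "at least 2")
})

test_that("fraction of field capacity reproduces every worked-example cell", {
  expect_equal(compute_ppv(17.0, 26.0), 0.65)
  expect_equal(compute_ppv(26.0, 26.0), 1.00)
  expect_equal(compute_ppv(16.2, 26.0), 0.62)
  df <- stress_worked_examples()
  expect_equal(compute_ppv(df$swc_pct, 26.0), df$ppv)
  # linear in swc at fixed capacity; unity at capacity
  expect_equal(compute_ppv(13, 26), compute_ppv(26, 26) / 2)
  expect_error(compute_ppv(10, 0), "positive")
})

test_that("the recommended trigger rounds the UCL down to the nearest 5 um", {
  reps <- list(r1 = fake_records(c(5, 24), c(NA, -2), mds = c(50, 95)))
  set.seed(17)
  z <- rnorm(500)
  base <- 51.5 + 21.7 * (z - mean(z)) / sd(z)
  cal <- calibrate_thresholds(reps, base, arrest_day_vwc = c(17.2, 16.8))
  expect_equal(cal$spc$ucl, 73.2)
  expect_equal(cal$recommended_mds_threshold, 70)
  expect_equal(cal$threshold_provenance, "spc")
  expect_equal(cal$recommended_vwc_threshold, 17)
  expect_equal(cal$arrest_ppv, 0.65)

  manual <- calibrate_thresholds(reps, base, mds_threshold = 80)
  expect_equal(manual$recommended_mds_threshold, 80)
  expect_equal(manual$threshold_provenance, "manual")

  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(cal, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$recommended_mds_threshold_um, 70)
  expect_equal(back$spc$ucl, 73.2)
})

test_that("arrest calibration recovers the generator's ground truth", {
  # noise-free: detected day and MDS match the bookkeeping exactly
  for (seed in 1:3) {
    scn <- generate_scenario(scenario_config(
      days = 16, regime = "sunny", drought_mode = "progressive",
      residual_structure = FALSE, noise_sd = 0, seed = seed))
    recs <- lapply(seq_len(3L), function(j)
      cycle_indicators(stem_series(scn$stem$time,
                                   scn$stem$values[, j, drop = FALSE])))
    cal <- calibrate_arrest_threshold(recs)
    expect_true(all(cal$per_replicate$arrest_date == scn$truth$arrest_day))
    expect_equal(cal$mean_arrest_mds_um, scn$truth$arrest_mds, tolerance = 1e-9)
    expect_equal(scn$truth$arrest_mds, 90, tolerance = 6)
  }
  # replicate noise (sd 5 um): detected day within one day of truth on
  # average, per seed
  for (seed in 1:5) {
    scn <- generate_scenario(scenario_config(
      days = 16, regime = "sunny", drought_mode = "progressive",
      residual_structure = FALSE, noise_sd = 5, seed = seed))
    recs <- lapply(seq_len(3L), function(j)
      cycle_indicators(stem_series(scn$stem$time,
                                   scn$stem$values[, j, drop = FALSE])))
    cal <- calibrate_arrest_threshold(recs)
    day_err <- abs(as.numeric(cal$per_replicate$arrest_date - scn$truth$arrest_day))
    expect_lte(mean(day_err, na.rm = TRUE), 1)
  }
})
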