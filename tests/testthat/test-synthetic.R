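test_that("noise-free cycles realise the configured template amplitude", {
  cfg <- scenario_config(days = 5, regime = "sunny", drought_mode = "none",
                         residual_structure = FALSE, noise_sd = 0,
                         n_replicates = 1L, seed = 41)
  scn <- generate_scenario(cfg)
  rec <- cycle_indicators(aggregate_replicates(scn$stem))
  expect_equal(rec$mds_um, scn$truth$daily$amplitude, tolerance = 1e-9)
  # the minimum sits inside the configured 16:00-17:00 clock window
  mins <- as.numeric(format(rec$t_mnsd, "%H")) +
    as.numeric(format(rec$t_mnsd, "%M")) / 60
  expect_true(all(mins >= 16 & mins <= 17))
  # the maximum is the dawn value near the contraction onset
  expect_true(all(format(rec$t_mxsd, "%H:%M") == "09:30"))
  # healthy days recover within the cycle and keep growing
  expect_true(all(rec$rt_h < 24))
  expect_true(all(rec$di_um[-1L] > 0))
})

test_that("cloudy days shrink less than sunny days", {
  cfg <- scenario_config(days = 6, regime = c(1, 0.55, 1, 0.55, 1, 0.55),
                         drought_mode = "none", residual_structure = FALSE,
                         noise_sd = 0, n_replicates = 1L, seed = 43)
  scn <- generate_scenario(cfg)
  mds <- scn$truth$daily$mds
  expect_true(all(mds[c(2, 4, 6)] < mds[c(1, 3, 5)]))
})

test_that("the generator's arrest bookkeeping matches its stated rule", {
  cfg <- scenario_config(days = 16, regime = "sunny",
                         drought_mode = "progressive",
                         residual_structure = FALSE, noise_sd = 0, seed = 45)
  scn <- generate_scenario(cfg)
  d <- scn$truth$daily
  rule <- which(d$mds >= cfg$arrest_mds_true & !is.na(d$di) & d$di <= 0)
  expect_equal(scn$truth$arrest_day, d$date[rule[1L]])
  expect_equal(scn$truth$arrest_mds, d$mds[rule[1L]])
  # cross-check by the indicator module on the noise-free signal
  rec <- cycle_indicators(stem_series(scn$stem$time,
                                      scn$stem$values[, 1L, drop = FALSE]))
  expect_equal(rec$mds_um, d$mds, tolerance = 1e-9)
  expect_equal(rec$di_um[-1L], d$di[-1L], tolerance = 1e-9)
  # well-watered scenarios never arrest
  healthy <- generate_scenario(scenario_config(days = 8, drought_mode = "none",
                                               noise_sd = 0, seed = 46))
  expect_true(is.na(healthy$truth$arrest_day))
})

test_that("environment covariates hit their correlation target", {
  scn <- generate_scenario(scenario_config(days = 11, seed = 47))  # n = 528
  r <- cor(scn$env$temp_c, scn$env$rh_pct)
  expect_equal(r, -0.79, tolerance = 0.1)
  expect_true(all(scn$env$rh_pct >= 0 & scn$env$rh_pct <= 100))
  expect_true(all(scn$env$vwc_pct >= 0 &
                    scn$env$vwc_pct <= scn$truth$config$field_capacity))
})

test_that("the residual component is deterministic given the environment", {
  scn <- generate_scenario(scenario_config(days = 4, seed = 49))
  r0 <- generate_residual_structure(scn$env, amplitude = 8, noise_sd = 0)
  expect_equal(r0$residual, r0$deterministic)
  r1 <- generate_residual_structure(scn$env, amplitude = 8, noise_sd = 2,
                                    seed = 7)
  r2 <- generate_residual_structure(scn$env, amplitude = 8, noise_sd = 2,
                                    seed = 7)
  expect_identical(r1$residual, r2$residual)
  expect_false(identical(r1$residual, r0$residual))
})

test_that("one seed drives every draw reproducibly", {
  a <- generate_scenario(scenario_config(days = 5, seed = 51))
  b <- generate_scenario(scenario_config(days = 5, seed = 51))
  c <- generate_scenario(scenario_config(days = 5, seed = 52))
  expect_identical(a$stem$values, b$stem$values)
  expect_identical(a$env$temp_c, b$env$temp_c)
  expect_false(identical(a$stem$values, c$stem$values))
  # zero sensor noise makes replicates identical to the true signal
  z <- generate_scenario(scenario_config(days = 3, noise_sd = 0,
                                         n_replicates = 2L, seed = 53))
  expect_equal(z$stem$values[, 1L], z$stem$values[, 2L])
  expect_equal(z$stem$values[, 1L], z$truth$signal)
})

test_that("scenarios round-trip through the sensor-table schema", {
  scn <- generate_scenario(scenario_config(days = 3, seed = 55))
  prefix <- file.path(withr::local_tempdir(), "scn")
  write_scenario(scn, prefix)
  back <- read_sensor_table(paste0(prefix, ".csv"))
  expect_equal(back$stem$values, scn$stem$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$env$vwc_pct, scn$env$vwc_pct, tolerance = 1e-12)
  truth <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$config$seed, 55)
  expect_equal(length(truth$daily$date), 3L)
})
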