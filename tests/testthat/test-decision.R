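test_that("the four quadrants follow the worked-example evidence", {
  th <- decision_thresholds()  # MDS >= 70, VWC <= 17
  expect_equal(evaluate_dual_threshold(99.7, 16.2, th)$verdict, "trigger")
  expect_equal(evaluate_dual_threshold(117.17, 18.9, th)$verdict,
               "atmospheric_false_positive")
  expect_equal(evaluate_dual_threshold(69.60, 17.0, th)$verdict,
               "masked_deficit")
  expect_equal(evaluate_dual_threshold(33.93, 26.0, th)$verdict, "no_stress")

  # boundary semantics: non-strict by default, strict on request
  expect_equal(evaluate_dual_threshold(70, 17, th)$verdict, "trigger")
  strict <- decision_thresholds(mds_strict = TRUE, vwc_strict = TRUE)
  expect_equal(evaluate_dual_threshold(70, 17, strict)$verdict, "no_stress")

  expect_error(evaluate_dual_threshold(-1, 20, th), "non-negative")
  expect_error(evaluate_dual_threshold(Inf, 20, th), "finite")
})

test_that("verdicts partition exhaustively and respond monotonically", {
  set.seed(23)
  th <- decision_thresholds()
  mds <- runif(500, 0, 150)
  vwc <- runif(500, 5, 30)
  dec <- evaluate_dual_threshold(mds, vwc, th)
  expect_true(all(dec$verdict %in% c("trigger", "atmospheric_false_positive",
                                     "masked_deficit", "no_stress")))
  # manual truth table
  m <- mds >= 70; v <- vwc <= 17
  expect_equal(dec$verdict == "trigger", m & v)
  expect_equal(dec$verdict == "atmospheric_false_positive", m & !v)
  expect_equal(dec$verdict == "masked_deficit", !m & v)
  expect_equal(dec$verdict == "no_stress", !m & !v)
  # raising MDS at fixed VWC never loses the MDS condition
  dec2 <- evaluate_dual_threshold(mds + 30, vwc, th)
  expect_true(all(dec2$mds_condition >= dec$mds_condition))
  dec3 <- evaluate_dual_threshold(mds, pmax(vwc - 10, 0.1), th)
  expect_true(all(dec3$vwc_condition >= dec$vwc_condition))
})

test_that("worked-example rows trigger exactly where both thresholds hold", {
  df <- stress_worked_examples()
  dec <- evaluate_dual_threshold(df$mds_um, df$swc_pct)
  expect_equal(dec$verdict == "trigger", df$mds_um >= 70 & df$swc_pct <= 17)
  expect_equal(sum(dec$verdict == "trigger"), 3L)
})

test_that("forecast-driven decisions find the earliest trigger cycle", {
  # flat forecast over wet soil: no triggers (two-day horizon)
  n <- 21L * 48L
  flat <- make_stem(rep(5500, n))
  fc <- forecast_stem(flat, flat_env(n), model = NULL,
                      config = forecast_config(horizon = 96L))
  out <- decide_from_forecast(fc, vwc = 24)
  expect_true(all(out$decisions$verdict != "trigger"))
  expect_true(is.na(out$earliest_trigger))

  # crafted forecast: first cycle shrinks 40 um, second 90 um; dry soil
  fake <- fc
  sod <- as.numeric(format(fake$time, "%H")) * 2 +
    as.numeric(format(fake$time, "%M")) / 30
  day2 <- cumsum(c(FALSE, diff(as.numeric(as.Date(format(fake$time, "%Y-%m-%d")))) > 0))
  dipd <- sin(pi * sod / 48)
  fake$y_hat <- 6000 - ifelse(day2 == 0, 40, 90) * dipd
  out2 <- decide_from_forecast(fake, vwc = 16)
  expect_equal(out2$decisions$verdict[1L], "masked_deficit")
  expect_equal(out2$decisions$verdict[2L], "trigger")
  expect_equal(out2$earliest_trigger, out2$decisions$eval_time[2L])

  # raising VWC anywhere above the ceiling leaves trigger timing unchanged
  out3 <- decide_from_forecast(fake, vwc = rep(16, nrow(fake)))
  expect_equal(out3$earliest_trigger, out2$earliest_trigger)
  expect_error(decide_from_forecast(fake, vwc = c(16, 16)), "align")
})

test_that("decision logs round-trip with rationale intact", {
  dec <- evaluate_dual_threshold(c(75, 40), c(16, 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  decision_log(dec, path)
  back <- read_decision_log(path)
  expect_equal(back$verdict, dec$verdict)
  expect_equal(back$rationale, dec$rationale)
  expect_equal(nrow(back), 2L)
  decision_log(dec[0, ], path)
  expect_equal(nrow(read_decision_log(path)), 0L)
})
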