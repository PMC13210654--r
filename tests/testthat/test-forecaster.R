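test_that("quadratic trend extrapolation reproduces polynomials exactly", {
  t <- seq_len(400L)
  y <- 5000 + 2.5 * t - 0.003 * t^2
  fc <- forecast_trend(y, horizon = 48L, fit_window = 336L)
  truth <- 5000 + 2.5 * (400L + 1:48) - 0.003 * (400L + 1:48)^2
  expect_equal(fc, truth, tolerance = 1e-6)

  expect_equal(forecast_trend(rep(7, 336L), 10L), rep(7, 10L))
  expect_error(forecast_trend(rep(7, 100L), 10L), "336")

  # noisy quadratic: match an independent normal-equations solve
  set.seed(21)
  yn <- y[65:400] + rnorm(336L, 0, 1)
  fc2 <- forecast_trend(yn, 48L)
  tt <- seq_len(336L)
  X <- cbind(1, tt, tt^2)
  beta <- solve(crossprod(X), crossprod(X, yn))
  th <- 336L + 1:48
  oracle <- cbind(1, th, th^2) %*% beta
  expect_equal(fc2, as.numeric(oracle), tolerance = 1e-8)
})

test_that("seasonal persistence repeats the previous cycle, recursing beyond it", {
  s <- rep(sin(2 * pi * (0:47) / 48) * 20, 4L)
  expect_equal(forecast_seasonal(s, 48L), s[1:48])
  expect_equal(forecast_seasonal(s, 96L)[49:96], forecast_seasonal(s, 48L))
  h30 <- forecast_seasonal(s, 30L)
  expect_equal(h30, s[145:174])
  expect_error(forecast_seasonal(s[1:40], 10L), "period")
})

test_that("seasonal-naive baseline is exact on periodic signals", {
  y <- rep(5000 + sin(2 * pi * (0:47) / 48) * 30, 5L)
  expect_equal(seasonal_naive_baseline(y[1:192], 48L), y[193:240])
  # adding a linear drift leaves a constant error of one day's drift
  y2 <- y + 2 * seq_along(y)
  err <- y2[193:240] - seasonal_naive_baseline(y2[1:192], 48L)
  expect_equal(err, rep(2 * 48, 48L))
  # index-arithmetic oracle
  n <- length(y2)
  expect_equal(seasonal_naive_baseline(y2, 20L), y2[n - 48L + 1:20])
})

test_that("supervised windows count, align, and encode time correctly", {
  scn <- generate_scenario(scenario_config(days = 8, seed = 2))
  agg <- aggregate_replicates(scn$stem)
  comp <- stl_decompose(agg, trend_window = 337L)
  cfg <- forecast_config(lookback = 24L, horizon = 48L)
  sup <- build_supervised_set(comp, scn$env, cfg)
  L <- 8L * 48L
  expect_equal(dim(sup$x), c(L - 24L - 48L + 1L, 24L, 9L))
  expect_equal(sup$y[1L, ], comp$remainder[25:72])
  expect_equal(sup$x[1L, , "remainder"], comp$remainder[1:24])
  sincos <- sup$x[1L, , "sin_t"]^2 + sup$x[1L, , "cos_t"]^2
  expect_equal(sincos, rep(1, 24L))
})

test_that("normalization is fitted on the training split only", {
  scn <- generate_scenario(scenario_config(days = 10, seed = 4))
  agg <- aggregate_replicates(scn$stem)
  comp <- stl_decompose(agg, trend_window = 337L)
  cfg <- forecast_config(layers = 1L, hidden_units = 8L, max_epochs = 2L,
                         batch_size = 128L, seed = 1L)
  sup <- build_supervised_set(comp, scn$env, cfg)
  model <- train_residual_model(sup, cfg)
  tr <- model$split$train
  flat <- matrix(sup$x[tr, , ], nrow = length(tr) * sup$lookback)
  expect_equal(unname(model$feature_mean), unname(colMeans(flat)))
  expect_equal(unname(model$feature_sd),
               unname(sqrt(colMeans(sweep(flat, 2L, colMeans(flat))^2))))
  # validation windows never precede the training boundary
  expect_true(min(sup$starts[model$split$val]) >
                model$split$boundaries["train_end"])
})

test_that("a zero residual is learned as (near) zero and training is deterministic", {
  scn <- generate_scenario(scenario_config(days = 10, residual_structure = FALSE,
                                           noise_sd = 0, seed = 6))
  agg <- aggregate_replicates(scn$stem)
  comp <- stl_decompose(agg, trend_window = 337L)
  comp$remainder[] <- 0
  cfg <- forecast_config(layers = 1L, hidden_units = 8L, max_epochs = 15L,
                         batch_size = 128L, dropout = 0, seed = 9L)
  sup <- build_supervised_set(comp, scn$env, cfg)
  m <- train_residual_model(sup, cfg)
  pred <- predict(m, sup$x[m$split$val, , , drop = FALSE])
  expect_lt(mean(abs(pred)), 0.2)  # micrometres; essentially zero signal

  m2 <- train_residual_model(sup, cfg)
  expect_identical(m$log, m2$log)
  expect_identical(m$params, m2$params)
})

test_that("the grid search ranks a learnable configuration first", {
  scn <- generate_scenario(scenario_config(days = 12, residual_amplitude = 15,
                                           residual_noise_sd = 0.5, seed = 8))
  agg <- aggregate_replicates(scn$stem)
  comp <- stl_decompose(agg, trend_window = 337L)
  base <- forecast_config(layers = 1L, hidden_units = 16L, max_epochs = 8L,
                          batch_size = 128L, patience = 8L, seed = 3L)
  sup <- build_supervised_set(comp, scn$env, base)

  g1 <- data.frame(layers = 1L, hidden_units = 16L, learning_rate = 1e-3,
                   batch_size = 128L)
  out1 <- hyperparameter_search(sup, g1, base, max_epochs = 2L)
  expect_equal(nrow(out1$leaderboard), 1L)
  expect_equal(out1$best_config$hidden_units, 16L)

  # a learning rate too small to move the weights must rank last
  g2 <- expand.grid(layers = 1L, hidden_units = 16L,
                    learning_rate = c(1e-3, 1e-9), batch_size = 128L)
  out2 <- hyperparameter_search(sup, g2, base, max_epochs = 8L)
  expect_equal(nrow(out2$leaderboard), 2L)
  expect_equal(out2$leaderboard$learning_rate[1L], 1e-3)
  expect_error(hyperparameter_search(sup, g1[0, ], base), "empty")
})

test_that("hybrid reconstruction is exact and accurate on a closed-form signal", {
  n <- 21L * 48L
  t <- seq_len(n)
  y <- 5000 + 0.4 * t + 3e-5 * t^2 + 50 * sin(2 * pi * t / 48)
  s <- make_stem(y)
  env <- flat_env(n)
  fc <- forecast_stem(s, env, model = NULL)
  expect_identical(fc$y_hat, fc$trend_hat + fc$seasonal_hat + fc$residual_hat)
  expect_equal(as.numeric(diff(fc$time)), rep(30, 47L))
  expect_equal(as.numeric(fc$time[1L] - s$time[n], units = "mins"), 30)
  truth <- 5000 + 0.4 * (n + 1:48) + 3e-5 * (n + 1:48)^2 +
    50 * sin(2 * pi * (n + 1:48) / 48)
  expect_lt(max(abs(fc$y_hat - truth)), 0.01 * 100)  # 1% of peak-to-trough
})

test_that("model checkpoints round-trip through JSON", {
  scn <- generate_scenario(scenario_config(days = 8, seed = 10))
  agg <- aggregate_replicates(scn$stem)
  cfg <- forecast_config(layers = 2L, hidden_units = c(6L, 5L), max_epochs = 2L,
                         batch_size = 128L, seed = 2L)
  fit <- fit_hybrid(agg, scn$env, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  x <- fit$supervised$x[1:3, , , drop = FALSE]
  expect_equal(predict(back, x), predict(fit$model, x), tolerance = 1e-12)
  expect_equal(back$config$hidden_units, cfg$hidden_units)
})

test_that("backtest excludes pre-test origins and reports both models", {
  scn <- generate_scenario(scenario_config(days = 20, seed = 12))
  agg <- aggregate_replicates(scn$stem)
  cfg <- forecast_config(layers = 1L, hidden_units = 8L, max_epochs = 3L,
                         batch_size = 256L, seed = 5L)
  fit <- fit_hybrid(agg, scn$env, cfg)
  bt <- backtest_hybrid(agg, scn$env, fit$model)
  test_start <- fit$split$boundaries["val_end"] + 1L
  expect_true(all(bt$origins >= test_start - 1L))
  expect_true(all(bt$origins + cfg$horizon <= n_samples(agg)))
  expect_s3_class(bt$hybrid, "metric_report")
  expect_equal(bt$hybrid$n, length(bt$origins) * 48L)
})
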