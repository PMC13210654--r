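# Hybrid 24-h stem-diameter forecaster: deterministic trend extrapolation
# (quadratic least squares over the last 7 days) + seasonal persistence
# (previous cycle) + a GRU residual corrector driven by lagged STL components,
# environment covariates and sine-cosine time-of-day encoding, additively
# reconstructed over a 48-step horizon.

#' Forecaster configuration
#'
#' Bundles all tunables of the hybrid predictor. The defaults mirror the
#' optimised architecture from a 3x3x3x3 grid over layers/units/learning
#' rate/batch size (2 layers x 64 units, lr 0.001, batch 32), with a lookback
#' of 24 steps (12 h) and a direct multi-output horizon of 48 steps (24 h).
#'
#' @param lookback feature window length in 30-min steps.
#' @param horizon forecast length in steps (at most 7 periods).
#' @param trend_fit_window trend history used by the quadratic fit (steps).
#' @param layers number of stacked recurrent layers.
#' @param hidden_units units per layer (recycled to `layers`).
#' @param dropout dropout rate between layers, in `[0, 1)`.
#' @param learning_rate,batch_size,max_epochs,patience optimiser settings.
#' @param period seasonal period in steps.
#' @param seed integer seed driving initialisation, dropout and batching.
#' @return an object of class `forecast_config`.
#' @export
forecast_config <- function(lookback = 24L, horizon = 48L,
                            trend_fit_window = 336L, layers = 2L,
                            hidden_units = 64L, dropout = 0.2,
                            learning_rate = 1e-3, batch_size = 32L,
                            max_epochs = 100L, patience = 10L,
                            period = 48L, seed = 42L) {
  stopifnot(lookback >= 1L, horizon >= 1L, horizon <= 7L * period,
            dropout >= 0, dropout < 1, layers >= 1L)
  hidden_units <- rep_len(as.integer(hidden_units), layers)
  structure(list(lookback = as.integer(lookback), horizon = as.integer(horizon),
                 trend_fit_window = as.integer(trend_fit_window),
                 poly_order = 2L, layers = as.integer(layers),
                 hidden_units = hidden_units, dropout = dropout,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 period = as.integer(period), seed = as.integer(seed)),
            class = "forecast_config")
}

#' Quadratic trend extrapolation
#'
#' Least-squares second-order polynomial fit on the last `fit_window` trend
#' points (time index as regressor), evaluated at the horizon indices.
#'
#' @param trend numeric trend component (history).
#' @param horizon steps ahead to forecast.
#' @param fit_window history length used for the fit (default 336 = 7 days).
#' @return numeric vector of length `horizon`.
#' @export
forecast_trend <- function(trend, horizon, fit_window = 336L) {
  n <- length(trend)
  if (n < fit_window)
    stop("trend history too short: need ", fit_window, " points, have ", n,
         call. = FALSE)
  y <- trend[(n - fit_window + 1L):n]
  t0 <- seq_len(fit_window) - (fit_window + 1) / 2  # centred index for conditioning
  X <- cbind(1, t0, t0^2)
  beta <- stats::lm.fit(X, y)$coefficients
  th <- fit_window + seq_len(horizon) - (fit_window + 1) / 2
  as.numeric(cbind(1, th, th^2) %*% beta)
}

#' Seasonal persistence forecast
#'
#' `S(t+h) = S(t+h-period)`: each horizon step repeats the value one period
#' earlier; beyond one period the rule recurses on its own forecasts.
#'
#' @param seasonal numeric seasonal component (history, length >= `period`).
#' @param horizon steps ahead.
#' @param period seasonal period in steps.
#' @return numeric vector of length `horizon`.
#' @export
forecast_seasonal <- function(seasonal, horizon, period = 48L) {
  n <- length(seasonal)
  if (n < period)
    stop("seasonal history shorter than one period", call. = FALSE)
  ext <- c(seasonal, numeric(horizon))
  for (h in seq_len(horizon)) ext[n + h] <- ext[n + h - period]
  ext[n + seq_len(horizon)]
}

#' Seasonal-naive baseline forecast
#'
#' Persistence of the raw signal: `Y(t+h) = Y(t+h-period)`, recursing beyond
#' one period. The comparison baseline for the hybrid model.
#'
#' @param y numeric observed history (length >= `period`), or a single-column
#'   [stem_series].
#' @param horizon steps ahead.
#' @param period seasonal period in steps.
#' @return numeric vector of length `horizon`.
#' @export
seasonal_naive_baseline <- function(y, horizon, period = 48L) {
  if (inherits(y, "stem_series")) {
    .single_column(y, "baseline forecasting")
    y <- y$values[, 1L]
  }
  if (length(y) < period)
    stop("history shorter than one period", call. = FALSE)
  forecast_seasonal(y, horizon, period)
}

#' @noRd
.feature_matrix <- function(components, env) {
  slot <- .seconds_of_day(env$time) / STEP_SECONDS
  ang <- 2 * pi * slot / STEPS_PER_DAY
  m <- cbind(trend = components$trend, seasonal = components$seasonal,
             remainder = components$remainder, temp_c = env$temp_c,
             rh_pct = env$rh_pct, light_lux = env$light_lux,
             vwc_pct = env$vwc_pct, sin_t = sin(ang), cos_t = cos(ang))
  m
}

#' Build the supervised learning set for the residual corrector
#'
#' Sliding windows of `lookback` steps over the feature matrix (STL
#' components, environment covariates, sine-cosine time encoding), each
#' paired with the remainder over the following `horizon` steps as a direct
#' multi-output target. Features are stored in native units; normalization
#' parameters are fitted on the training split at training time only.
#'
#' @param components an `stl_components` object.
#' @param env an [env_series] aligned with the decomposed series.
#' @param config a [forecast_config].
#' @return list with `x` (array `n_windows x lookback x n_features`), `y`
#'   (matrix `n_windows x horizon`), `starts` (window start indices on the
#'   series timeline), `feature_names`, `lookback`, `horizon`, `n_time`.
#' @export
build_supervised_set <- function(components, env, config = forecast_config()) {
  stopifnot(inherits(components, "stl_components"), inherits(env, "env_series"))
  if (length(components$y) != length(env$time))
    stop("components and environment series are not aligned", call. = FALSE)
  if (!is.null(components$time) &&
      any(as.numeric(components$time) != as.numeric(env$time)))
    stop("components and environment series are not aligned", call. = FALSE)
  L <- length(components$y)
  lb <- config$lookback; hz <- config$horizon
  nW <- L - lb - hz + 1L
  if (nW < 1L) stop("series too short for the chosen lookback + horizon", call. = FALSE)
  fm <- .feature_matrix(components, env)
  if (anyNA(fm)) stop("features contain missing values; impute first", call. = FALSE)
  x <- array(NA_real_, dim = c(nW, lb, ncol(fm)),
             dimnames = list(NULL, NULL, colnames(fm)))
  y <- matrix(NA_real_, nW, hz)
  for (i in seq_len(nW)) {
    x[i, , ] <- fm[i:(i + lb - 1L), ]
    y[i, ] <- components$remainder[(i + lb):(i + lb + hz - 1L)]
  }
  list(x = x, y = y, starts = seq_len(nW), feature_names = colnames(fm),
       lookback = lb, horizon = hz, n_time = L)
}

#' @noRd
.split_windows <- function(supervised, split = c(0.6, 0.2, 0.2)) {
  stopifnot(length(split) == 3L, abs(sum(split) - 1) < 1e-8)
  L <- supervised$n_time
  b1 <- floor(split[1L] * L)
  b2 <- floor((split[1L] + split[2L]) * L)
  span_end <- supervised$starts + supervised$lookback + supervised$horizon - 1L
  list(train = which(span_end <= b1),
       val = which(supervised$starts > b1 & span_end <= b2),
       test = which(supervised$starts > b2),
       boundaries = c(train_end = b1, val_end = b2))
}

#' Train the GRU residual corrector
#'
#' Chronological split (windows overlapping a split boundary are excluded),
#' z-score normalization of features and targets fitted on the training
#' split only, minibatch Adam on mean-squared error, and early stopping on
#' validation loss with best-weights restore. Fully seeded: the same seed
#' reproduces the same training log.
#'
#' @param supervised output of [build_supervised_set()].
#' @param config a [forecast_config].
#' @param split chronological train/validation/test fractions of the
#'   underlying timeline (default 60/20/20).
#' @return an object of class `residual_model`: weights, normalization
#'   parameters, config, split boundaries, per-epoch training log.
#' @export
train_residual_model <- function(supervised, config = forecast_config(),
                                 split = c(0.6, 0.2, 0.2)) {
  sp <- .split_windows(supervised, split)
  if (length(sp$train) < 2L) stop("training split has too few windows", call. = FALSE)
  # normalization parameters from training-split windows only
  flat_train <- matrix(supervised$x[sp$train, , ],
                       nrow = length(sp$train) * supervised$lookback,
                       dimnames = list(NULL, supervised$feature_names))
  mu <- colMeans(flat_train)
  sdv <- sqrt(colMeans(sweep(flat_train, 2L, mu)^2))
  sdv[sdv <= 0] <- 1  # constant feature carries no signal; leave centred at 0
  y_tr <- supervised$y[sp$train, , drop = FALSE]
  y_mu <- mean(y_tr)
  y_sd <- stats::sd(as.numeric(y_tr))
  if (!is.finite(y_sd) || y_sd <= 0) y_sd <- 1
  norm_x <- function(x) {
    for (f in seq_len(dim(x)[3L])) x[, , f] <- (x[, , f] - mu[f]) / sdv[f]
    x
  }
  xt <- norm_x(supervised$x[sp$train, , , drop = FALSE])
  xv <- norm_x(supervised$x[sp$val, , , drop = FALSE])
  yt <- (y_tr - y_mu) / y_sd
  yv <- (supervised$y[sp$val, , drop = FALSE] - y_mu) / y_sd
  fit <- .gru_train(xt, yt, xv, yv,
                    units = config$hidden_units, horizon = supervised$horizon,
                    dropout = config$dropout, lr = config$learning_rate,
                    batch_size = config$batch_size, max_epochs = config$max_epochs,
                    patience = config$patience, seed = config$seed)
  structure(list(params = fit$params, config = config,
                 feature_mean = mu, feature_sd = sdv,
                 target_mean = y_mu, target_sd = y_sd,
                 split = sp, log = fit$log, best_epoch = fit$best_epoch,
                 seed = config$seed),
            class = "residual_model")
}

#' @export
print.residual_model <- function(x, ...) {
  cat("<residual_model> GRU", paste(x$config$hidden_units, collapse = "+"),
      "units, head width", x$config$horizon, "\n")
  cat("  trained", nrow(x$log), "epochs (best", x$best_epoch, "), seed", x$seed, "\n")
  cat("  final val MSE (normalized):",
      format(x$log$val_mse[x$best_epoch], digits = 4), "\n")
  invisible(x)
}

#' Predict residuals for feature windows
#'
#' @param object a `residual_model`.
#' @param x feature array (`n x lookback x n_features`) in native units, laid
#'   out as in [build_supervised_set()].
#' @param ... unused.
#' @return matrix `n x horizon` of residual forecasts in micrometres.
#' @export
predict.residual_model <- function(object, x, ...) {
  for (f in seq_len(dim(x)[3L]))
    x[, , f] <- (x[, , f] - object$feature_mean[f]) / object$feature_sd[f]
  out <- .gru_forward(object$params, x)$yhat
  out * object$target_sd + object$target_mean
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per grid point at a (typically reduced) epoch budget and
#' ranks by validation RMSE of the residual prediction; ties go to the
#' smaller model (fewer parameters).
#'
#' @param supervised output of [build_supervised_set()].
#' @param grid data.frame with columns `layers`, `hidden_units`,
#'   `learning_rate`, `batch_size`; defaults to the full 81-point space
#'   (1/2/3 layers, 32/64/128 units, lr 1e-3/1e-4/1e-5, batch 16/32/64).
#' @param base_config settings shared by all grid points.
#' @param split chronological split fractions.
#' @param max_epochs epoch budget per grid point.
#' @return list with `best_config` and `leaderboard` (one row per grid point,
#'   ranked).
#' @export
hyperparameter_search <- function(supervised, grid = NULL,
                                  base_config = forecast_config(),
                                  split = c(0.6, 0.2, 0.2), max_epochs = 15L) {
  if (is.null(grid))
    grid <- expand.grid(layers = c(1L, 2L, 3L), hidden_units = c(32L, 64L, 128L),
                        learning_rate = c(1e-3, 1e-4, 1e-5),
                        batch_size = c(16L, 32L, 64L))
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- forecast_config(
      lookback = base_config$lookback, horizon = base_config$horizon,
      trend_fit_window = base_config$trend_fit_window,
      layers = grid$layers[i], hidden_units = grid$hidden_units[i],
      dropout = base_config$dropout, learning_rate = grid$learning_rate[i],
      batch_size = grid$batch_size[i], max_epochs = max_epochs,
      patience = base_config$patience, period = base_config$period,
      seed = base_config$seed)
    m <- train_residual_model(supervised, cfg, split)
    sp <- m$split
    pred <- predict(m, supervised$x[sp$val, , , drop = FALSE])
    vrmse <- rmse(as.numeric(supervised$y[sp$val, , drop = FALSE]), as.numeric(pred))
    n_par <- sum(vapply(m$params$layers, function(l)
      length(l$W) + length(l$U) + length(l$b), numeric(1L))) +
      length(m$params$Wo) + length(m$params$bo)
    res[[i]] <- data.frame(grid[i, , drop = FALSE], val_rmse = vrmse, n_params = n_par)
  }
  lb <- do.call(rbind, res)
  lb <- lb[order(lb$val_rmse, lb$n_params), , drop = FALSE]
  rownames(lb) <- NULL
  best <- lb[1L, ]
  best_config <- forecast_config(
    lookback = base_config$lookback, horizon = base_config$horizon,
    trend_fit_window = base_config$trend_fit_window, layers = best$layers,
    hidden_units = best$hidden_units, dropout = base_config$dropout,
    learning_rate = best$learning_rate, batch_size = best$batch_size,
    max_epochs = base_config$max_epochs, patience = base_config$patience,
    period = base_config$period, seed = base_config$seed)
  list(best_config = best_config, leaderboard = lb)
}

#' Hybrid 24-h forecast from a series end or interior origin
#'
#' Decomposes the history up to `origin`, extrapolates the trend
#' (quadratic), persists the seasonal cycle, predicts the remainder with the
#' trained corrector (zero if `model` is `NULL`), and reconstructs
#' `Y-hat = T-hat + S-hat + R-hat` per step.
#'
#' @param series a gap-free single-column [stem_series].
#' @param env an aligned [env_series].
#' @param model a `residual_model`, or `NULL` for the deterministic-only
#'   forecast.
#' @param config a [forecast_config].
#' @param origin index of the forecast origin on the series timeline
#'   (default: series end); only samples `1..origin` are used.
#' @return an object of class `stem_forecast`: data.frame with `time`,
#'   `trend_hat`, `seasonal_hat`, `residual_hat`, `y_hat`, plus attributes
#'   `origin_time` and `config`.
#' @export
forecast_stem <- function(series, env, model = NULL,
                          config = if (!is.null(model)) model$config else forecast_config(),
                          origin = NULL) {
  stopifnot(inherits(series, "stem_series"), inherits(env, "env_series"))
  .check_aligned(series, env)
  .single_column(series, "forecasting")
  L <- length(series$time)
  if (is.null(origin)) origin <- L
  need <- max(2L * config$period, config$trend_fit_window, config$lookback)
  if (origin < need)
    stop("need at least ", need, " samples of history before the origin", call. = FALSE)
  hist_idx <- seq_len(origin)
  comp <- stl_decompose(series$values[hist_idx, 1L], period = config$period,
                        trend_window = 337L)
  t_hat <- forecast_trend(comp$trend, config$horizon, config$trend_fit_window)
  s_hat <- forecast_seasonal(comp$seasonal, config$horizon, config$period)
  if (!is.null(model)) {
    env_h <- env_series(env$time[hist_idx], env$temp_c[hist_idx], env$rh_pct[hist_idx],
                        env$light_lux[hist_idx], env$vwc_pct[hist_idx])
    fm <- .feature_matrix(comp, env_h)
    win <- fm[(origin - config$lookback + 1L):origin, , drop = FALSE]
    x <- array(win, dim = c(1L, config$lookback, ncol(fm)),
               dimnames = list(NULL, NULL, colnames(fm)))
    r_hat <- as.numeric(predict(model, x))
  } else {
    r_hat <- numeric(config$horizon)
  }
  tm <- series$time[origin] + STEP_SECONDS * seq_len(config$horizon)
  out <- data.frame(time = tm, trend_hat = t_hat, seasonal_hat = s_hat,
                    residual_hat = r_hat, y_hat = t_hat + s_hat + r_hat)
  structure(out, class = c("stem_forecast", "data.frame"),
            origin_time = series$time[origin], config = config)
}

#' Write a forecast as a delimited table
#' @param forecast a `stem_forecast`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(forecast, path, sep = ",") {
  df <- as.data.frame(forecast)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%S")
  names(df)[1L] <- "timestamp"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the full hybrid pipeline on a series
#'
#' Decomposes the series, builds the supervised set and trains the residual
#' corrector under a chronological split.
#'
#' @param series a gap-free single-column [stem_series].
#' @param env an aligned [env_series].
#' @param config a [forecast_config].
#' @param split chronological split fractions.
#' @return list with `model`, `components`, `supervised`, `split`.
#' @export
fit_hybrid <- function(series, env, config = forecast_config(),
                       split = c(0.6, 0.2, 0.2)) {
  .single_column(series, "hybrid fitting")
  comp <- stl_decompose(series, period = config$period, trend_window = 337L)
  sup <- build_supervised_set(comp, env, config)
  model <- train_residual_model(sup, config, split)
  list(model = model, components = comp, supervised = sup, split = model$split)
}

#' Rolling-origin backtest on the held-out test block
#'
#' Issues hybrid and seasonal-naive forecasts from origins inside the test
#' block (decomposing only history before each origin) and pools the
#' per-step errors into RMSE / R-squared / MAPE for both.
#'
#' @param series a gap-free single-column [stem_series].
#' @param env an aligned [env_series].
#' @param model a trained `residual_model` (its split defines the test
#'   block), or `NULL` with `test_start` supplied.
#' @param config a [forecast_config].
#' @param stride spacing between consecutive origins in steps (default: one
#'   horizon, i.e. non-overlapping forecasts).
#' @param test_start first timeline index of the test block (default: from
#'   the model's split boundaries).
#' @return list with `hybrid` and `naive` [metric_report()] rows, `origins`,
#'   and the pooled observation/forecast vectors.
#' @export
backtest_hybrid <- function(series, env, model, config = model$config,
                            stride = config$horizon, test_start = NULL) {
  .single_column(series, "backtesting")
  L <- length(series$time)
  if (is.null(test_start)) {
    if (is.null(model)) stop("supply either a model or test_start", call. = FALSE)
    test_start <- as.integer(model$split$boundaries["val_end"]) + 1L
  }
  origins <- seq(test_start - 1L, L - config$horizon, by = stride)
  origins <- origins[origins >= max(2L * config$period, config$trend_fit_window)]
  if (length(origins) == 0L) stop("no feasible backtest origins", call. = FALSE)
  obs <- hyb <- nai <- numeric(0)
  for (o in origins) {
    fc <- forecast_stem(series, env, model, config, origin = o)
    ahead <- (o + 1L):(o + config$horizon)
    obs <- c(obs, series$values[ahead, 1L])
    hyb <- c(hyb, fc$y_hat)
    nai <- c(nai, seasonal_naive_baseline(series$values[seq_len(o), 1L],
                                          config$horizon, config$period))
  }
  list(hybrid = metric_report(obs, hyb, label = "test"),
       naive = metric_report(obs, nai, label = "test"),
       origins = origins, obs = obs, hybrid_pred = hyb, naive_pred = nai)
}

#' Save / load a trained residual model as JSON
#'
#' The checkpoint bundles weights, normalization parameters, config and seed
#' in one plain-text file.
#'
#' @param model a `residual_model`.
#' @param path file path.
#' @return `path` invisibly (`save_model`); a `residual_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "residual_model"))
  ser <- list(
    layers = lapply(model$params$layers, function(l)
      list(W = l$W, U = l$U, b = l$b)),
    Wo = model$params$Wo, bo = model$params$bo,
    input_dim = model$params$input_dim, units = model$params$units,
    horizon = model$params$horizon,
    feature_mean = as.list(model$feature_mean),
    feature_sd = as.list(model$feature_sd),
    target_mean = model$target_mean, target_sd = model$target_sd,
    config = unclass(model$config), seed = model$seed,
    best_epoch = model$best_epoch, log = model$log)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  params <- list(
    layers = lapply(seq_along(s$layers$W), function(i)
      list(W = as_mat(s$layers$W[[i]]), U = as_mat(s$layers$U[[i]]),
           b = as.numeric(s$layers$b[[i]]))),
    Wo = as_mat(s$Wo), bo = as.numeric(s$bo),
    input_dim = s$input_dim, units = s$units, horizon = s$horizon)
  cfg <- do.call(forecast_config, s$config[setdiff(names(s$config), "poly_order")])
  structure(list(params = params, config = cfg,
                 feature_mean = unlist(s$feature_mean),
                 feature_sd = unlist(s$feature_sd),
                 target_mean = s$target_mean, target_sd = s$target_sd,
                 split = NULL, log = s$log, best_epoch = s$best_epoch,
                 seed = s$seed),
            class = "residual_model")
}
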