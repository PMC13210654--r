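# Seeded synthetic greenhouse scenarios: a diurnal stem-diameter template
# (morning maximum near the contraction onset, afternoon minimum in a fixed
# clock window, nocturnal recovery), slow growth, sunny/cloudy amplitude
# regimes, soil-water depletion coupled to shrinkage amplitude and growth
# arrest, correlated microclimate covariates, an env-driven remainder
# component, and replicate sensors with autocorrelated noise. Every draw is
# governed by one seed, and the generator records its own ground truth.

#' Scenario configuration
#'
#' Defaults describe a peak-fruiting greenhouse tomato: ~5.4 mm stem growing
#' 20 um/day, 55 um sunny-day shrinkage amplitude (30-70 um healthy MDS
#' band), contraction starting 09:30 with the minimum at 16:30, recovery
#' complete by 22:00, field capacity 26.0% volumetric. Under progressive
#' drought the shrinkage amplitude inflates as a saturating function of the
#' soil-water deficit and daily growth collapses as the amplitude approaches
#' `arrest_mds_true`, so the daily increment turns non-positive and recovery
#' fails exactly when the internal MDS crosses the configured arrest value.
#'
#' @param days scenario length in days.
#' @param base_diameter initial stem diameter, um.
#' @param growth_rate healthy growth, um/day.
#' @param seasonal_amplitude sunny-day contraction amplitude, um.
#' @param contraction_onset clock time contraction starts (`"HH:MM"`).
#' @param min_window two clock times bracketing the daily minimum; the
#'   template places the minimum at the window midpoint.
#' @param recovery_end clock time by which turgor recovery completes.
#' @param regime `"mixed"`, `"sunny"`, `"cloudy"`, or a numeric vector of
#'   per-day amplitude multipliers.
#' @param cloudy_amplitude_mult amplitude multiplier on cloudy days.
#' @param p_cloudy probability a mixed-regime day is cloudy.
#' @param drought_mode `"none"`, `"constant_gradient"` or `"progressive"`.
#' @param swc_initial starting soil VWC, %.
#' @param swc_target_range VWC band maintained in constant-gradient mode, %.
#' @param swc_daily_depletion VWC loss per day in progressive mode, %/day.
#' @param field_capacity soil field capacity, % volumetric.
#' @param arrest_mds_true ground-truth arrest MDS, um (progressive mode).
#' @param stress_gain,stress_k saturating stress coupling: the amplitude
#'   multiplier is `1 + stress_gain * d^2 / (d^2 + stress_k^2)` with
#'   `d = max(0, FC - swc)`.
#' @param r_temp_rh target Pearson correlation between air temperature and
#'   relative humidity.
#' @param light_max clear-sky midday light intensity, lux.
#' @param residual_structure add the env-driven remainder component?
#' @param residual_amplitude amplitude of the deterministic remainder, um.
#' @param residual_noise_sd sd of the AR(1) remainder noise, um.
#' @param noise_sd marginal sd of per-replicate sensor noise, um (AR(1) with
#'   `noise_phi`; dendrometer noise is slow drift, not white).
#' @param noise_phi AR(1) coefficient of replicate noise at the 30-min step.
#' @param n_replicates replicate sensors per treatment.
#' @param seed integer seed driving all draws.
#' @param start first timestamp (midnight, ISO date).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(days = 60L, base_diameter = 5400, growth_rate = 20,
                            seasonal_amplitude = 55,
                            contraction_onset = "09:30",
                            min_window = c("16:00", "17:00"),
                            recovery_end = "22:00",
                            regime = "mixed", cloudy_amplitude_mult = 0.55,
                            p_cloudy = 0.3,
                            drought_mode = c("none", "constant_gradient", "progressive"),
                            swc_initial = 24, swc_target_range = c(20.8, 26),
                            swc_daily_depletion = 0.8, field_capacity = 26.0,
                            arrest_mds_true = 90, stress_gain = 2.5,
                            stress_k = 14, r_temp_rh = -0.79,
                            light_max = 60000, residual_structure = TRUE,
                            residual_amplitude = 8, residual_noise_sd = 2,
                            noise_sd = 2, noise_phi = 0.95, n_replicates = 3L,
                            seed = 1L, start = "2025-05-01") {
  drought_mode <- match.arg(drought_mode)
  stopifnot(days >= 2L, seasonal_amplitude > 0, cloudy_amplitude_mult > 0,
            field_capacity > 0, n_replicates >= 1L,
            noise_phi >= 0, noise_phi < 1)
  onset <- .clock_seconds(contraction_onset) / 3600
  umin <- mean(vapply(min_window, .clock_seconds, numeric(1L))) / 3600
  urec <- .clock_seconds(recovery_end) / 3600
  if (!(onset < umin && umin < urec && urec <= 24))
    stop("require contraction onset < minimum < recovery end within one day",
         call. = FALSE)
  structure(list(days = as.integer(days), base_diameter = base_diameter,
                 growth_rate = growth_rate, seasonal_amplitude = seasonal_amplitude,
                 onset_h = onset, umin_h = umin, urec_h = urec,
                 regime = regime, cloudy_amplitude_mult = cloudy_amplitude_mult,
                 p_cloudy = p_cloudy, drought_mode = drought_mode,
                 swc_initial = swc_initial, swc_target_range = swc_target_range,
                 swc_daily_depletion = swc_daily_depletion,
                 field_capacity = field_capacity,
                 arrest_mds_true = arrest_mds_true, stress_gain = stress_gain,
                 stress_k = stress_k, r_temp_rh = r_temp_rh,
                 light_max = light_max, residual_structure = residual_structure,
                 residual_amplitude = residual_amplitude,
                 residual_noise_sd = residual_noise_sd,
                 noise_sd = noise_sd, noise_phi = noise_phi,
                 n_replicates = as.integer(n_replicates), seed = as.integer(seed),
                 start = start),
            class = "scenario_config")
}

# Diurnal contraction depth in [0, 1]: 0 before onset, half-cosine rise to 1
# at the minimum, half-cosine fall back to 0 at recovery end, 0 after.
#' @noRd
.dip_shape <- function(u, onset, umin, urec) {
  s <- numeric(length(u))
  ris <- u > onset & u <= umin
  fal <- u > umin & u < urec
  s[ris] <- 0.5 * (1 - cos(pi * (u[ris] - onset) / (umin - onset)))
  s[fal] <- 0.5 * (1 + cos(pi * (u[fal] - umin) / (urec - umin)))
  s
}

#' Env-driven remainder component
#'
#' A smooth nonlinear function of air temperature and light,
#' `amplitude * tanh((T - 20)/6) * L / max(L)`, plus AR(1) noise: the
#' learnable signal the residual corrector is meant to capture. With
#' `noise_sd = 0` the component is deterministic given the environment.
#'
#' @param env an [env_series].
#' @param amplitude deterministic amplitude, um.
#' @param noise_sd marginal sd of the AR(1) noise term, um.
#' @param phi AR(1) coefficient.
#' @param seed optional seed (omit when called inside a seeded generator).
#' @return list with `residual`, `deterministic` and the ground-truth
#'   description of the generating function.
#' @export
generate_residual_structure <- function(env, amplitude = 8, noise_sd = 2,
                                        phi = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lmax <- max(env$light_lux, 1)
  det <- amplitude * tanh((env$temp_c - 20) / 6) * env$light_lux / lmax
  list(residual = det + .ar1_noise(length(det), noise_sd, phi),
       deterministic = det,
       ground_truth = list(form = "amplitude * tanh((T-20)/6) * L/max(L) + AR1",
                           amplitude = amplitude, noise_sd = noise_sd, phi = phi))
}

#' Generate a synthetic greenhouse scenario
#'
#' @param config a [scenario_config()].
#' @return list with `stem` (replicate [stem_series]), `env` ([env_series])
#'   and `truth`: the generator's own bookkeeping (per-day regime
#'   multiplier, soil VWC, amplitude, growth, true MXSD/MNSD/MDS/DI/RT, the
#'   arrest day and its MDS, the noise-free signal, true growth line and
#'   remainder, and the config echo).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  nd <- config$days
  n <- nd * STEPS_PER_DAY
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  time <- t0 + STEP_SECONDS * (seq_len(n) - 1L)
  day <- rep(seq_len(nd), each = STEPS_PER_DAY)
  u <- rep(seq(0, 24 - 0.5, by = 0.5), nd)

  # weather regime: per-day amplitude multiplier
  mult <- if (is.numeric(config$regime)) rep_len(config$regime, nd)
          else switch(config$regime,
                      sunny = rep(1, nd),
                      cloudy = rep(config$cloudy_amplitude_mult, nd),
                      mixed = ifelse(stats::runif(nd) < config$p_cloudy,
                                     config$cloudy_amplitude_mult, 1))

  # daily soil water content
  fc <- config$field_capacity
  swc_daily <- switch(config$drought_mode,
    none = pmin(fc, pmax(0, config$swc_initial + stats::rnorm(nd, 0, 0.3))),
    progressive = pmax(5, config$swc_initial -
                         config$swc_daily_depletion * (seq_len(nd) - 1L)),
    constant_gradient = {
      lo <- config$swc_target_range[1L]; hi <- config$swc_target_range[2L]
      s <- numeric(nd); cur <- hi
      for (d in seq_len(nd)) {
        s[d] <- cur
        cur <- cur - 1.2
        if (cur < lo) cur <- hi
      }
      s
    })

  # stress coupling: amplitude inflates with soil-water deficit (saturating)
  deficit <- pmax(0, fc - swc_daily)
  stress_mult <- 1 + config$stress_gain * deficit^2 / (deficit^2 + config$stress_k^2)
  amp <- config$seasonal_amplitude * mult * stress_mult

  # growth collapses sharply once the amplitude reaches the arrest MDS
  # (decline capped at 1.5x the healthy rate: stems dehydrate, they do not
  # shrink without bound), and the nocturnal recovery deficit builds up
  # smoothly around the threshold -- the day before arrest already shows
  # incomplete recovery while its dawn maximum still rises
  if (config$drought_mode == "progressive") {
    theta <- config$arrest_mds_true
    growth <- config$growth_rate * pmax(1 - (amp / theta)^40, -1.5)
    rho <- 0.3 / (1 + exp(-(amp - theta) / 3))  # recovery deficit fraction
    rho[rho < 1e-6] <- 0
  } else {
    growth <- rep(config$growth_rate, nd)
    rho <- numeric(nd)
  }

  # environment: shared standardized diurnal driver, loadings calibrated so
  # cor(T, H) hits the target in expectation
  solar <- pmax(0, sin(pi * (u - 7) / 13)) * (u >= 7 & u <= 20)
  drv <- mult[day] * solar
  drv <- (drv - mean(drv)) / stats::sd(drv)
  rr <- abs(config$r_temp_rh)
  sig_ratio <- sqrt((1 - rr) / rr)
  a_t <- 5; a_h <- 12
  temp <- 20 + a_t * drv + .ar1_noise(n, a_t * sig_ratio, 0.7)
  rh <- 65 - a_h * drv + .ar1_noise(n, a_h * sig_ratio, 0.7)
  rh <- pmin(100, pmax(2, rh))
  light <- config$light_max * mult[day] * solar + .ar1_noise(n, 1500, 0.5)
  light <- pmin(200000, pmax(0, light))
  day_centre <- (seq_len(nd) - 0.5) * STEPS_PER_DAY
  vwc <- stats::approx(day_centre, swc_daily, xout = seq_len(n), rule = 2)$y +
    .ar1_noise(n, 0.1, 0.8)
  vwc <- pmin(fc, pmax(0, vwc))
  env <- env_series(time, temp, rh, light, vwc)

  resid <- if (config$residual_structure)
    generate_residual_structure(env, config$residual_amplitude,
                                config$residual_noise_sd)
  else list(residual = numeric(n), deterministic = numeric(n),
            ground_truth = list(form = "none"))

  # stem template. Morning gain (positive growth) accrues linearly up to the
  # contraction onset and holds, the dip is subtracted from the accrued
  # level, so MDS equals the day's amplitude exactly. The evening recovery
  # falls short of the morning maximum by the deficit
  # D = amp * rho + max(-growth, 0): zero on healthy days (full recovery at
  # recovery_end, RT < 24), positive under stress (RT = 24), and carried
  # into the next day's baseline so the dawn maximum declines (DI <= 0)
  # once deficits outpace morning gains.
  morning <- pmax(growth, 0)
  rec_deficit <- pmin(amp * rho + pmax(-growth, 0), amp)
  net <- morning - rec_deficit
  rise <- pmin(u / config$onset_h, 1)
  lvl <- config$base_diameter + c(0, cumsum(net))[day]
  dip <- .dip_shape(u, config$onset_h, config$umin_h, config$urec_h)
  frac <- (rec_deficit / amp)[day]
  dip_eff <- ifelse(u > config$umin_h, frac + (1 - frac) * dip, dip)
  trend_true <- lvl + morning[day] * rise
  y0 <- trend_true - amp[day] * dip_eff + resid$residual

  vals <- matrix(NA_real_, n, config$n_replicates)
  for (j in seq_len(config$n_replicates))
    vals[, j] <- y0 + .ar1_noise(n, config$noise_sd, config$noise_phi)
  stem <- stem_series(time, vals,
                      replicate_ids = paste0("r", seq_len(config$n_replicates)),
                      treatment_id = config$drought_mode)

  # ground-truth bookkeeping on the noise-free signal
  dates <- as.Date(config$start) + seq_len(nd) - 1L
  daily <- data.frame(date = dates, regime_mult = mult, swc = swc_daily,
                      amplitude = amp, growth = growth,
                      mxsd = NA_real_, mnsd = NA_real_, mds = NA_real_,
                      di = NA_real_, rt = NA_real_)
  for (d in seq_len(nd)) {
    idx <- which(day == d)
    v <- y0[idx]
    im <- which.max(v); ii <- which.min(v)
    daily$mxsd[d] <- v[im]; daily$mnsd[d] <- v[ii]
    daily$mds[d] <- v[im] - v[ii]
    after <- ii:length(v)
    hit <- after[v[after] >= v[im]]
    daily$rt[d] <- if (length(hit)) (hit[1L] - ii) * 0.5 else 24
  }
  daily$di[-1L] <- diff(daily$mxsd)
  arrest_idx <- if (config$drought_mode == "progressive")
    which(daily$mds >= config$arrest_mds_true & !is.na(daily$di) & daily$di <= 0)
  else integer(0)
  truth <- list(daily = daily,
                arrest_day = if (length(arrest_idx)) dates[arrest_idx[1L]] else as.Date(NA),
                arrest_mds = if (length(arrest_idx)) daily$mds[arrest_idx[1L]] else NA_real_,
                signal = y0, trend_true = trend_true,
                residual_true = resid$residual,
                residual_ground_truth = resid$ground_truth,
                config = config)
  list(stem = stem, env = env, truth = truth)
}

#' Write a scenario to disk
#'
#' Writes the sensor table in the schema [read_sensor_table()] reads, plus a
#' ground-truth sidecar (`<prefix>_truth.json`) with the daily bookkeeping
#' and arrest information.
#'
#' @param scenario output of [generate_scenario()].
#' @param prefix path prefix; files `<prefix>.csv` and `<prefix>_truth.json`
#'   are written.
#' @return the data file path, invisibly.
#' @export
write_scenario <- function(scenario, prefix) {
  path <- paste0(prefix, ".csv")
  write_sensor_table(scenario$stem, scenario$env, path)
  tr <- scenario$truth
  side <- list(daily = lapply(seq_len(nrow(tr$daily)), function(i) {
                 r <- tr$daily[i, ]
                 list(date = as.character(r$date), regime_mult = r$regime_mult,
                      swc = r$swc, amplitude = r$amplitude, growth = r$growth,
                      mxsd = r$mxsd, mnsd = r$mnsd, mds = r$mds,
                      di = r$di, rt = r$rt)
               }),
               arrest_day = as.character(tr$arrest_day),
               arrest_mds = tr$arrest_mds,
               residual_ground_truth = tr$residual_ground_truth,
               config = unclass(tr$config))
  jsonlite::write_json(side, paste0(prefix, "_truth.json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Seeded daily (SWC, MDS) pairs with an exact target correlation structure
#'
#' Bivariate Gaussian sampler (Cholesky construction) for correlation
#' diagnostics: daily soil water content and maximum daily shrinkage with a
#' specified population Pearson correlation.
#'
#' @param n_days number of daily pairs.
#' @param r target Pearson correlation (default -0.48).
#' @param swc_mean,swc_sd,mds_mean,mds_sd marginal moments.
#' @param seed optional seed.
#' @return data.frame with columns `swc` and `mds`.
#' @export
generate_correlated_daily <- function(n_days, r = -0.48, swc_mean = 20,
                                      swc_sd = 3, mds_mean = 70, mds_sd = 20,
                                      seed = NULL) {
  stopifnot(abs(r) < 1)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n_days); z2 <- stats::rnorm(n_days)
  mds <- mds_mean + mds_sd * z1
  swc <- swc_mean + swc_sd * (r * z1 + sqrt(1 - r^2) * z2)
  data.frame(swc = swc, mds = mds)
}
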