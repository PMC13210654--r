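# Builders shared across test files. All fixtures are generated in code.

t_grid <- function(n, start = "2025-05-01 00:00:00") {
  as.POSIXct(start, tz = "UTC") + 1800 * (seq_len(n) - 1L)
}

make_stem <- function(values, start = "2025-05-01 00:00:00", ...) {
  stem_series(t_grid(NROW(values), start), values, ...)
}

# sinusoidal stem signal with a 24-h period
sine_stem <- function(days, amplitude = 30, mean_level = 5000, phase = 0) {
  n <- days * 48L
  make_stem(mean_level + amplitude * sin(2 * pi * (seq_len(n) - 1) / 48 + phase))
}

flat_env <- function(n, vwc = 24) {
  env_series(t_grid(n), temp_c = rep(22, n), rh_pct = rep(60, n),
             light_lux = rep(10000, n), vwc_pct = rep(vwc, n))
}

# one 48-sample diurnal cycle with its maximum at 09:30 and minimum at
# 16:30, hitting the given extremes exactly; the evening recovers to just
# below the maximum so the dawn value stays the cycle max
cycle_from_extremes <- function(max_val, min_val, date = "2025-05-04") {
  i_max <- 20L   # 09:30
  i_min <- 34L   # 16:30
  mid <- (max_val + min_val) / 2
  v <- numeric(48L)
  v[1:i_max] <- seq(mid, max_val, length.out = i_max)
  v[i_max:i_min] <- seq(max_val, min_val, length.out = i_min - i_max + 1L)
  v[i_min:48] <- seq(min_val, max_val - 0.1 * (max_val - min_val),
                     length.out = 48L - i_min + 1L)
  make_stem(v, start = paste(date, "00:00:00"))
}

# the subset of bundled worked-example rows whose printed MDS equals the
# printed extremes difference at 2-decimal precision
consistent_worked_rows <- function() {
  df <- stress_worked_examples()
  df[abs((df$dawn_max_um - df$dusk_min_um) - df$mds_um) < 0.005, ]
}
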