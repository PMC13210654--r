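# Internal helpers shared across modules.

STEP_SECONDS <- 1800L          # 30-min sampling grid
STEPS_PER_DAY <- 48L

#' @noRd
.is_uniform_grid <- function(time, step = STEP_SECONDS) {
  if (length(time) < 2L) return(TRUE)
  d <- as.numeric(diff(time), units = "secs")
  all(abs(d - step) < 1e-6)
}

#' Parse "HH:MM" clock time to seconds since midnight.
#' @noRd
.clock_seconds <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop("clock time must be 'HH:MM', got: ", x, call. = FALSE)
  h <- as.integer(m[2]); mn <- as.integer(m[3])
  if (h > 23L || mn > 59L) stop("invalid clock time: ", x, call. = FALSE)
  h * 3600L + mn * 60L
}

#' Seconds since local midnight for POSIXct timestamps (timezone-naive logic).
#' @noRd
.seconds_of_day <- function(time) {
  lt <- as.POSIXlt(time)
  lt$hour * 3600L + lt$min * 60L + round(lt$sec)
}

#' Run-length encoding of NA runs; returns data.frame(start, end, len).
#' @noRd
.na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Stationary AR(1) noise with a given marginal standard deviation.
#' @noRd
.ar1_noise <- function(n, sd, phi) {
  if (sd <= 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1L] <- stats::rnorm(1L, 0, sd)
  if (n > 1L) {
    eps <- stats::rnorm(n - 1L, 0, innov_sd)
    for (i in 2:n) e[i] <- phi * e[i - 1L] + eps[i - 1L]
  }
  e
}

#' @noRd
.assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(name, " must be finite", call. = FALSE)
  invisible(x)
}
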