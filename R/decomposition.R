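# Seasonal-trend decomposition using Loess of the 30-min stem signal into
# additive trend + seasonal + remainder.

#' STL decomposition of a stem-diameter series
#'
#' Decomposes the (gap-free, single-column) series into
#' `trend + seasonal + remainder` by seasonal-trend decomposition using
#' Loess, with a seasonal period of 48 steps (one 24-h physiological cycle at
#' 30-min sampling) and a 336-step (7-day) trend smoothing window. The
#' seasonal sub-series smoother is periodic (maximally smooth seasonal),
#' robustness iterations are off, and the remainder is stored as
#' `y - trend - seasonal` so additivity holds exactly.
#'
#' @param series a gap-free single-column [stem_series], or a numeric vector.
#' @param period seasonal period in steps (default 48).
#' @param trend_window trend Loess window in steps (default 336); an even
#'   value is adjusted to the next odd integer with a warning.
#' @param robust logical; robustness iterations (default off).
#' @return an object of class `stl_components`: list with `time`, `y`,
#'   `trend`, `seasonal`, `remainder`, `period`, `trend_window`.
#' @export
stl_decompose <- function(series, period = 48L, trend_window = 336L,
                          robust = FALSE) {
  if (inherits(series, "stem_series")) {
    .single_column(series, "STL decomposition")
    y <- series$values[, 1L]
    tm <- series$time
  } else {
    y <- as.numeric(series)
    tm <- NULL
  }
  if (anyNA(y))
    stop("series contains gaps; impute before decomposition", call. = FALSE)
  if (length(y) < 2L * period)
    stop("need at least two full periods (", 2L * period, " samples)", call. = FALSE)
  tw <- as.integer(trend_window)
  if (tw %% 2L == 0L) {
    warning("trend_window must be odd; adjusted to ", tw + 1L)
    tw <- tw + 1L
  }
  fit <- stats::stl(stats::ts(y, frequency = period), s.window = "periodic",
                    t.window = tw, robust = robust)
  trend <- as.numeric(fit$time.series[, "trend"])
  seasonal <- as.numeric(fit$time.series[, "seasonal"])
  structure(list(time = tm, y = y, trend = trend, seasonal = seasonal,
                 remainder = y - trend - seasonal,
                 period = as.integer(period), trend_window = tw),
            class = "stl_components")
}

#' @export
print.stl_components <- function(x, ...) {
  cat("<stl_components> n =", length(x$y), " period =", x$period,
      " trend_window =", x$trend_window, "\n")
  print(decomposition_report(x))
  invisible(x)
}

#' Variance share of each decomposition component
#'
#' @param components an `stl_components` object.
#' @return data.frame with per-component variance and its share of the summed
#'   component variances (shares sum to ~1 on centred data).
#' @export
decomposition_report <- function(components) {
  stopifnot(inherits(components, "stl_components"))
  v <- c(trend = stats::var(components$trend),
         seasonal = stats::var(components$seasonal),
         remainder = stats::var(components$remainder))
  data.frame(component = names(v), variance = as.numeric(v),
             share = as.numeric(v) / sum(v), row.names = NULL)
}

#' Export STL components as a delimited table
#' @param components an `stl_components` object.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_components <- function(components, path, sep = ",") {
  stopifnot(inherits(components, "stl_components"))
  ts_col <- if (is.null(components$time)) seq_along(components$y)
            else format(components$time, "%Y-%m-%dT%H:%M:%S")
  df <- data.frame(timestamp = ts_col, trend = components$trend,
                   seasonal = components$seasonal, remainder = components$remainder)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
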