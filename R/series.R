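#' Stem-diameter series
#'
#' Container for a uniformly sampled (30-min grid) dendrometer record with one
#' column per replicate sensor. Missing samples are `NA` in `values` and carry
#' a per-sample quality flag: `"observed"`, `"interpolated"`, `"analog"`
#' (analog-day filled), `"removed"` (outlier) or `"missing"`.
#'
#' @param time `POSIXct` timestamps, strictly increasing on a 30-min step.
#' @param values numeric matrix (or vector) of stem diameter in micrometres,
#'   one column per replicate.
#' @param replicate_ids character labels, one per column.
#' @param treatment_id single treatment label.
#' @param flags optional character matrix of quality flags, same shape as
#'   `values`; defaults to `"observed"`/`"missing"` from the NA pattern.
#' @return An object of class `stem_series`.
#' @export
stem_series <- function(time, values, replicate_ids = NULL,
                        treatment_id = "T1", flags = NULL) {
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct", call. = FALSE)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(time))
    stop("values and time lengths differ", call. = FALSE)
  if (ncol(values) < 1L) stop("need at least one replicate", call. = FALSE)
  if (any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (!.is_uniform_grid(time))
    stop("timestamps must lie on a uniform 30-min grid", call. = FALSE)
  if (is.null(replicate_ids)) {
    replicate_ids <- colnames(values)
    if (is.null(replicate_ids)) replicate_ids <- paste0("rep", seq_len(ncol(values)))
  }
  colnames(values) <- replicate_ids
  if (is.null(flags)) {
    flags <- matrix(ifelse(is.na(values), "missing", "observed"),
                    nrow = nrow(values), dimnames = dimnames(values))
  } else {
    flags <- as.matrix(flags)
    if (!identical(dim(flags), dim(values)))
      stop("flags must have the same shape as values", call. = FALSE)
  }
  structure(list(time = time, values = values, flags = flags,
                 replicate_ids = replicate_ids, treatment_id = treatment_id),
            class = "stem_series")
}

#' Environmental covariate series
#'
#' Greenhouse microclimate and soil record aligned to a stem-diameter series:
#' air temperature (deg C), relative humidity (%), light intensity (lux) and
#' soil volumetric water content (% by volume).
#'
#' @param time `POSIXct` timestamps on the 30-min grid.
#' @param temp_c,rh_pct,light_lux,vwc_pct numeric vectors.
#' @return An object of class `env_series`.
#' @export
env_series <- function(time, temp_c, rh_pct, light_lux, vwc_pct) {
  n <- length(time)
  stopifnot(length(temp_c) == n, length(rh_pct) == n,
            length(light_lux) == n, length(vwc_pct) == n)
  if (!.is_uniform_grid(time))
    stop("timestamps must lie on a uniform 30-min grid", call. = FALSE)
  ok_rh <- is.na(rh_pct) | (rh_pct >= 0 & rh_pct <= 100)
  if (!all(ok_rh)) stop("relative humidity must be within [0, 100]", call. = FALSE)
  ok_sw <- is.na(vwc_pct) | (vwc_pct >= 0 & vwc_pct <= 100)
  if (!all(ok_sw)) stop("soil VWC must be within [0, 100]", call. = FALSE)
  structure(list(time = time, temp_c = as.numeric(temp_c),
                 rh_pct = as.numeric(rh_pct), light_lux = as.numeric(light_lux),
                 vwc_pct = as.numeric(vwc_pct)),
            class = "env_series")
}

#' @export
print.stem_series <- function(x, ...) {
  cat("<stem_series> ", length(x$time), " samples x ", ncol(x$values),
      " replicate(s), treatment ", x$treatment_id, "\n", sep = "")
  cat("  span: ", format(x$time[1L]), " .. ", format(x$time[length(x$time)]),
      " (30-min grid)\n", sep = "")
  tab <- table(factor(x$flags, levels = c("observed", "interpolated",
                                          "analog", "removed", "missing")))
  cat("  flags:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.env_series <- function(x, ...) {
  cat("<env_series> ", length(x$time), " samples: temp_c, rh_pct, light_lux, vwc_pct\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.stem_series <- function(x, ...) {
  df <- data.frame(timestamp = x$time)
  for (j in seq_len(ncol(x$values))) df[[paste0("sd_", x$replicate_ids[j])]] <- x$values[, j]
  for (j in seq_len(ncol(x$flags)))  df[[paste0("flag_", x$replicate_ids[j])]] <- x$flags[, j]
  df
}

#' @export
as.data.frame.env_series <- function(x, ...) {
  data.frame(timestamp = x$time, temp_c = x$temp_c, rh_pct = x$rh_pct,
             light_lux = x$light_lux, vwc_pct = x$vwc_pct)
}

#' Number of samples in a series
#' @param x a `stem_series` or `env_series`.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$time)

#' @noRd
.check_aligned <- function(series, env) {
  if (length(series$time) != length(env$time) ||
      any(as.numeric(series$time) != as.numeric(env$time)))
    stop("stem and environment series are not aligned on the same timeline",
         call. = FALSE)
  invisible(TRUE)
}

#' @noRd
.single_column <- function(series, what = "this operation") {
  if (ncol(series$values) != 1L)
    stop(what, " requires a single-column (aggregated) series; call aggregate_replicates() first",
         call. = FALSE)
  invisible(series)
}
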