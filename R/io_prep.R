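# Reading, validation, cleaning, aggregation and normalization of raw
# 30-min sensor tables.

#' Read a raw sensor table
#'
#' Reads a delimited text table with header
#' `timestamp, sd_<rep>..., temp_c, rh_pct, light_lux, vwc_pct` (plus optional
#' `flag_<rep>` columns written by [write_sensor_table()]) into an aligned
#' pair of series. Timestamps must be ISO-8601 and parseable; they are
#' validated against a 30-min grid and any missing grid slot is inserted as a
#' flagged gap.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param treatment_id treatment label attached to the stem series.
#' @return list with elements `stem` ([stem_series]) and `env` ([env_series]).
#' @export
read_sensor_table <- function(path, sep = ",", treatment_id = "T1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"timestamp" %in% names(df)) stop("missing 'timestamp' column", call. = FALSE)
  tm <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(tm))
    stop("unparseable timestamps at rows: ",
         paste(utils::head(which(is.na(tm)), 5L), collapse = ", "), call. = FALSE)
  if (anyDuplicated(tm)) {
    dup <- format(tm[duplicated(tm)])
    stop("duplicate timestamps: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  o <- order(tm); tm <- tm[o]; df <- df[o, , drop = FALSE]
  off <- as.numeric(tm - tm[1L], units = "secs")
  if (any(abs(off - round(off / STEP_SECONDS) * STEP_SECONDS) > 1e-6))
    stop("timestamps do not lie on a 30-min grid", call. = FALSE)
  grid <- seq(tm[1L], tm[length(tm)], by = STEP_SECONDS)
  idx <- match(as.numeric(tm), as.numeric(grid))

  sd_cols <- grep("^sd_", names(df), value = TRUE)
  if (length(sd_cols) == 0L) stop("no stem-diameter columns (sd_*) found", call. = FALSE)
  reps <- sub("^sd_", "", sd_cols)
  vals <- matrix(NA_real_, nrow = length(grid), ncol = length(sd_cols),
                 dimnames = list(NULL, reps))
  for (j in seq_along(sd_cols)) vals[idx, j] <- as.numeric(df[[sd_cols[j]]])
  flags <- NULL
  flag_cols <- paste0("flag_", reps)
  if (all(flag_cols %in% names(df))) {
    flags <- matrix("missing", nrow = length(grid), ncol = length(reps),
                    dimnames = list(NULL, reps))
    for (j in seq_along(flag_cols)) flags[idx, j] <- as.character(df[[flag_cols[j]]])
  }
  stem <- stem_series(grid, vals, replicate_ids = reps,
                      treatment_id = treatment_id, flags = flags)

  envv <- function(col) {
    out <- rep(NA_real_, length(grid))
    if (col %in% names(df)) out[idx] <- as.numeric(df[[col]])
    out
  }
  env <- env_series(grid, envv("temp_c"), envv("rh_pct"),
                    envv("light_lux"), envv("vwc_pct"))
  list(stem = stem, env = env)
}

#' Write a stem + environment pair as a delimited sensor table
#'
#' Inverse of [read_sensor_table()]; flag columns are included so cleaned
#' series round-trip losslessly.
#'
#' @param stem a [stem_series].
#' @param env an [env_series] on the same timeline.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_sensor_table <- function(stem, env, path, sep = ",") {
  .check_aligned(stem, env)
  df <- cbind(as.data.frame(stem),
              as.data.frame(env)[, c("temp_c", "rh_pct", "light_lux", "vwc_pct")])
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove outliers by rolling Tukey fences
#'
#' Flags samples falling outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with the
#' quartiles computed in a centred rolling window, as `"removed"` (they become
#' gaps). The boxplot rule applied per window preserves the diurnal rhythm
#' while tracking slow growth drift.
#'
#' @param series a [stem_series].
#' @param window_days rolling window length in days (minimum 2).
#' @param k fence multiplier (1.5 = standard boxplot whisker rule).
#' @return the cleaned [stem_series].
#' @export
remove_outliers <- function(series, window_days = 2, k = 1.5) {
  stopifnot(inherits(series, "stem_series"))
  if (window_days < 2)
    stop("outlier window must span at least 2 days of samples", call. = FALSE)
  w <- as.integer(round(window_days * STEPS_PER_DAY))
  half <- w %/% 2L
  n <- nrow(series$values)
  warned <- FALSE
  for (j in seq_len(ncol(series$values))) {
    x <- series$values[, j]
    drop <- logical(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      xs <- x[lo:hi]
      xs <- xs[!is.na(xs)]
      if (length(xs) == 0L) {
        if (!warned) { warning("window with no observed samples; left unchanged"); warned <- TRUE }
        next
      }
      q <- stats::quantile(xs, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2L] - q[1L]
      if (!is.na(x[i]) && (x[i] < q[1L] - k * iqr || x[i] > q[2L] + k * iqr))
        drop[i] <- TRUE
    }
    series$values[drop, j] <- NA_real_
    series$flags[drop, j] <- "removed"
  }
  series
}

#' Fill gaps by interpolation or analog-day transfer
#'
#' Tiered imputation: gap runs of at most `sparse_max_steps` samples with
#' observed neighbours on both sides are filled by linear interpolation;
#' longer runs (and runs touching a series boundary) are filled from an
#' analog day -- the day whose z-scored daily-mean weather (temperature,
#' humidity, light) is closest to the gap day's -- with the donor segment
#' level-shifted by a linear blend of the endpoint offsets so the fill joins
#' the observed record continuously. Boundary gaps are never linearly
#' extrapolated.
#'
#' @param series a [stem_series] with flagged gaps.
#' @param env an aligned [env_series] used for analog-day matching.
#' @param sparse_max_steps largest gap (in 30-min steps) treated as sparse
#'   (default 4 = 2 h).
#' @return the imputed [stem_series]; filled samples are flagged
#'   `"interpolated"` or `"analog"`.
#' @export
impute_gaps <- function(series, env, sparse_max_steps = 4L) {
  stopifnot(inherits(series, "stem_series"), inherits(env, "env_series"))
  .check_aligned(series, env)
  n <- nrow(series$values)
  day_id <- as.integer(as.numeric(as.Date(format(series$time, "%Y-%m-%d"))))
  day_id <- day_id - min(day_id) + 1L
  slot <- .seconds_of_day(series$time) %/% STEP_SECONDS + 1L  # 1..48 clock slot

  # z-scored daily mean weather for analog matching
  wdf <- data.frame(day = day_id, t = env$temp_c, h = env$rh_pct, l = env$light_lux)
  agg <- stats::aggregate(wdf[c("t", "h", "l")], by = list(day = wdf$day),
                          FUN = function(z) mean(z, na.rm = TRUE))
  zs <- scale(agg[c("t", "h", "l")])
  zs[!is.finite(zs)] <- 0

  for (j in seq_len(ncol(series$values))) {
    x <- series$values[, j]
    runs <- .na_runs(x)
    if (nrow(runs) == 0L) next
    for (r in seq_len(nrow(runs))) {
      s <- runs$start[r]; e <- runs$end[r]; len <- runs$len[r]
      has_left <- s > 1L && !is.na(x[s - 1L])
      has_right <- e < n && !is.na(x[e + 1L])
      if (len <= sparse_max_steps && has_left && has_right) {
        x[s:e] <- stats::approx(x = c(s - 1L, e + 1L), y = c(x[s - 1L], x[e + 1L]),
                                xout = s:e)$y
        series$flags[s:e, j] <- "interpolated"
        next
      }
      # analog-day fill
      gap_day <- day_id[(s + e) %/% 2L]
      cand <- setdiff(agg$day, gap_day)
      # donor day must have fully observed values in this column
      ok <- vapply(cand, function(d) all(!is.na(x[day_id == d])) &&
                     sum(day_id == d) == STEPS_PER_DAY, logical(1L))
      cand <- cand[ok]
      if (length(cand) == 0L)
        stop("no eligible analog donor day for gap spanning samples ",
             s, "..", e, call. = FALSE)
      gi <- match(gap_day, agg$day)
      di <- match(cand, agg$day)
      dist <- sqrt(rowSums((zs[di, , drop = FALSE] -
                              matrix(zs[gi, ], nrow = length(di), ncol = 3L, byrow = TRUE))^2))
      donor <- cand[which.min(dist)]
      donor_by_slot <- rep(NA_real_, STEPS_PER_DAY)
      dsel <- which(day_id == donor)
      donor_by_slot[slot[dsel]] <- x[dsel]
      fill <- donor_by_slot[slot[s:e]]
      # level shift: blend endpoint offsets (constant shift at a boundary)
      off_l <- if (has_left) x[s - 1L] - donor_by_slot[slot[s - 1L]] else NA_real_
      off_r <- if (has_right) x[e + 1L] - donor_by_slot[slot[e + 1L]] else NA_real_
      if (is.na(off_l) && is.na(off_r))
        stop("gap spanning samples ", s, "..", e,
             " has no observed boundary to anchor an analog fill", call. = FALSE)
      if (is.na(off_l)) off_l <- off_r
      if (is.na(off_r)) off_r <- off_l
      wts <- if (len == 1L) 0.5 else seq(0, 1, length.out = len)
      x[s:e] <- fill + (1 - wts) * off_l + wts * off_r
      series$flags[s:e, j] <- "analog"
    }
    series$values[, j] <- x
  }
  series
}

#' Aggregate replicate sensors to a single series
#'
#' Per-timestep arithmetic mean over the non-missing replicates; a step with
#' no available replicate propagates a gap.
#'
#' @param series a multi-replicate [stem_series].
#' @return a single-column [stem_series] (replicate id `"mean"`).
#' @export
aggregate_replicates <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  v <- rowMeans(series$values, na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_
  # flag: worst contributing source wins
  fl <- apply(series$flags, 1L, function(f) {
    f <- f[!(f %in% c("missing", "removed"))]
    if (length(f) == 0L) return("missing")
    for (lev in c("analog", "interpolated")) if (lev %in% f) return(lev)
    "observed"
  })
  fl[is.na(v)] <- "missing"
  stem_series(series$time, matrix(v, ncol = 1L), replicate_ids = "mean",
              treatment_id = series$treatment_id,
              flags = matrix(fl, ncol = 1L))
}

#' Fit a feature normalizer
#'
#' Min-max mode maps the training minimum to 0 and maximum to 1; z-score mode
#' centres and scales by the population standard deviation (divide by n).
#' Parameters must be estimated from the training window only.
#'
#' @param x numeric vector or matrix (features in columns) from the training
#'   window.
#' @param mode `"minmax"` or `"zscore"`.
#' @return an object of class `normalizer` holding per-feature parameters.
#' @export
fit_normalizer <- function(x, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("f", seq_len(ncol(x)))
  if (mode == "minmax") {
    mn <- apply(x, 2L, min, na.rm = TRUE)
    mx <- apply(x, 2L, max, na.rm = TRUE)
    bad <- !(mx > mn)
    if (any(bad))
      stop("degenerate (constant) feature(s): ", paste(nms[bad], collapse = ", "),
           call. = FALSE)
    p <- list(mode = mode, min = mn, max = mx, features = nms)
  } else {
    mu <- colMeans(x, na.rm = TRUE)
    sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2, na.rm = TRUE))  # population sd
    bad <- !(sdv > 0)
    if (any(bad))
      stop("degenerate (constant) feature(s): ", paste(nms[bad], collapse = ", "),
           call. = FALSE)
    p <- list(mode = mode, mean = mu, sd = sdv, features = nms)
  }
  structure(p, class = "normalizer")
}

#' Apply a fitted normalizer
#' @param x numeric vector or matrix in native units.
#' @param params a `normalizer` from [fit_normalizer()].
#' @return normalized values, same shape as `x`.
#' @export
apply_normalizer <- function(x, params) {
  stopifnot(inherits(params, "normalizer"))
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  out <- if (params$mode == "minmax")
    sweep(sweep(x, 2L, params$min), 2L, params$max - params$min, "/")
  else
    sweep(sweep(x, 2L, params$mean), 2L, params$sd, "/")
  if (vec) drop(out) else out
}

#' Invert a fitted normalizer
#' @param x normalized values.
#' @param params a `normalizer` from [fit_normalizer()].
#' @return values in native units; `invert(apply(x)) == x` to rounding.
#' @export
invert_normalizer <- function(x, params) {
  stopifnot(inherits(params, "normalizer"))
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  out <- if (params$mode == "minmax")
    sweep(sweep(x, 2L, params$max - params$min, "*"), 2L, params$min, "+")
  else
    sweep(sweep(x, 2L, params$sd, "*"), 2L, params$mean, "+")
  if (vec) drop(out) else out
}
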