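# Diurnal cycle segmentation and stem-diameter variation indicators:
# MXSD / MNSD (daily extremes), MDS (maximum daily shrinkage), DI (daily
# increment of the maximum) and RT (recovery time, capped at 24 h).

#' Segment a stem series into diurnal cycles
#'
#' Splits a single-column series into consecutive, non-overlapping 24-h
#' windows starting at a clock-time anchor. Partial head/tail windows are
#' flagged incomplete.
#'
#' @param series a single-column [stem_series].
#' @param anchor cycle start clock time, `"HH:MM"` (default midnight).
#' @return list of cycles; each has `start` (POSIXct), `date` (calendar date
#'   of the window start), `time`, `values` and `complete` (all 48 slots
#'   present).
#' @export
segment_cycles <- function(series, anchor = "00:00") {
  stopifnot(inherits(series, "stem_series"))
  .single_column(series, "cycle segmentation")
  n <- length(series$time)
  if (n < STEPS_PER_DAY) {
    warning("series shorter than one 24-h cycle; no cycles")
    return(list())
  }
  a <- .clock_seconds(anchor)
  secs <- as.numeric(series$time)
  sod <- .seconds_of_day(series$time)
  cyc_start_num <- secs - ((sod - a) %% 86400)
  out <- list()
  for (s in unique(cyc_start_num)) {
    idx <- which(cyc_start_num == s)
    start <- as.POSIXct(s, origin = "1970-01-01", tz = "UTC")
    out[[length(out) + 1L]] <- list(
      start = start,
      date = as.Date(format(start, "%Y-%m-%d")),
      time = series$time[idx],
      values = series$values[idx, 1L],
      complete = length(idx) == STEPS_PER_DAY)
  }
  out
}

#' Compute diurnal water-status indicators per cycle
#'
#' For each complete cycle with enough valid samples: MXSD/MNSD are the cycle
#' maximum/minimum (earliest occurrence on ties) with their times;
#' MDS = MXSD - MNSD; DI is the day-over-day difference of MXSD (defined only
#' when the previous calendar day has a usable cycle); RT is the time in
#' hours from the minimum until the signal first re-attains the same cycle's
#' MXSD, at the 30-min sample resolution, capped at 24 h when recovery is
#' incomplete within the window.
#'
#' @param cycles output of [segment_cycles()].
#' @param min_valid_fraction minimum fraction of non-missing samples for a
#'   cycle's indicators to be computed (default 0.9).
#' @return a data.frame of class `indicator_records` with columns
#'   `date, mxsd_um, mnsd_um, t_mxsd, t_mnsd, mds_um, di_um, rt_h, n_valid`.
#' @export
compute_cycle_indicators <- function(cycles, min_valid_fraction = 0.9) {
  cycles <- Filter(function(cy) cy$complete, cycles)
  n <- length(cycles)
  rec <- data.frame(
    date = as.Date(character()), mxsd_um = numeric(), mnsd_um = numeric(),
    t_mxsd = as.POSIXct(character(), tz = "UTC"),
    t_mnsd = as.POSIXct(character(), tz = "UTC"),
    mds_um = numeric(), di_um = numeric(), rt_h = numeric(), n_valid = integer())
  if (n == 0L) return(structure(rec, class = c("indicator_records", "data.frame")))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cy <- cycles[[i]]
    v <- cy$values
    valid <- which(!is.na(v))
    if (length(valid) < min_valid_fraction * STEPS_PER_DAY) {
      rows[[i]] <- data.frame(date = cy$date, mxsd_um = NA_real_, mnsd_um = NA_real_,
                              t_mxsd = as.POSIXct(NA, tz = "UTC"),
                              t_mnsd = as.POSIXct(NA, tz = "UTC"),
                              mds_um = NA_real_, di_um = NA_real_, rt_h = NA_real_,
                              n_valid = length(valid))
      next
    }
    i_max <- valid[which.max(v[valid])]   # earliest tie by which.max
    i_min <- valid[which.min(v[valid])]
    mxsd <- v[i_max]; mnsd <- v[i_min]
    after <- valid[valid >= i_min]
    rec_idx <- after[v[after] >= mxsd]
    rt <- if (length(rec_idx) == 0L) 24
          else as.numeric(cy$time[rec_idx[1L]] - cy$time[i_min], units = "hours")
    rows[[i]] <- data.frame(date = cy$date, mxsd_um = mxsd, mnsd_um = mnsd,
                            t_mxsd = cy$time[i_max], t_mnsd = cy$time[i_min],
                            mds_um = mxsd - mnsd, di_um = NA_real_, rt_h = rt,
                            n_valid = length(valid))
  }
  rec <- do.call(rbind, rows)
  # DI: current MXSD minus previous calendar day's MXSD
  for (i in seq_len(nrow(rec))) {
    prev <- which(rec$date == rec$date[i] - 1L)
    if (length(prev) == 1L && !is.na(rec$mxsd_um[i]) && !is.na(rec$mxsd_um[prev]))
      rec$di_um[i] <- rec$mxsd_um[i] - rec$mxsd_um[prev]
  }
  structure(rec, class = c("indicator_records", "data.frame"))
}

#' Convenience wrapper: segment and compute indicators in one call
#'
#' @inheritParams segment_cycles
#' @inheritParams compute_cycle_indicators
#' @return an `indicator_records` data.frame; see [compute_cycle_indicators()].
#' @export
cycle_indicators <- function(series, anchor = "00:00", min_valid_fraction = 0.9) {
  compute_cycle_indicators(segment_cycles(series, anchor), min_valid_fraction)
}

#' Write an indicator table to delimited text
#'
#' @param records an `indicator_records` data.frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
indicator_table <- function(records, path, sep = ",") {
  df <- as.data.frame(records)
  df$date <- format(df$date)
  df$t_mxsd <- format(df$t_mxsd, "%Y-%m-%dT%H:%M:%S")
  df$t_mnsd <- format(df$t_mnsd, "%Y-%m-%dT%H:%M:%S")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indicator table written by [indicator_table()]
#' @param path file path.
#' @param sep field separator.
#' @return an `indicator_records` data.frame.
#' @export
read_indicator_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$t_mxsd <- as.POSIXct(df$t_mxsd, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  df$t_mnsd <- as.POSIXct(df$t_mnsd, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  structure(df, class = c("indicator_records", "data.frame"))
}
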