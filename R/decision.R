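# Plant-soil dual-threshold irrigation decision engine. Irrigation triggers
# only when the physiological condition (MDS at/above the trigger) AND the
# soil condition (VWC at/below the ceiling) both hold; the remaining
# quadrants name why not: an atmospheric false positive (shrinkage without
# soil depletion) or a masked deficit (dry soil without a shrinkage signal).

#' Decision thresholds
#'
#' @param mds_trigger MDS trigger in micrometres (default 70).
#' @param vwc_ceiling soil VWC ceiling in % (default 17).
#' @param mds_strict if `TRUE` the MDS condition is `>` instead of `>=`
#'   (default non-strict; at printed precision the difference matters only at
#'   exactly the trigger value).
#' @param vwc_strict if `TRUE` the VWC condition is `<` instead of `<=`.
#' @return an object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(mds_trigger = 70, vwc_ceiling = 17,
                                mds_strict = FALSE, vwc_strict = FALSE) {
  stopifnot(mds_trigger > 0, vwc_ceiling > 0, vwc_ceiling < 100)
  structure(list(mds_trigger = mds_trigger, vwc_ceiling = vwc_ceiling,
                 mds_strict = mds_strict, vwc_strict = vwc_strict),
            class = "decision_thresholds")
}

#' Evaluate the dual-threshold rule
#'
#' Vectorised four-quadrant verdict: `trigger` (both conditions hold),
#' `atmospheric_false_positive` (shrinkage signal but wet soil),
#' `masked_deficit` (dry soil but no shrinkage signal), `no_stress`
#' (neither).
#'
#' @param mds maximum daily shrinkage value(s), micrometres (non-negative).
#' @param vwc soil volumetric water content value(s), %.
#' @param thresholds a [decision_thresholds()] object.
#' @param source label recorded for the MDS provenance (`"observed"` or
#'   `"forecast"`).
#' @return data.frame of class `irrigation_decisions` with columns
#'   `mds, vwc, source, mds_condition, vwc_condition, verdict, rationale`.
#' @export
evaluate_dual_threshold <- function(mds, vwc, thresholds = decision_thresholds(),
                                    source = "observed") {
  .assert_finite(mds, "mds"); .assert_finite(vwc, "vwc")
  if (any(mds < 0)) stop("mds must be non-negative", call. = FALSE)
  if (length(vwc) == 1L) vwc <- rep(vwc, length(mds))
  stopifnot(length(mds) == length(vwc))
  m_ok <- if (thresholds$mds_strict) mds > thresholds$mds_trigger
          else mds >= thresholds$mds_trigger
  v_ok <- if (thresholds$vwc_strict) vwc < thresholds$vwc_ceiling
          else vwc <= thresholds$vwc_ceiling
  verdict <- ifelse(m_ok & v_ok, "trigger",
             ifelse(m_ok, "atmospheric_false_positive",
             ifelse(v_ok, "masked_deficit", "no_stress")))
  mop <- if (thresholds$mds_strict) ">" else ">="
  vop <- if (thresholds$vwc_strict) "<" else "<="
  rationale <- sprintf("MDS %.2f um %s %.0f um: %s; VWC %.1f%% %s %.0f%%: %s",
                       mds, mop, thresholds$mds_trigger,
                       ifelse(m_ok, "met", "not met"),
                       vwc, vop, thresholds$vwc_ceiling,
                       ifelse(v_ok, "met", "not met"))
  structure(data.frame(mds = mds, vwc = vwc, source = source,
                       mds_condition = m_ok, vwc_condition = v_ok,
                       verdict = verdict, rationale = rationale),
            class = c("irrigation_decisions", "data.frame"))
}

#' Decide from a 24-h stem forecast
#'
#' Segments the reconstructed forecast into diurnal cycles, computes each
#' cycle's forecast MDS from the reconstructed extremes, pairs it with the
#' soil VWC stream (a scalar is persisted across the horizon; soil drying is
#' never extrapolated), and evaluates the dual-threshold rule per cycle.
#'
#' @param forecast a `stem_forecast` from [forecast_stem()].
#' @param vwc soil VWC: a scalar (last observation, persisted) or a vector
#'   aligned with the forecast steps.
#' @param thresholds a [decision_thresholds()] object.
#' @param anchor cycle anchor clock time.
#' @return list with `decisions` (an `irrigation_decisions` data.frame with
#'   `cycle_date` and `eval_time` columns) and `earliest_trigger` (POSIXct or
#'   `NA`).
#' @export
decide_from_forecast <- function(forecast, vwc, thresholds = decision_thresholds(),
                                 anchor = "00:00") {
  stopifnot(inherits(forecast, "stem_forecast"))
  h <- nrow(forecast)
  if (length(vwc) == 1L) vwc <- rep(vwc, h)
  if (length(vwc) != h)
    stop("vwc stream does not align with the forecast horizon", call. = FALSE)
  a <- .clock_seconds(anchor)
  sod <- .seconds_of_day(forecast$time)
  cyc <- as.numeric(forecast$time) - ((sod - a) %% 86400)
  u <- sort(unique(cyc))
  rows <- lapply(u, function(s) {
    i <- which(cyc == s)
    data.frame(cycle_date = as.Date(as.POSIXct(s, origin = "1970-01-01", tz = "UTC")),
               eval_time = forecast$time[i[length(i)]],
               mds = max(forecast$y_hat[i]) - min(forecast$y_hat[i]),
               vwc = vwc[i[length(i)]],
               n_steps = length(i))
  })
  cy <- do.call(rbind, rows)
  dec <- evaluate_dual_threshold(cy$mds, cy$vwc, thresholds, source = "forecast")
  dec <- cbind(cy[c("cycle_date", "eval_time", "n_steps")],
               dec[setdiff(names(dec), c("mds", "vwc"))],
               cy[c("mds", "vwc")])
  dec <- structure(dec, class = c("irrigation_decisions", "data.frame"))
  trig <- which(dec$verdict == "trigger")
  list(decisions = dec,
       earliest_trigger = if (length(trig)) dec$eval_time[trig[1L]]
                          else as.POSIXct(NA, tz = "UTC"))
}

#' Write / read a decision log
#'
#' Lossless delimited export of an `irrigation_decisions` table including the
#' rationale column.
#'
#' @param decisions an `irrigation_decisions` data.frame.
#' @param path output file path.
#' @param sep field separator (default tab; rationales contain commas).
#' @return `path`, invisibly.
#' @export
decision_log <- function(decisions, path, sep = "\t") {
  df <- as.data.frame(decisions)
  for (col in intersect(c("cycle_date"), names(df))) df[[col]] <- format(df[[col]])
  for (col in intersect(c("eval_time"), names(df)))
    df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname decision_log
#' @export
read_decision_log <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if ("cycle_date" %in% names(df)) df$cycle_date <- as.Date(df$cycle_date)
  if ("eval_time" %in% names(df))
    df$eval_time <- as.POSIXct(df$eval_time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  structure(df, class = c("irrigation_decisions", "data.frame"))
}
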