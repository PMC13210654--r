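# Physiological threshold calibration from progressive-drought indicator
# records: the growth-arrest criterion (RT = 24 h and DI <= 0) and a
# statistical-process-control baseline (mean + 1 sigma upper control limit).

#' Detect the growth-arrest day in an indicator record sequence
#'
#' The physiological tipping point is the first complete cycle in which the
#' stem failed to re-attain the daily maximum within 24 h (`rt_h = 24`) and
#' the daily increment was non-positive (`di_um <= 0`): nocturnal rehydration
#' no longer restores the previous day's maximum.
#'
#' @param records an `indicator_records` data.frame for one replicate.
#' @return list of class `arrest_result`: `arrest` (logical), `date`,
#'   `mds_um`, `row` (index into `records`); `arrest = FALSE` when no cycle
#'   meets the criterion.
#' @export
detect_growth_arrest <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L)
    stop("need at least 2 consecutive complete cycles", call. = FALSE)
  usable <- !is.na(records$rt_h) & !is.na(records$di_um)
  if (any(!usable & is.na(records$mds_um)))
    warning("cycles with unavailable indicators skipped")
  hit <- which(usable & records$rt_h >= 24 & records$di_um <= 0)
  if (length(hit) == 0L)
    return(structure(list(arrest = FALSE, date = as.Date(NA), mds_um = NA_real_,
                          row = NA_integer_), class = "arrest_result"))
  i <- hit[1L]
  structure(list(arrest = TRUE, date = records$date[i], mds_um = records$mds_um[i],
                 row = i), class = "arrest_result")
}

#' Mean arrest-day MDS across replicates
#'
#' Extracts each replicate's arrest-day MDS and averages them; replicates
#' without a detected arrest are dropped from the mean but reported.
#'
#' @param records_list list of per-replicate `indicator_records`.
#' @return list with `per_replicate` (data.frame: replicate, arrest_date,
#'   arrest_mds_um) and `mean_arrest_mds_um`.
#' @export
calibrate_arrest_threshold <- function(records_list) {
  if (length(records_list) == 0L) stop("no replicate records supplied", call. = FALSE)
  if (is.data.frame(records_list)) records_list <- list(rep1 = records_list)
  nms <- names(records_list)
  if (is.null(nms)) nms <- paste0("rep", seq_along(records_list))
  det <- lapply(records_list, detect_growth_arrest)
  per <- data.frame(
    replicate = nms,
    arrest_date = as.Date(vapply(det, function(d) as.character(d$date), character(1L))),
    arrest_mds_um = vapply(det, function(d) d$mds_um, numeric(1L)))
  vals <- per$arrest_mds_um[!is.na(per$arrest_mds_um)]
  if (length(vals) == 0L)
    stop("no replicate reached growth arrest; cannot calibrate", call. = FALSE)
  list(per_replicate = per, mean_arrest_mds_um = mean(vals))
}

#' Statistical-process-control baseline of normal-phase MDS
#'
#' Mean, sample standard deviation, the 1-sigma upper control limit
#' `UCL = mean + sd`, and the empirical fraction of baseline observations at
#' or below the UCL (about 0.841 for Gaussian data).
#'
#' @param mds numeric vector of normal-growth-phase MDS values (n >= 2).
#' @return list of class `spc_baseline`: `n`, `mean_mds`, `sd_mds`, `ucl`,
#'   `capture_fraction`.
#' @export
spc_baseline <- function(mds) {
  mds <- mds[!is.na(mds)]
  if (length(mds) < 2L) stop("need at least 2 baseline observations", call. = FALSE)
  m <- mean(mds); s <- stats::sd(mds)
  ucl <- m + s
  structure(list(n = length(mds), mean_mds = m, sd_mds = s, ucl = ucl,
                 capture_fraction = mean(mds <= ucl)),
            class = "spc_baseline")
}

#' @export
print.spc_baseline <- function(x, ...) {
  cat(sprintf("<spc_baseline> n=%d  MDS %.1f +/- %.1f um  UCL(1 sigma) %.1f um  capture %.3f\n",
              x$n, x$mean_mds, x$sd_mds, x$ucl, x$capture_fraction))
  invisible(x)
}

#' Soil water content as a fraction of field capacity
#'
#' `PPV = SWC / FC`, reported to 2 decimals. The measured field capacity of
#' the reference sandy loam is 26.0% volumetric.
#'
#' @param swc soil volumetric water content, %.
#' @param field_capacity field capacity, % (> 0).
#' @return fraction(s) rounded to 2 decimals.
#' @export
compute_ppv <- function(swc, field_capacity = 26.0) {
  if (any(field_capacity <= 0)) stop("field capacity must be positive", call. = FALSE)
  round(swc / field_capacity, 2L)
}

#' Full threshold calibration report
#'
#' Combines the arrest-mean and SPC estimates and derives the recommended
#' irrigation trigger: the 1-sigma UCL rounded down to the nearest 5 um
#' (conservative, so intervention precedes the statistical boundary), unless
#' overridden manually.
#'
#' @param records_list per-replicate progressive-drought `indicator_records`.
#' @param baseline_mds normal-growth-phase MDS values for the SPC baseline.
#' @param arrest_day_vwc optional per-replicate soil VWC (%) on the arrest
#'   day, averaged into the recommended soil ceiling.
#' @param mds_threshold optional manual override of the MDS trigger (um).
#' @param field_capacity field capacity, % volumetric.
#' @return list of class `calibration_result`.
#' @export
calibrate_thresholds <- function(records_list, baseline_mds,
                                 arrest_day_vwc = NULL, mds_threshold = NULL,
                                 field_capacity = 26.0) {
  arrest <- calibrate_arrest_threshold(records_list)
  spc <- spc_baseline(baseline_mds)
  if (is.null(mds_threshold)) {
    rec_mds <- 5 * floor(spc$ucl / 5)
    provenance <- "spc"
  } else {
    rec_mds <- mds_threshold
    provenance <- "manual"
  }
  rec_vwc <- if (is.null(arrest_day_vwc)) NA_real_
             else round(mean(arrest_day_vwc, na.rm = TRUE), 1L)
  structure(list(arrest = arrest, spc = spc,
                 recommended_mds_threshold = rec_mds,
                 recommended_vwc_threshold = rec_vwc,
                 threshold_provenance = provenance,
                 field_capacity = field_capacity,
                 arrest_ppv = if (is.null(arrest_day_vwc)) NA_real_
                              else compute_ppv(mean(arrest_day_vwc, na.rm = TRUE),
                                               field_capacity)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  mean arrest-day MDS : %.2f um (over %d replicate(s))\n",
              x$arrest$mean_arrest_mds_um,
              sum(!is.na(x$arrest$per_replicate$arrest_mds_um))))
  cat(sprintf("  SPC baseline        : %.1f +/- %.1f um, UCL %.1f um\n",
              x$spc$mean_mds, x$spc$sd_mds, x$spc$ucl))
  cat(sprintf("  recommended trigger : MDS >= %.0f um (%s)\n",
              x$recommended_mds_threshold, x$threshold_provenance))
  if (!is.na(x$recommended_vwc_threshold))
    cat(sprintf("  recommended ceiling : VWC <= %.1f %% (PPV %.2f)\n",
                x$recommended_vwc_threshold, x$arrest_ppv))
  invisible(x)
}

#' Write a calibration report as JSON
#' @param result a `calibration_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  ser <- list(
    per_replicate = lapply(seq_len(nrow(result$arrest$per_replicate)), function(i) {
      r <- result$arrest$per_replicate[i, ]
      list(replicate = r$replicate, arrest_date = as.character(r$arrest_date),
           arrest_mds_um = r$arrest_mds_um)
    }),
    mean_arrest_mds_um = result$arrest$mean_arrest_mds_um,
    spc = unclass(result$spc),
    recommended_mds_threshold_um = result$recommended_mds_threshold,
    recommended_vwc_threshold_pct = result$recommended_vwc_threshold,
    threshold_provenance = result$threshold_provenance)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}
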