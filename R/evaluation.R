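# Forecast-quality metrics and correlation diagnostics.

#' Root mean square error
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` with SST about the mean of `y`; undefined (error) for
#' constant `y`.
#' @inheritParams rmse
#' @return scalar, at most 1.
#' @export
r2 <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("R-squared undefined for constant observations", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Mean absolute percentage error with a +0.01 stabiliser
#'
#' `mean(|y - yhat| / (y + 0.01)) * 100`. Note this is not the textbook
#' MAPE: the denominator is `y + 0.01` (not `|y|`), the 0.01 stabilising the
#' division near zero, and the absolute value applies to the numerator only.
#' Consequently the metric is asymmetric in `(y, yhat)` and assumes `y`
#' non-negative in its intended use.
#'
#' @inheritParams rmse
#' @return percentage (>= 0 for non-negative `y`).
#' @export
mape <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (any(abs(y + 0.01) < 1e-12))
    stop("singular denominator: y = -0.01 present", call. = FALSE)
  mean(abs(y - yhat) / (y + 0.01)) * 100
}

#' Bundle the three metrics into one report row
#' @inheritParams rmse
#' @param label split label (e.g. `"validation"`, `"test"`).
#' @return one-row data.frame `rmse, r2, mape, n, split` of class
#'   `metric_report`.
#' @export
metric_report <- function(y, yhat, label = "test") {
  structure(data.frame(rmse = rmse(y, yhat), r2 = r2(y, yhat),
                       mape = mape(y, yhat), n = length(y), split = label),
            class = c("metric_report", "data.frame"))
}

#' Write metric reports as JSON keyed by model name
#' @param reports named list of `metric_report` rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(reports, path) {
  jsonlite::write_json(lapply(reports, function(r) as.list(as.data.frame(r))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Symmetric matrix of Pearson r over complete rows, with two-sided p-values
#' from the exact t transform `t = r sqrt((n-2)/(1-r^2))`. Constant columns
#' yield `NA` entries and a warning.
#'
#' @param df numeric data.frame or matrix (>= 3 complete rows).
#' @return list of class `cor_matrix` with matrices `r`, `p` and the row
#'   count `n`.
#' @export
correlation_matrix <- function(df) {
  m <- as.matrix(df)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 complete rows", call. = FALSE)
  k <- ncol(m)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations undefined")
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- NA_real_
  diag(r) <- ifelse(sds > 0, 1, NA_real_)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat("<cor_matrix> Pearson r over", x$n, "complete rows\n")
  print(round(x$r, 3))
  invisible(x)
}
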