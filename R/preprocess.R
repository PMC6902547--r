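#' Remove outlying strides by the median/MAD rule
#'
#' Optional cleaning step: drops strides whose absolute deviation from the
#' series median exceeds `k` SD-consistent MADs (MAD scaled by 1.4826). The
#' hallway walking protocols behind stride-interval datasets include
#' turnaround strides that can be much longer than steady-state strides; this
#' filter can exclude them. Disabled by default so the literal
#' detrend-then-fit procedure is the default path.
#'
#' A constant series has MAD 0; in that degenerate case nothing is removed.
#'
#' @param series a [stride_series].
#' @param k positive multiplier on the SD-consistent MAD (default 3).
#' @param enabled if `FALSE` (default) the series is returned unchanged with
#'   `outliers_removed = 0`.
#' @return A [stride_series] with attribute `outliers_removed` (integer count).
#' @export
remove_outliers <- function(series, k = 3, enabled = FALSE) {
  stopifnot(inherits(series, "stride_series"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop_gait("k must be a positive scalar", "gait_param_error")
  }
  if (!enabled) {
    attr(series, "outliers_removed") <- 0L
    return(series)
  }
  x <- series$stride_times
  m <- stats::median(x)
  s <- stats::mad(x, constant = 1.4826)
  keep <- if (s == 0) rep(TRUE, length(x)) else abs(x - m) <= k * s
  if (!any(keep)) {
    stop_gait("outlier removal would discard every stride", "gait_degenerate_error")
  }
  out <- series
  out$stride_times <- x[keep]
  if (!is.null(series$elapsed_times)) out$elapsed_times <- series$elapsed_times[keep]
  attr(out, "outliers_removed") <- sum(!keep)
  out
}

#' Subtract a linear trend from a stride-time series
#'
#' Fits an ordinary least-squares line to stride time against stride index
#' (t = 0, 1, ..., n-1) and returns the residual series the AR(2) model is
#' fitted to. Slow drift in stride time (fatigue, pacing) would otherwise be
#' absorbed into the autoregressive coefficients; removing it isolates the
#' stride-to-stride dynamics.
#'
#' @param series a [stride_series] of length >= 30.
#' @param regressor `"index"` (default; stride number) or `"elapsed"` (elapsed
#'   time in seconds, requires `elapsed_times`). Stride index is the standard
#'   convention for stride-interval series plotted as stride number vs stride
#'   time.
#' @return An object of class `detrended_series` with fields `residuals`,
#'   `trend_intercept`, `trend_slope`, `n`, `outliers_removed`, plus carried
#'   metadata (`subject_id`, `group_label`, `foot`, `stride_mean_s`).
#' @examples
#' s <- stride_series(1.0 + 0.01 * (0:49), subject_id = "line")
#' d <- detrend_linear(s)
#' c(d$trend_intercept, d$trend_slope)  # 1.0, 0.01
#' @export
detrend_linear <- function(series, regressor = c("index", "elapsed")) {
  stopifnot(inherits(series, "stride_series"))
  regressor <- match.arg(regressor)
  y <- series$stride_times
  n <- length(y)
  if (n < 30L) {
    stop_gait(sprintf("series has %d strides; >= 30 required for detrending", n),
              "gait_length_error")
  }
  t <- if (regressor == "index") {
    as.numeric(seq_len(n) - 1L)
  } else {
    if (is.null(series$elapsed_times)) {
      stop_gait("regressor = 'elapsed' requires elapsed_times", "gait_schema_error")
    }
    series$elapsed_times
  }
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc * tc)
  intercept <- mean(y) - slope * mean(t)
  res <- y - intercept - slope * t
  structure(
    list(
      residuals = res,
      trend_intercept = intercept,
      trend_slope = slope,
      n = n,
      outliers_removed = attr(series, "outliers_removed") %||% 0L,
      subject_id = series$subject_id,
      group_label = series$group_label,
      foot = series$foot,
      stride_mean_s = mean(series$stride_times)
    ),
    class = "detrended_series"
  )
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf(
    "<detrended_series> subject=%s n=%d slope=%.2e s/stride intercept=%.3f s\n",
    x$subject_id, x$n, x$trend_slope, x$trend_intercept
  ))
  invisible(x)
}
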