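#' Construct a stride-time series object
#'
#' A `stride_series` holds one subject's ordered stride intervals (seconds)
#' together with a group label and provenance. It is the unit of input for the
#' whole analysis: cleaning, detrending, and AR(2) fitting all operate per
#' series.
#'
#' @param stride_times numeric vector of stride intervals in seconds; must be
#'   finite and strictly positive.
#' @param subject_id character scalar identifying the subject.
#' @param group_label character scalar, e.g. `"control"`, `"huntington"`,
#'   `"als"`, `"park"`.
#' @param foot which limb's stride sequence this is: `"left"`, `"right"`, or
#'   `"mean"` (per-stride average of both feet).
#' @param elapsed_times optional numeric vector of elapsed times (seconds) at
#'   each stride; must be strictly increasing when supplied.
#' @param source character scalar describing provenance (file path,
#'   `"simulated"`, ...).
#'
#' @return An object of class `stride_series`.
#' @examples
#' s <- stride_series(c(1.10, 1.12, 1.08), subject_id = "toy")
#' length(s$stride_times)
#' @export
stride_series <- function(stride_times,
                          subject_id = "unknown",
                          group_label = "unknown",
                          foot = c("left", "right", "mean"),
                          elapsed_times = NULL,
                          source = "unknown") {
  foot <- match.arg(foot)
  stride_times <- as.numeric(stride_times)
  if (length(stride_times) == 0L) {
    stop_gait("stride_times is empty", "gait_length_error")
  }
  if (any(!is.finite(stride_times)) || any(stride_times <= 0)) {
    stop_gait("stride_times must be finite and > 0 after cleaning",
              "gait_schema_error")
  }
  if (!is.null(elapsed_times)) {
    elapsed_times <- as.numeric(elapsed_times)
    if (length(elapsed_times) != length(stride_times)) {
      stop_gait("elapsed_times must match stride_times in length",
                "gait_schema_error")
    }
    if (any(diff(elapsed_times) <= 0)) {
      stop_gait("elapsed_times must be strictly increasing",
                "gait_schema_error")
    }
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      group_label = as.character(group_label),
      foot = foot,
      stride_times = stride_times,
      elapsed_times = elapsed_times,
      source = as.character(source)
    ),
    class = "stride_series"
  )
}

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf(
    "<stride_series> subject=%s group=%s foot=%s n=%d mean=%.3f s (source: %s)\n",
    x$subject_id, x$group_label, x$foot, length(x$stride_times),
    mean(x$stride_times), x$source
  ))
  invisible(x)
}

# group label inferred from gaitndd-style filename prefixes (control1.ts, hunt3.ts, ...)
infer_group_label <- function(path) {
  base <- tolower(basename(path))
  if (startsWith(base, "control")) return("control")
  if (startsWith(base, "hunt")) return("huntington")
  if (startsWith(base, "als")) return("als")
  if (startsWith(base, "park")) return("park")
  "unknown"
}

#' Read a stride-interval file in the gaitndd columnar format
#'
#' Parses a whitespace-delimited numeric text file of per-stride timing
#' measures, as distributed by the PhysioNet `gaitndd` database: column 1 is
#' elapsed time (s) and subsequent columns are per-stride interval measures
#' for the left and right feet. Only the elapsed-time column and the selected
#' stride-interval column(s) are used.
#'
#' Rows whose stride value is non-numeric or non-positive are dropped and the
#' number of drops is reported via `message()`.
#'
#' @param path path to a whitespace-delimited text file with at least two
#'   numeric columns.
#' @param foot `"left"`, `"right"`, or `"mean"` (per-row mean of the left and
#'   right stride columns). Which limb the original analysis used is not
#'   documented; the default is `"left"`.
#' @param column_map named integer vector mapping roles to column indices.
#'   Must name `elapsed` and at least one of `left`/`right`. The default
#'   matches the accession layout: elapsed time, left stride, right stride.
#' @param group_label overrides the group inferred from the filename prefix
#'   (`control*` / `hunt*` / `als*` / `park*`).
#' @param min_strides minimum number of valid rows; fewer is an error.
#'
#' @return A [stride_series].
#' @export
read_gaitndd_file <- function(path,
                              foot = c("left", "right", "mean"),
                              column_map = c(elapsed = 1L, left = 2L, right = 3L),
                              group_label = NULL,
                              min_strides = 30L) {
  foot <- match.arg(foot)
  if (!file.exists(path)) {
    stop_gait(sprintf("cannot read '%s': no such file", path), "gait_io_error")
  }
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      fill = TRUE, comment.char = ""),
    error = function(e) {
      stop_gait(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                "gait_io_error")
    }
  )
  if (ncol(raw) < 2L) {
    stop_gait(sprintf("'%s' has %d column(s); need at least 2", path, ncol(raw)),
              "gait_schema_error")
  }
  if (!("elapsed" %in% names(column_map))) {
    stop_gait("column_map must name an 'elapsed' column", "gait_schema_error")
  }
  need <- switch(foot,
    left = "left",
    right = "right",
    mean = c("left", "right")
  )
  missing_roles <- setdiff(c("elapsed", need), names(column_map))
  if (length(missing_roles) > 0L) {
    stop_gait(sprintf("column_map lacks role(s): %s",
                      paste(missing_roles, collapse = ", ")),
              "gait_schema_error")
  }
  idx <- column_map[c("elapsed", need)]
  if (any(idx > ncol(raw)) || any(idx < 1L)) {
    stop_gait(sprintf("column_map references column(s) beyond the %d present",
                      ncol(raw)),
              "gait_schema_error")
  }

  num <- function(j) suppressWarnings(as.numeric(raw[[j]]))
  elapsed <- num(column_map[["elapsed"]])
  stride <- if (foot == "mean") {
    (num(column_map[["left"]]) + num(column_map[["right"]])) / 2
  } else {
    num(column_map[[foot]])
  }

  keep <- is.finite(stride) & stride > 0
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_gaitndd_file: dropped %d invalid row(s) from %s",
                    dropped, basename(path)))
  }
  if (sum(keep) < min_strides) {
    stop_gait(sprintf("'%s': only %d valid stride(s); need >= %d",
                      path, sum(keep), min_strides),
              "gait_length_error")
  }
  elapsed_kept <- elapsed[keep]
  if (any(!is.finite(elapsed_kept)) || any(diff(elapsed_kept) <= 0)) {
    elapsed_kept <- NULL  # elapsed column unusable; stride order still file order
  }
  series <- stride_series(
    stride_times = stride[keep],
    subject_id = sub("\\.[^.]*$", "", basename(path)),
    group_label = group_label %||% infer_group_label(path),
    foot = foot,
    elapsed_times = elapsed_kept,
    source = path
  )
  attr(series, "rows_dropped") <- dropped
  series
}

internal_csv_header <- c("subject_id", "group_label", "foot",
                         "stride_index", "stride_time_s")

#' Read / write the internal stride-series CSV dialect
#'
#' RFC-4180 CSV with header columns `subject_id`, `group_label`, `foot`,
#' `stride_index`, `stride_time_s`, one row per stride, in series order.
#' `write_internal_csv()` followed by `read_internal_csv()` is the identity on
#' the fields the format stores (elapsed times and free-text source are not
#' stored).
#'
#' @param path CSV file path.
#' @return `read_internal_csv()` returns a [stride_series];
#'   `write_internal_csv()` returns `path` invisibly.
#' @export
read_internal_csv <- function(path) {
  if (!file.exists(path)) {
    stop_gait(sprintf("cannot read '%s': no such file", path), "gait_io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop_gait(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                "gait_io_error")
    }
  )
  if (!all(internal_csv_header %in% names(df))) {
    stop_gait(sprintf("'%s' lacks required header columns: %s", path,
                      paste(setdiff(internal_csv_header, names(df)),
                            collapse = ", ")),
              "gait_schema_error")
  }
  if (nrow(df) == 0L) {
    stop_gait(sprintf("'%s' has a header but no data rows", path),
              "gait_length_error")
  }
  idx <- as.integer(df$stride_index)
  if (any(diff(idx) != 1L)) {
    warning(sprintf("'%s': stride_index not contiguous; row order preserved",
                    basename(path)))
  }
  stride_series(
    stride_times = as.numeric(df$stride_time_s),
    subject_id = df$subject_id[1L],
    group_label = df$group_label[1L],
    foot = df$foot[1L],
    source = path
  )
}

#' @param series a [stride_series] to serialize.
#' @rdname read_internal_csv
#' @export
write_internal_csv <- function(series, path) {
  stopifnot(inherits(series, "stride_series"))
  df <- data.frame(
    subject_id = series$subject_id,
    group_label = series$group_label,
    foot = series$foot,
    stride_index = seq_along(series$stride_times),
    stride_time_s = series$stride_times
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
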