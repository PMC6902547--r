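#' Two-sample t-test on a per-subject metric
#'
#' Standard two-sided two-sample t-test, implemented from the closed-form
#' expressions. The Welch variant (default) uses the Satterthwaite degrees of
#' freedom and does not pool variances — appropriate when group SDs differ,
#' as they do for most gait metrics here; the pooled variant is kept for
#' sensitivity analysis.
#'
#' @param values_a,values_b numeric vectors, each with >= 2 finite values.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param metric_name label carried into the result.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return An object of class `group_comparison`: `metric_name`, `mean_a`,
#'   `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `t_stat`, `df`, `p_value`,
#'   `alpha`, `variant`.
#' @examples
#' two_sample_ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), variant = "pooled")
#' @export
two_sample_ttest <- function(values_a, values_b,
                             variant = c("welch", "pooled"),
                             metric_name = "metric",
                             alpha = 0.05) {
  variant <- match.arg(variant)
  a <- as.numeric(values_a[is.finite(values_a)])
  b <- as.numeric(values_b[is.finite(values_b)])
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop_gait("each group needs >= 2 finite values", "gait_param_error")
  }
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      stop_gait("zero variance in both groups with equal means: t undefined",
                "gait_degenerate_error")
    }
    t_stat <- sign(ma - mb) * Inf
    df <- na + nb - 2
    p <- 0
  } else if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t_stat <- (ma - mb) / se
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    se2a <- va / na
    se2b <- vb / nb
    se <- sqrt(se2a + se2b)
    t_stat <- (ma - mb) / se
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(
    list(metric_name = metric_name,
         mean_a = ma, sd_a = sqrt(va), n_a = na,
         mean_b = mb, sd_b = sqrt(vb), n_b = nb,
         t_stat = t_stat, df = df, p_value = p,
         alpha = alpha, variant = variant),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  star <- if (x$p_value < x$alpha) " *" else ""
  cat(sprintf(
    "<group_comparison %s> %.3f +/- %.3f (n=%d) vs %.3f +/- %.3f (n=%d): t=%.3f df=%.1f p=%.4g%s\n",
    x$metric_name, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$t_stat, x$df, x$p_value, star
  ))
  invisible(x)
}

#' Coverage ellipse for a group's coefficient pairs
#'
#' Fits an ellipse around a group's \eqn{(\phi_1, \phi_2)} points on the
#' stationarity triangle. `gaussian` mode scales the sample-covariance
#' ellipse by the \eqn{\chi^2_2} quantile at the coverage target (a
#' parametric prediction ellipse); `empirical` mode (default) rescales that
#' ellipse to the smallest Mahalanobis radius that actually encloses at least
#' the target fraction of the input points — matching the descriptive
#' "encircles 95% of the individuals" construction.
#'
#' @param points two-column matrix or data frame of \eqn{(\phi_1, \phi_2)}
#'   pairs; >= 3 non-collinear points.
#' @param coverage_target fraction of points the ellipse should enclose
#'   (default 0.95).
#' @param mode `"empirical"` (default) or `"gaussian"`.
#' @return An object of class `coverage_ellipse`: `center`, `semi_axes`
#'   (major, minor), `angle` (radians, major axis vs phi1 axis),
#'   `coverage_target`, `empirical_coverage`, `mode`, and the `covariance`
#'   used.
#' @export
coverage_ellipse <- function(points,
                             coverage_target = 0.95,
                             mode = c("empirical", "gaussian")) {
  mode <- match.arg(mode)
  pts <- as.matrix(points)
  if (ncol(pts) != 2L || nrow(pts) < 3L || any(!is.finite(pts))) {
    stop_gait(">= 3 finite (phi1, phi2) points required", "gait_param_error")
  }
  if (coverage_target <= 0 || coverage_target >= 1) {
    stop_gait("coverage_target must be in (0, 1)", "gait_param_error")
  }
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= .Machine$double.eps * max(abs(ev$values), 1)) {
    stop_gait("degenerate (collinear) point cloud: covariance is singular",
              "gait_degenerate_error")
  }
  d2 <- stats::mahalanobis(pts, ctr, S)
  r2 <- if (mode == "gaussian") {
    stats::qchisq(coverage_target, df = 2)
  } else {
    k <- ceiling(coverage_target * nrow(pts))
    sort(d2)[k]
  }
  emp <- mean(d2 <= r2 * (1 + 1e-12))
  structure(
    list(center = ctr,
         semi_axes = sqrt(ev$values * r2),
         angle = atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L]),
         coverage_target = coverage_target,
         empirical_coverage = emp,
         mode = mode,
         covariance = S,
         mahalanobis_r2 = r2),
    class = "coverage_ellipse"
  )
}

#' Points on a coverage ellipse's outline (for plotting)
#'
#' @param ellipse a [coverage_ellipse].
#' @param n number of outline points.
#' @return An n x 2 matrix of (phi1, phi2) coordinates.
#' @export
ellipse_outline <- function(ellipse, n = 361L) {
  stopifnot(inherits(ellipse, "coverage_ellipse"))
  th <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ellipse$semi_axes[1L] * cos(th), ellipse$semi_axes[2L] * sin(th))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2L, 2L)
  t(rot %*% u + ellipse$center)
}

#' Distance-threshold classification of disease status
#'
#' A declared reconstruction: the source study reports that metric
#' performance was judged by accuracy, sensitivity and specificity but does
#' not state the classification procedure. Here a subject is predicted to be
#' in the positive (disease) class when their centroid distance falls below a
#' threshold — the disease group sits nearer the oscillatory centroid — with
#' the automatic threshold at the midpoint of the two group mean distances.
#'
#' @param distances per-subject centroid distances.
#' @param labels per-subject group labels; exactly two classes required.
#' @param positive_label the label treated as the positive (smaller-distance)
#'   class; default: the class with the smaller mean distance.
#' @param threshold numeric cut-off, or `"auto"` (midpoint of group means).
#' @return An object of class `classification_report`: `threshold`,
#'   `positive_label`, `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (2x2 matrix), `note`.
#' @export
classify_by_distance <- function(distances, labels,
                                 positive_label = NULL,
                                 threshold = "auto") {
  distances <- as.numeric(distances)
  labels <- as.character(labels)
  stopifnot(length(distances) == length(labels))
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop_gait(sprintf("exactly two classes required; got %d", length(classes)),
              "gait_param_error")
  }
  means <- tapply(distances, labels, mean)
  if (is.null(positive_label)) {
    positive_label <- names(means)[which.min(means)]
  } else if (!positive_label %in% classes) {
    stop_gait(sprintf("positive_label '%s' not among the labels", positive_label),
              "gait_param_error")
  }
  if (identical(threshold, "auto")) {
    threshold <- mean(means)  # midpoint of the two group means
  }
  truth_pos <- labels == positive_label
  pred_pos <- distances < threshold
  tp <- sum(pred_pos & truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                      dimnames = list(predicted = c("positive", "negative"),
                                      truth = c("positive", "negative")))
  structure(
    list(threshold = threshold,
         positive_label = positive_label,
         accuracy = (tp + tn) / length(labels),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         confusion = confusion,
         note = paste("distance-threshold classifier; a reconstruction,",
                      "not a published procedure")),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> positive='%s' threshold=%.4f: accuracy=%.3f sensitivity=%.3f specificity=%.3f\n",
    x$positive_label, x$threshold, x$accuracy, x$sensitivity, x$specificity
  ))
  cat("note:", x$note, "\n")
  invisible(x)
}

#' Per-group summary of stride-time and stability metrics
#'
#' Aggregates a per-subject results table into per-group mean and SD of mean
#' stride time, AR1, AR2 and centroid distance, plus the fraction of each
#' group's subjects falling in each triangle region — the shape of the
#' published group-comparison table.
#'
#' @param subjects data frame with columns `group_label`, `stride_time_s`,
#'   `phi1`, `phi2`, `distance`, `region` (one row per subject; the fits
#'   table written by [run_pipeline] has this shape).
#' @return A list with `metrics` (group x metric mean/sd/n; `sd` is 0 with
#'   `sd_undefined = TRUE` for single-subject groups) and `regions` (group x
#'   region fractions).
#' @export
summarize_cohort <- function(subjects) {
  need <- c("group_label", "stride_time_s", "phi1", "phi2", "distance", "region")
  if (!is.data.frame(subjects) || !all(need %in% names(subjects))) {
    stop_gait(sprintf("subjects table must have columns: %s",
                      paste(need, collapse = ", ")),
              "gait_schema_error")
  }
  if (nrow(subjects) == 0L) {
    stop_gait("empty subjects table", "gait_data_error")
  }
  metric_cols <- c(stride_time_s = "stride_time_s", ar1 = "phi1",
                   ar2 = "phi2", ar_distance = "distance")
  groups <- sort(unique(subjects$group_label))
  rows <- do.call(rbind, lapply(groups, function(g) {
    sub <- subjects[subjects$group_label == g, , drop = FALSE]
    do.call(rbind, lapply(names(metric_cols), function(mn) {
      v <- sub[[metric_cols[[mn]]]]
      data.frame(group_label = g, metric = mn,
                 mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n = length(v),
                 sd_undefined = length(v) < 2L)
    }))
  }))
  region_levels <- c("non_oscillatory", "oscillatory", "boundary", "unstable")
  regions <- do.call(rbind, lapply(groups, function(g) {
    sub <- subjects[subjects$group_label == g, , drop = FALSE]
    frac <- vapply(region_levels,
                   function(r) mean(sub$region == r), numeric(1))
    data.frame(group_label = g, region = region_levels,
               fraction = as.numeric(frac), n = nrow(sub))
  }))
  rownames(rows) <- rownames(regions) <- NULL
  list(metrics = rows, regions = regions)
}
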