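#' Fit a second-order autoregressive model
#'
#' Fits the AR(2) model
#' \deqn{y_t = \delta + \phi_1 y_{t-1} + \phi_2 y_{t-2} + \varepsilon_t}
#' to a detrended stride-time series. The coefficient pair
#' \eqn{(\phi_1, \phi_2)} summarizes how strongly the current stride time
#' depends on the two previous strides and is the coordinate pair plotted on
#' the stationarity triangle.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`cls`}{conditional least squares: ordinary least squares of
#'     \eqn{y_t} on \eqn{(1, y_{t-1}, y_{t-2})} over \eqn{t = 3, \dots, n}.
#'     `sigma2` is the unbiased residual variance (residual sum of squares
#'     over \eqn{n_{\mathrm{eff}} - 3}).}
#'   \item{`yule_walker`}{solves the order-2 Yule-Walker equations built from
#'     the biased (divide-by-\eqn{n}) sample autocovariances; `sigma2` is the
#'     implied innovation variance
#'     \eqn{\hat\gamma_0 (1 - \hat\phi_1 r_1 - \hat\phi_2 r_2)}.}
#' }
#'
#' @param detrended a `detrended_series` (see [detrend_linear]) or a plain
#'   numeric vector of length >= 30.
#' @param method `"cls"` (default) or `"yule_walker"`.
#' @return An object of class `ar_fit` with fields `phi1`, `phi2`, `delta`,
#'   `sigma2`, `n_effective`, `method`.
#' @examples
#' set.seed(1)
#' d <- detrend_linear(simulate_subject(0.4, 0.1, seed = 1))
#' fit_ar2(d)
#' @export
fit_ar2 <- function(detrended, method = c("cls", "yule_walker")) {
  method <- match.arg(method)
  y <- if (inherits(detrended, "detrended_series")) detrended$residuals
       else as.numeric(detrended)
  n <- length(y)
  if (n < 30L) {
    stop_gait(sprintf("series has %d values; >= 30 required for AR(2) fitting", n),
              "gait_length_error")
  }
  if (method == "cls") {
    yt <- y[3:n]
    X <- cbind(1, y[2:(n - 1L)], y[1:(n - 2L)])
    qrX <- qr(X)
    if (qrX$rank < 2L) {
      stop_gait("singular regressor matrix (constant or degenerate residuals)",
                "gait_degenerate_error")
    }
    beta <- qr.coef(qrX, yt)
    # exactly collinear lag columns (e.g. a noiseless geometric recursion):
    # the pivoted solution drops one lag; report its coefficient as 0
    beta[is.na(beta)] <- 0
    resid <- yt - X %*% beta
    n_eff <- n - 2L
    fit <- list(phi1 = beta[[2L]], phi2 = beta[[3L]], delta = beta[[1L]],
                sigma2 = sum(resid^2) / (n_eff - 3L),
                n_effective = n_eff, method = "cls")
  } else {
    ybar <- mean(y)
    yc <- y - ybar
    c0 <- sum(yc^2) / n
    if (c0 <= 0) {
      stop_gait("zero-variance series; Yule-Walker equations are degenerate",
                "gait_degenerate_error")
    }
    r1 <- sum(yc[1:(n - 1L)] * yc[2:n]) / n / c0
    r2 <- sum(yc[1:(n - 2L)] * yc[3:n]) / n / c0
    G <- matrix(c(1, r1, r1, 1), 2L, 2L)
    phi <- tryCatch(solve(G, c(r1, r2)), error = function(e) {
      stop_gait("singular Yule-Walker system (|r1| = 1)", "gait_degenerate_error")
    })
    fit <- list(phi1 = phi[[1L]], phi2 = phi[[2L]],
                delta = ybar * (1 - phi[[1L]] - phi[[2L]]),
                sigma2 = c0 * (1 - phi[[1L]] * r1 - phi[[2L]] * r2),
                n_effective = n, method = "yule_walker")
  }
  structure(fit, class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf(
    "<ar_fit %s> phi1=%.4f phi2=%.4f delta=%.2e sigma2=%.3e n_eff=%d\n",
    x$method, x$phi1, x$phi2, x$delta, x$sigma2, x$n_effective
  ))
  invisible(x)
}

#' Sample autocorrelation and partial autocorrelation
#'
#' Computes the biased (divide-by-n) sample ACF and the PACF via the
#' Durbin-Levinson recursion, the standard diagnostics for choosing the AR
#' model order: an AR(2) process shows a PACF that cuts off after lag 2.
#'
#' @param detrended a `detrended_series` or numeric vector.
#' @param max_lag largest lag to compute; must be < n/2.
#' @return An object of class `correlogram` with fields `lags` (0..max_lag),
#'   `acf`, `pacf` (lag 0 entry is 1 by convention), and `ci_halfwidth`
#'   (\eqn{1.96/\sqrt{n}}, the white-noise band).
#' @export
correlogram <- function(detrended, max_lag = 20L) {
  y <- if (inherits(detrended, "detrended_series")) detrended$residuals
       else as.numeric(detrended)
  n <- length(y)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n / 2) {
    stop_gait(sprintf("max_lag must be in [1, n/2); got %d with n = %d",
                      max_lag, n),
              "gait_param_error")
  }
  yc <- y - mean(y)
  c0 <- sum(yc^2) / n
  if (c0 <= 0) {
    stop_gait("zero-variance series has no correlogram", "gait_degenerate_error")
  }
  rho <- vapply(seq_len(max_lag), function(k) {
    sum(yc[1:(n - k)] * yc[(k + 1):n]) / n / c0
  }, numeric(1))

  # Durbin-Levinson: pacf(k) is the last coefficient of the order-k AR fit
  pacf <- numeric(max_lag)
  phi_prev <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1L) {
      a <- rho[1L]
      phi_prev <- a
    } else {
      num <- rho[k] - sum(phi_prev * rho[(k - 1L):1L])
      den <- 1 - sum(phi_prev * rho[1:(k - 1L)])
      a <- num / den
      phi_prev <- c(phi_prev - a * phi_prev[(k - 1L):1L], a)
    }
    pacf[k] <- a
  }
  structure(
    list(lags = 0:max_lag, acf = c(1, rho), pacf = c(1, pacf),
         ci_halfwidth = 1.96 / sqrt(n), n = n),
    class = "correlogram"
  )
}

# stationarity margins: all three > 0 <=> (phi1, phi2) strictly inside the triangle
ar2_margins <- function(phi1, phi2) {
  cbind(
    sum_lt_1 = 1 - phi1 - phi2,   # phi1 + phi2 < 1
    diff_lt_1 = 1 + phi1 - phi2,  # phi2 - phi1 < 1
    abs_lt_1 = 1 - abs(phi2)      # |phi2| < 1
  )
}

#' Vectorized stationarity-triangle region labels
#'
#' Labels each coefficient pair by its location relative to the AR(2)
#' stationarity triangle (vertices (-2,-1), (2,-1), (0,1)): `"unstable"`
#' outside the triangle, and inside it `"oscillatory"` when the
#' characteristic roots are complex (discriminant \eqn{\phi_1^2 + 4\phi_2 <
#' 0}, damped harmonic dynamics) or `"non_oscillatory"` when both roots are
#' real (two embedded time constants). Pairs within `tol` of the triangle
#' edge or of the discriminant parabola are labelled `"boundary"`.
#'
#' @param phi1,phi2 numeric vectors (recycled to common length).
#' @param tol boundary half-width (default 1e-9).
#' @return Character vector of region labels.
#' @export
ar2_region <- function(phi1, phi2, tol = 1e-9) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop_gait("tol must be a positive scalar", "gait_param_error")
  }
  k <- max(length(phi1), length(phi2))
  phi1 <- rep_len(as.numeric(phi1), k)
  phi2 <- rep_len(as.numeric(phi2), k)
  m <- ar2_margins(phi1, phi2)
  mmin <- pmin(m[, 1L], m[, 2L], m[, 3L])
  disc <- phi1^2 + 4 * phi2
  out <- character(k)
  out[mmin < -tol] <- "unstable"
  edge <- abs(mmin) <= tol
  out[edge] <- "boundary"
  inside <- mmin > tol
  out[inside & disc < -tol] <- "oscillatory"
  out[inside & disc > tol] <- "non_oscillatory"
  out[inside & abs(disc) <= tol] <- "boundary"
  out
}

#' Classify an AR(2) coefficient pair on the stationarity triangle
#'
#' The stationarity triangle is the set of \eqn{(\phi_1, \phi_2)} for which
#' the AR(2) process is stationary, equivalently for which both roots of the
#' characteristic polynomial \eqn{z^2 - \phi_1 z - \phi_2} lie strictly
#' inside the unit circle, equivalently the three inequalities
#' \eqn{\phi_1 + \phi_2 < 1}, \eqn{\phi_2 - \phi_1 < 1}, \eqn{|\phi_2| < 1}.
#' Inside the triangle, complex roots (discriminant \eqn{\phi_1^2 + 4\phi_2 <
#' 0}) give damped oscillatory dynamics; real roots give non-oscillatory
#' damped dynamics. The sub-region with complex roots is bounded above by the
#' parabola \eqn{\phi_2 = -\phi_1^2/4} (often loosely drawn as a semicircle).
#'
#' @param phi1,phi2 a single coefficient pair.
#' @param tol boundary half-width; pairs within `tol` of a region boundary
#'   are labelled `"boundary"` rather than forced into a region.
#' @return An object of class `stability_assessment` with fields `phi1`,
#'   `phi2`, `region` (one of `"unstable"`, `"oscillatory"`,
#'   `"non_oscillatory"`, `"boundary"`), `distance` (see [ar_distance]) and
#'   `char_roots` (the two roots of \eqn{z^2 - \phi_1 z - \phi_2}).
#' @examples
#' classify_stability(0, -1/3)   # triangle centroid: oscillatory
#' classify_stability(0.4, 0.1)  # control-like: non-oscillatory
#' classify_stability(1.5, 0.5)  # outside: unstable
#' @export
classify_stability <- function(phi1, phi2, tol = 1e-9) {
  stopifnot(length(phi1) == 1L, length(phi2) == 1L,
            is.finite(phi1), is.finite(phi2))
  region <- ar2_region(phi1, phi2, tol = tol)
  disc <- complex(real = phi1^2 + 4 * phi2)
  roots <- c((phi1 + sqrt(disc)) / 2, (phi1 - sqrt(disc)) / 2)
  structure(
    list(phi1 = phi1, phi2 = phi2, region = region,
         distance = ar_distance(phi1, phi2), char_roots = roots),
    class = "stability_assessment"
  )
}

#' @export
print.stability_assessment <- function(x, ...) {
  cat(sprintf(
    "<stability_assessment> (phi1=%.4f, phi2=%.4f): %s, distance to centroid = %.4f\n",
    x$phi1, x$phi2, x$region, x$distance
  ))
  invisible(x)
}

#' Distance to the stationarity-triangle centroid
#'
#' The stability statistic: the Euclidean distance from \eqn{(\phi_1,
#' \phi_2)} to the centroid of the stationarity triangle at \eqn{(0, -1/3)},
#' which lies in the oscillatory region. Smaller distances indicate dynamics
#' closer to (and possibly inside) the oscillatory region; larger distances,
#' non-oscillatory damped dynamics. Unitless because the AR coefficients are
#' dimensionless.
#'
#' @param phi1,phi2 numeric vectors (recycled).
#' @return Numeric vector of distances, \eqn{\sqrt{\phi_1^2 + (\phi_2 + 1/3)^2}}.
#' @examples
#' ar_distance(0, -1/3)  # 0
#' ar_distance(0.4, 0.1) # ~0.59, typical of control gait
#' @export
ar_distance <- function(phi1, phi2) {
  sqrt(phi1^2 + (phi2 + 1 / 3)^2)
}

#' Stationarity-triangle geometry
#'
#' @return A list with `vertices` (3x2 matrix, rows (-2,-1), (2,-1), (0,1))
#'   and `centroid` (the vertex average, (0, -1/3)).
#' @export
triangle_geometry <- function() {
  v <- matrix(c(-2, -1,
                 2, -1,
                 0,  1),
              nrow = 3L, byrow = TRUE,
              dimnames = list(NULL, c("phi1", "phi2")))
  list(vertices = v, centroid = colMeans(v))
}
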