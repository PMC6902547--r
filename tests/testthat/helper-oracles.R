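# Independent oracles and tiny fixture builders, kept deliberately separate
# from the implementation paths they check.

# direct OLS fit of y_t on (1, y[t-1], y[t-2]) via lm() -- oracle for fit_ar2(cls)
oracle_ar2_ols <- function(y) {
  n <- length(y)
  df <- data.frame(yt = y[3:n], l1 = y[2:(n - 1)], l2 = y[1:(n - 2)])
  coef(lm(yt ~ l1 + l2, data = df))
}

# characteristic-root stationarity: both roots of z^2 - phi1 z - phi2 inside
# the unit circle (vectorized, quadratic formula in complex arithmetic)
oracle_root_moduli <- function(phi1, phi2) {
  sq <- sqrt(as.complex(phi1^2 + 4 * phi2))
  pmax(Mod((phi1 + sq) / 2), Mod((phi1 - sq) / 2))
}

# closed-form stationary variance of a zero-mean AR(2) process
ar2_variance <- function(phi1, phi2, sigma) {
  sigma^2 * (1 - phi2) / ((1 + phi2) * ((1 - phi2)^2 - phi1^2))
}

# whitespace-delimited toy accession file: elapsed, left stride, right stride
# (left may contain non-numeric tokens like "NaN" to exercise row dropping)
write_toy_gaitndd <- function(path, left,
                              right = NULL, elapsed = NULL) {
  ln <- suppressWarnings(as.numeric(left))
  ln[!is.finite(ln)] <- 1
  if (is.null(right)) right <- ln + 0.01
  if (is.null(elapsed)) elapsed <- cumsum(ln)
  writeLines(sprintf("%.4f %s %s", elapsed, as.character(left),
                     as.character(right)), path)
  path
}

# simulate one detrended-and-fitted subject; returns the cls coefficient pair
sim_and_fit <- function(phi1, phi2, n, sigma, seed, method = "cls") {
  s <- simulate_subject(phi1, phi2, stride_mean = 1.1, innovation_sd = sigma,
                        n_strides = n, seed = seed)
  fit <- fit_ar2(detrend_linear(s), method = method)
  c(phi1 = fit$phi1, phi2 = fit$phi2)
}

# per-subject phi1/phi2/distance table for a list of cohort specs
fit_cohort_table <- function(specs) {
  do.call(rbind, lapply(specs, function(sp) {
    rows <- lapply(simulate_cohort(sp), function(s) {
      fit <- fit_ar2(detrend_linear(s))
      data.frame(group_label = s$group_label, phi1 = fit$phi1, phi2 = fit$phi2,
                 distance = ar_distance(fit$phi1, fit$phi2))
    })
    do.call(rbind, rows)
  }))
}
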