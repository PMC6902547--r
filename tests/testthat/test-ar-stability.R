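test_that("a noiseless first-order recursion is recovered to machine precision", {
  y <- 0.5^(0:99)  # y_t = 0.5 y_{t-1}, y_0 = 1
  fit <- fit_ar2(y)
  expect_equal(fit$phi1, 0.5, tolerance = 1e-12)
  expect_equal(fit$phi2, 0.0, tolerance = 1e-12)
  expect_identical(fit$n_effective, 98L)
})

test_that("white noise fits near-zero coefficients", {
  set.seed(12)
  fit <- fit_ar2(rnorm(100000))
  expect_lt(abs(fit$phi1), 3 / sqrt(100000))
  expect_lt(abs(fit$phi2), 3 / sqrt(100000))
})

test_that("cls agrees with a direct lm() oracle; yule_walker with stats::ar.yw", {
  set.seed(13)
  for (rep in 1:8) {
    s <- simulate_subject(runif(1, -0.4, 0.6), runif(1, -0.4, 0.3),
                          innovation_sd = 0.05, n_strides = 200,
                          seed = 300 + rep)
    y <- detrend_linear(s)$residuals
    cls <- fit_ar2(y, method = "cls")
    beta <- oracle_ar2_ols(y)
    expect_equal(cls$delta, unname(beta[1]), tolerance = 1e-10)
    expect_equal(cls$phi1, unname(beta[2]), tolerance = 1e-10)
    expect_equal(cls$phi2, unname(beta[3]), tolerance = 1e-10)

    yw <- fit_ar2(y, method = "yule_walker")
    ref <- ar.yw(y, aic = FALSE, order.max = 2, demean = TRUE)
    expect_equal(yw$phi1, ref$ar[1], tolerance = 1e-8)
    expect_equal(yw$phi2, ref$ar[2], tolerance = 1e-8)
  }
})

test_that("cls and yule_walker converge on long stationary series", {
  gaps <- vapply(1:11, function(r) {
    s <- simulate_subject(0.4, 0.1, innovation_sd = 0.05, n_strides = 5000,
                          seed = 500 + r)
    y <- detrend_linear(s)$residuals
    a <- fit_ar2(y, "cls"); b <- fit_ar2(y, "yule_walker")
    max(abs(a$phi1 - b$phi1), abs(a$phi2 - b$phi2))
  }, numeric(1))
  expect_lt(median(gaps), 0.02)
})

test_that("parameter recovery across both triangle regions", {
  # mean estimate over replicates within 0.05 of truth, 9 points, n = 300
  pts <- list(c(0.4, 0.1), c(0.1, 0.0), c(0, -1/3), c(-0.5, -0.3),
              c(0.8, -0.5), c(-0.8, -0.5), c(0.5, 0.2), c(0, 0.5),
              c(-0.3, 0.15))
  for (j in seq_along(pts)) {
    p <- pts[[j]]
    est <- vapply(1:120, function(r) {
      sim_and_fit(p[1], p[2], n = 300, sigma = 0.05, seed = j * 1000 + r)
    }, numeric(2))
    expect_lt(abs(mean(est[1, ]) - p[1]), 0.05)
    expect_lt(abs(mean(est[2, ]) - p[2]), 0.05)
  }
})

test_that("degenerate and short inputs are refused", {
  expect_error(fit_ar2(rep(0, 100)), class = "gait_degenerate_error")
  expect_error(fit_ar2(rnorm(10)), class = "gait_length_error")
  expect_error(fit_ar2(rep(0, 100), "yule_walker"),
               class = "gait_degenerate_error")
})

test_that("correlogram matches stats::acf / stats::pacf", {
  set.seed(14)
  y <- as.numeric(arima.sim(list(ar = c(0.4, 0.1)), 500))
  cg <- correlogram(y, max_lag = 20)
  expect_equal(cg$acf[1], 1)
  expect_equal(cg$pacf[1], 1)
  ref_acf <- drop(acf(y, lag.max = 20, plot = FALSE, demean = TRUE)$acf)
  ref_pacf <- drop(pacf(y, lag.max = 20, plot = FALSE)$acf)
  expect_equal(cg$acf, ref_acf, tolerance = 1e-10)
  expect_equal(cg$pacf[-1], ref_pacf, tolerance = 1e-10)
  expect_equal(cg$ci_halfwidth, 1.96 / sqrt(500))
})

test_that("noiseless geometric decay shows the analytic AR(1) correlogram", {
  y <- 0.5^(0:1999)
  cg <- correlogram(y, max_lag = 6)
  expect_equal(cg$acf[2:5], 0.5^(1:4), tolerance = 0.01)
})

test_that("an AR(2) process has a PACF cutoff after lag 2", {
  s <- simulate_subject(0.4, 0.1, innovation_sd = 0.05, n_strides = 5000,
                        seed = 44)
  cg <- correlogram(detrend_linear(s)$residuals, max_lag = 10)
  expect_gt(abs(cg$pacf[2]), cg$ci_halfwidth)   # lag 1
  expect_gt(abs(cg$pacf[3]), cg$ci_halfwidth)   # lag 2
  expect_true(all(abs(cg$pacf[4:11]) < 3 * cg$ci_halfwidth))
})

test_that("correlogram parameter validation", {
  expect_error(correlogram(rnorm(50), max_lag = 25), class = "gait_param_error")
  expect_error(correlogram(rep(1, 50), max_lag = 5),
               class = "gait_degenerate_error")
})

test_that("stability classification: canonical points", {
  centroid <- classify_stability(0, -1/3)
  expect_identical(centroid$region, "oscillatory")
  expect_equal(centroid$distance, 0)
  expect_identical(classify_stability(1.5, 0.5)$region, "unstable")
  ctl <- classify_stability(0.4, 0.1)
  expect_identical(ctl$region, "non_oscillatory")
  expect_true(all(Mod(ctl$char_roots) < 1))
  expect_true(all(Im(ctl$char_roots) == 0))
  expect_identical(classify_stability(0, 0)$region, "boundary")  # repeated root 0
})

test_that("characteristic roots satisfy the defining polynomial", {
  set.seed(15)
  for (rep in 1:20) {
    p1 <- runif(1, -2.5, 2.5); p2 <- runif(1, -2.5, 2.5)
    a <- classify_stability(p1, p2)
    resid <- a$char_roots^2 - p1 * a$char_roots - p2
    expect_lt(max(Mod(resid)), 1e-10)
  }
})

test_that("region labels agree with the root-modulus oracle at random points", {
  set.seed(16)
  p1 <- runif(4000, -2.5, 2.5)
  p2 <- runif(4000, -1.5, 1.5)
  region <- ar2_region(p1, p2)
  moduli <- oracle_root_moduli(p1, p2)
  clear <- abs(moduli - 1) > 1e-6 & region != "boundary"
  expect_identical(region[clear] == "unstable", moduli[clear] > 1)
  # oscillation <=> complex roots <=> negative discriminant
  inside <- clear & region != "unstable"
  disc <- p1^2 + 4 * p2
  expect_identical(region[inside] == "oscillatory", disc[inside] < 0)
})

test_that("centroid distance closed form and properties", {
  expect_equal(ar_distance(0, -1/3), 0)
  expect_equal(ar_distance(0, 1), 4/3, tolerance = 1e-15)
  expect_equal(ar_distance(0.4, 0.1), sqrt(313) / 30, tolerance = 1e-15)
  set.seed(17)
  p1 <- rnorm(100); p2 <- rnorm(100)
  expect_true(all(ar_distance(p1, p2) >= 0))
  expect_identical(which(ar_distance(c(0, p1), c(-1/3, p2)) == 0), 1L)
})

test_that("triangle geometry: vertices, centroid, area", {
  g <- triangle_geometry()
  expect_equal(unname(g$centroid), c(0, -1/3), tolerance = 1e-15)
  v <- g$vertices
  # vertex (2, -1) sits on two stationarity constraints with equality
  expect_equal(unname(1 - v[2, 1] - v[2, 2]), 0)
  expect_equal(unname(1 - abs(v[2, 2])), 0)
  shoelace <- abs(sum(v[, 1] * v[c(2, 3, 1), 2] - v[c(2, 3, 1), 1] * v[, 2])) / 2
  expect_equal(shoelace, 4)
})
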