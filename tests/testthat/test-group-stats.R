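test_that("identical groups give t = 0, p = 1", {
  cmp <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$t_stat, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("pooled variant matches the hand-computed textbook example", {
  # a = 1..5, b = 2..6: mean gap -1, pooled SE 1 => t = -1, df = 8
  cmp <- two_sample_ttest(1:5, 2:6, variant = "pooled")
  expect_equal(cmp$t_stat, -1, tolerance = 1e-12)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$p_value, 2 * pt(-1, 8), tolerance = 1e-12)
})

test_that("both variants match the stats::t.test oracle on random data", {
  set.seed(31)
  for (rep in 1:12) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    w <- two_sample_ttest(a, b, "welch")
    ref_w <- t.test(a, b)
    expect_equal(w$t_stat, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref_w$p.value, tolerance = 1e-10)
    p <- two_sample_ttest(a, b, "pooled")
    ref_p <- t.test(a, b, var.equal = TRUE)
    expect_equal(p$t_stat, unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(p$p_value, ref_p$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate t-test inputs", {
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)),
               class = "gait_degenerate_error")
  cmp <- two_sample_ttest(c(1, 1), c(2, 2))
  expect_identical(cmp$t_stat, -Inf)
  expect_equal(cmp$p_value, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), class = "gait_param_error")
})

test_that("type-I error of the cohort-level AR1 test is near nominal", {
  # both groups drawn from the same control-like spec; reduced replicate
  # count for the unit suite (full 1000-replicate run is in acceptance)
  n_rep <- 400
  rejections <- vapply(1:n_rep, function(r) {
    sp_a <- default_cohort_specs(1500000 + 1000 * r)$control
    sp_b <- default_cohort_specs(1500500 + 1000 * r)$control
    sp_b$n_subjects <- 20L
    tab <- fit_cohort_table(list(sp_a, sp_b))
    split_at <- seq_len(16)
    cmp <- two_sample_ttest(tab$phi1[split_at], tab$phi1[-split_at], "welch")
    cmp$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("small-point-cloud empirical ellipse encloses everything", {
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  ell <- coverage_ellipse(pts, coverage_target = 0.95, mode = "empirical")
  expect_equal(ell$empirical_coverage, 1.0)
  expect_equal(unname(ell$center), c(0, 0))
})

test_that("gaussian ellipse achieves chi-square coverage on normal clouds", {
  set.seed(32)
  pts <- matrix(rnorm(20000), ncol = 2)
  ell <- coverage_ellipse(pts, 0.95, mode = "gaussian")
  expect_gt(ell$empirical_coverage, 0.94)
  expect_lt(ell$empirical_coverage, 0.96)
})

test_that("ellipse translation equivariance", {
  set.seed(33)
  pts <- cbind(rnorm(50, sd = 0.3), rnorm(50, sd = 0.1))
  e0 <- coverage_ellipse(pts)
  e1 <- coverage_ellipse(sweep(pts, 2, c(-2, 5), `+`))
  expect_equal(unname(e1$center), unname(e0$center) + c(-2, 5), tolerance = 1e-12)
  expect_equal(e1$semi_axes, e0$semi_axes, tolerance = 1e-12)
  expect_equal(e1$angle, e0$angle, tolerance = 1e-12)
})

test_that("empirical mode always covers at least the target on its inputs", {
  set.seed(34)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    pts <- cbind(rnorm(n), rnorm(n, sd = runif(1, 0.2, 2)))
    tgt <- runif(1, 0.5, 0.99)
    ell <- coverage_ellipse(pts, tgt, mode = "empirical")
    expect_gte(ell$empirical_coverage, tgt)
  }
})

test_that("ellipse outline lies on the fitted Mahalanobis contour", {
  set.seed(35)
  pts <- cbind(rnorm(40), rnorm(40))
  ell <- coverage_ellipse(pts, 0.9, "gaussian")
  d2 <- mahalanobis(ellipse_outline(ell, 73), ell$center, ell$covariance)
  expect_equal(d2, rep(ell$mahalanobis_r2, 73), tolerance = 1e-8)
})

test_that("degenerate ellipse inputs are refused", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(coverage_ellipse(line), class = "gait_degenerate_error")
  expect_error(coverage_ellipse(rbind(c(0, 0), c(1, 1))),
               class = "gait_param_error")
  expect_error(coverage_ellipse(cbind(rnorm(5), rnorm(5)), coverage_target = 1),
               class = "gait_param_error")
})

test_that("perfectly separated distances classify perfectly", {
  d <- c(rep(0.6, 16), rep(0.4, 20))
  lab <- c(rep("control", 16), rep("huntington", 20))
  rep_ <- classify_by_distance(d, lab)
  expect_identical(rep_$positive_label, "huntington")
  expect_equal(rep_$threshold, 0.5)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
})

test_that("threshold below all distances: sensitivity 0, specificity 1", {
  d <- c(rep(0.6, 5), rep(0.4, 5))
  lab <- rep(c("a", "b"), each = 5)
  rep_ <- classify_by_distance(d, lab, positive_label = "b", threshold = 0.1)
  expect_equal(rep_$sensitivity, 0)
  expect_equal(rep_$specificity, 1)
})

test_that("shuffled labels give chance-level accuracy; identities hold exactly", {
  set.seed(36)
  d <- rnorm(2000, mean = 0.5, sd = 0.1)
  lab <- sample(rep(c("a", "b"), each = 1000))
  rep_ <- classify_by_distance(d, lab)
  expect_lt(abs(rep_$accuracy - 0.5), 0.05)  # balanced-prevalence baseline
  cm <- rep_$confusion
  expect_equal(sum(cm), 2000)
  expect_equal(rep_$accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  expect_equal(rep_$sensitivity, cm[1, 1] / sum(cm[, 1]))
  expect_equal(rep_$specificity, cm[2, 2] / sum(cm[, 2]))
})

test_that("one-class classification input is refused", {
  expect_error(classify_by_distance(c(0.4, 0.5), c("a", "a")),
               class = "gait_param_error")
})

test_that("cohort summary aggregates per group with degenerate-SD flag", {
  subjects <- data.frame(
    group_label = c("control", "huntington"),
    stride_time_s = c(1.1, 1.2),
    phi1 = c(0.4, 0.1), phi2 = c(0.1, 0.0),
    distance = c(0.59, 0.35),
    region = c("non_oscillatory", "oscillatory")
  )
  s <- summarize_cohort(subjects)
  ctl <- s$metrics[s$metrics$group_label == "control", ]
  expect_equal(ctl$mean[ctl$metric == "ar1"], 0.4)
  expect_true(all(ctl$sd == 0) && all(ctl$sd_undefined))
  frac <- s$regions
  expect_equal(frac$fraction[frac$group_label == "huntington" &
                             frac$region == "oscillatory"], 1)
})

test_that("subjects at the centroid summarize to zero mean distance", {
  subjects <- data.frame(
    group_label = "g", stride_time_s = 1.1,
    phi1 = 0, phi2 = -1/3,
    distance = ar_distance(0, -1/3),
    region = "oscillatory"
  )[rep(1, 4), ]
  s <- summarize_cohort(subjects)
  expect_equal(s$metrics$mean[s$metrics$metric == "ar_distance"], 0)
  expect_error(summarize_cohort(subjects[0, ]), class = "gait_data_error")
})
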