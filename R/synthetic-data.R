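# run code with a temporary RNG state so generators are pure functions of their seed
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

BURN_IN <- 200L  # AR(2) memory with roots well inside the unit circle decays much faster

#' Simulate one subject's stride-time series
#'
#' Generates a stationary AR(2) process with Gaussian innovations,
#' \eqn{y_t = \phi_1 y_{t-1} + \phi_2 y_{t-2} + \varepsilon_t}, discards a
#' 200-step burn-in so the retained segment is approximately stationary, and
#' adds the subject's mean stride time plus an optional linear trend. This is
#' the generative counterpart of the fitted model: the analysis pipeline
#' should recover \eqn{(\phi_1, \phi_2)} from the output.
#'
#' @param phi1,phi2 AR coefficients; must lie strictly inside the
#'   stationarity triangle.
#' @param stride_mean mean stride time in seconds (default 1.1 s, typical of
#'   healthy adult walking).
#' @param innovation_sd SD of the Gaussian innovations, in seconds.
#' @param trend_slope linear drift in seconds per stride (default 0).
#' @param n_strides series length (>= 30; default 250, roughly a five-minute
#'   walk at ~1.2 s per stride).
#' @param seed integer seed; identical arguments and seed give a bitwise
#'   identical series. `NULL` uses (and advances) the current RNG state.
#' @param subject_id,group_label metadata for the returned series.
#' @return A [stride_series] with `source = "simulated"`.
#' @examples
#' simulate_subject(0.4, 0.1, innovation_sd = 0.03, seed = 1)
#' @export
simulate_subject <- function(phi1, phi2,
                             stride_mean = 1.1,
                             innovation_sd = 0.05,
                             trend_slope = 0,
                             n_strides = 250L,
                             seed = NULL,
                             subject_id = "sim",
                             group_label = "unknown") {
  m <- ar2_margins(phi1, phi2)
  if (any(m <= 0)) {
    bad <- c("phi1 + phi2 < 1", "phi2 - phi1 < 1", "|phi2| < 1")[m[1, ] <= 0]
    stop_gait(sprintf("(phi1=%.3g, phi2=%.3g) is not strictly stationary; violates: %s",
                      phi1, phi2, paste(bad, collapse = ", ")),
              "gait_param_error")
  }
  n_strides <- as.integer(n_strides)
  if (n_strides < 30L) {
    stop_gait(sprintf("n_strides = %d; >= 30 required", n_strides),
              "gait_length_error")
  }
  if (innovation_sd < 0) {
    stop_gait("innovation_sd must be >= 0", "gait_param_error")
  }
  y <- with_seed(seed, {
    eps <- stats::rnorm(BURN_IN + n_strides, mean = 0, sd = innovation_sd)
    ar <- as.numeric(stats::filter(eps, c(phi1, phi2), method = "recursive"))
    ar[(BURN_IN + 1L):(BURN_IN + n_strides)]
  })
  t <- as.numeric(seq_len(n_strides) - 1L)
  stride_series(
    stride_times = stride_mean + trend_slope * t + y,
    subject_id = subject_id,
    group_label = group_label,
    foot = "left",
    source = "simulated"
  )
}

#' Specify a synthetic gait cohort
#'
#' A `cohort_spec` holds the generative parameters for one group: per-subject
#' AR coefficients are drawn from independent normals (rejection-sampled into
#' the stationarity triangle), mean stride times from a normal truncated
#' below at 0.4 s, and each subject's series is then produced by
#' [simulate_subject]. The defaults of [default_cohort_specs] emulate the
#' published control and Huntington's-disease group summaries.
#'
#' @param group_label group name, e.g. `"control"` or `"huntington"`.
#' @param n_subjects number of subjects (>= 1).
#' @param n_strides strides per subject (default 250).
#' @param phi1_mean,phi1_sd,phi2_mean,phi2_sd between-subject distribution of
#'   the AR coefficients; the mean pair must be stationary.
#' @param stride_mean_s,stride_mean_sd_s between-subject mean stride time
#'   distribution, seconds.
#' @param innovation_sd_s within-subject innovation SD, seconds.
#' @param trend_slope_s_per_stride common linear drift (default 0).
#' @param master_seed integer; the cohort is a pure function of the spec,
#'   including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label,
                        n_subjects,
                        n_strides = 250L,
                        phi1_mean, phi1_sd,
                        phi2_mean, phi2_sd,
                        stride_mean_s, stride_mean_sd_s,
                        innovation_sd_s,
                        trend_slope_s_per_stride = 0,
                        master_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_strides <- as.integer(n_strides)
  if (n_subjects < 1L) stop_gait("n_subjects must be >= 1", "gait_param_error")
  if (n_strides < 30L) {
    stop_gait("n_strides must be >= 30", "gait_length_error")
  }
  sds <- c(phi1_sd, phi2_sd, stride_mean_sd_s, innovation_sd_s)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop_gait("all SD fields must be finite and >= 0", "gait_param_error")
  }
  if (any(ar2_margins(phi1_mean, phi2_mean) <= 0)) {
    stop_gait(sprintf("mean pair (%.3g, %.3g) is not inside the stationarity triangle",
                      phi1_mean, phi2_mean),
              "gait_param_error")
  }
  structure(
    list(group_label = as.character(group_label),
         n_subjects = n_subjects, n_strides = n_strides,
         phi1_mean = phi1_mean, phi1_sd = phi1_sd,
         phi2_mean = phi2_mean, phi2_sd = phi2_sd,
         stride_mean_s = stride_mean_s, stride_mean_sd_s = stride_mean_sd_s,
         innovation_sd_s = innovation_sd_s,
         trend_slope_s_per_stride = trend_slope_s_per_stride,
         master_seed = as.integer(master_seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_spec %s> %d subjects x %d strides; phi1 ~ N(%.2f, %.2f), ",
           "phi2 ~ N(%.2f, %.2f); stride %.2f +/- %.2f s; innovation sd %.3f s; seed %d\n"),
    x$group_label, x$n_subjects, x$n_strides, x$phi1_mean, x$phi1_sd,
    x$phi2_mean, x$phi2_sd, x$stride_mean_s, x$stride_mean_sd_s,
    x$innovation_sd_s, x$master_seed
  ))
  invisible(x)
}

#' Default control-like and HD-like cohort specifications
#'
#' Emulates the published two-group study: 16 controls with mean coefficients
#' (0.4, 0.1) and mean stride time 1.1 s, versus 20 Huntington's-disease
#' subjects with mean coefficients (0.1, 0.0) and mean stride time 1.2 s,
#' with between-subject SDs matching the printed group summaries. Innovation
#' SDs (0.03 s control, 0.08 s HD) are not published quantities; they are
#' fixed choices that reproduce the printed stride-time SD ordering.
#'
#' @param master_seed integer master seed; the HD spec uses `master_seed + 10000`
#'   so the two groups draw independent streams.
#' @return Named list of two [cohort_spec] objects (`control`, `huntington`).
#' @export
default_cohort_specs <- function(master_seed = 1L) {
  master_seed <- as.integer(master_seed)
  list(
    control = cohort_spec(
      group_label = "control", n_subjects = 16L, n_strides = 250L,
      phi1_mean = 0.4, phi1_sd = 0.1,
      phi2_mean = 0.1, phi2_sd = 0.1,
      stride_mean_s = 1.1, stride_mean_sd_s = 0.1,
      innovation_sd_s = 0.03,
      master_seed = master_seed
    ),
    huntington = cohort_spec(
      group_label = "huntington", n_subjects = 20L, n_strides = 250L,
      phi1_mean = 0.1, phi1_sd = 0.2,
      phi2_mean = 0.0, phi2_sd = 0.1,
      stride_mean_s = 1.2, stride_mean_sd_s = 0.2,
      innovation_sd_s = 0.08,
      master_seed = (master_seed + 10000L) %% .Machine$integer.max
    )
  )
}

MAX_REJECTION_DRAWS <- 10000L
STRIDE_MEAN_FLOOR_S <- 0.4  # physiologic positivity floor for mean stride time
SERIES_SEED_OFFSET <- 524287L  # separates the innovation stream from the parameter draw

#' Simulate a cohort of stride-time series
#'
#' Draws each subject's generative parameters from the spec's between-subject
#' distributions and simulates their series. Per-subject seeds are
#' `master_seed + i` (counter-based, so adding subjects does not reshuffle
#' earlier ones); the innovation stream uses a fixed offset from the same
#' counter. Coefficient pairs are rejection-sampled until strictly inside the
#' stationarity triangle; mean stride times are resampled until above the
#' 0.4 s floor.
#'
#' @param spec a [cohort_spec].
#' @return A list of [stride_series], one per subject, with ids
#'   `<group_label>_01`, `<group_label>_02`, ... Each series carries its
#'   generative parameters as attributes `true_phi1`, `true_phi2`,
#'   `true_stride_mean` for parameter-recovery checks.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_subjects), function(i) {
    param_seed <- (spec$master_seed + i) %% .Machine$integer.max
    pars <- with_seed(param_seed, {
      draws <- 0L
      repeat {
        draws <- draws + 1L
        if (draws > MAX_REJECTION_DRAWS) {
          stop_gait(sprintf(
            "subject %d: > %d rejection draws; coefficient means too close to the stationarity boundary",
            i, MAX_REJECTION_DRAWS), "gait_param_error")
        }
        p1 <- stats::rnorm(1L, spec$phi1_mean, spec$phi1_sd)
        p2 <- stats::rnorm(1L, spec$phi2_mean, spec$phi2_sd)
        if (all(ar2_margins(p1, p2) > 0)) break
      }
      draws <- 0L
      repeat {
        draws <- draws + 1L
        if (draws > MAX_REJECTION_DRAWS) {
          stop_gait(sprintf(
            "subject %d: > %d draws below the %.1f s stride-mean floor",
            i, MAX_REJECTION_DRAWS, STRIDE_MEAN_FLOOR_S), "gait_param_error")
        }
        mu <- stats::rnorm(1L, spec$stride_mean_s, spec$stride_mean_sd_s)
        if (mu >= STRIDE_MEAN_FLOOR_S) break
      }
      list(phi1 = p1, phi2 = p2, stride_mean = mu)
    })
    s <- simulate_subject(
      phi1 = pars$phi1, phi2 = pars$phi2,
      stride_mean = pars$stride_mean,
      innovation_sd = spec$innovation_sd_s,
      trend_slope = spec$trend_slope_s_per_stride,
      n_strides = spec$n_strides,
      seed = (spec$master_seed + i + SERIES_SEED_OFFSET) %% .Machine$integer.max,
      subject_id = sprintf("%s_%02d", spec$group_label, i),
      group_label = spec$group_label
    )
    # simulation ground truth, for parameter-recovery checks
    attr(s, "true_phi1") <- pars$phi1
    attr(s, "true_phi2") <- pars$phi2
    attr(s, "true_stride_mean") <- pars$stride_mean
    s
  })
}

#' Read cohort specifications from a JSON config file
#'
#' The file holds an array (or named object) of objects whose fields are the
#' arguments of [cohort_spec]. Used by the `simulate` input mode of the
#' pipeline and the CLI.
#'
#' @param path JSON file path.
#' @return Named list of [cohort_spec] objects.
#' @export
read_cohort_specs <- function(path) {
  if (!file.exists(path)) {
    stop_gait(sprintf("cannot read '%s': no such file", path), "gait_io_error")
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_gait(sprintf("cannot parse '%s' as JSON: %s",
                                      path, conditionMessage(e)),
                              "gait_schema_error")
                  })
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  specs <- lapply(raw, function(item) {
    item <- as.list(item)
    do.call(cohort_spec, item[intersect(names(item), names(formals(cohort_spec)))])
  })
  names(specs) <- vapply(specs, `[[`, character(1), "group_label")
  specs
}
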