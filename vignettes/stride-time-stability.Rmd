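---
title: "Stride-time pattern stability via AR(2) modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride-time pattern stability via AR(2) modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strideAR)
```

## The model and its assumptions

A walking subject's consecutive stride intervals $y_1, \dots, y_n$ (seconds)
form a time series. `strideAR` analyzes its *pattern stability* in three
steps.

**1. Linear detrending.** An ordinary least-squares line on stride index
$t = 0, \dots, n-1$ is subtracted (`detrend_linear()`). Slow drift — pacing,
fatigue — would otherwise contaminate the autoregressive coefficients; what
remains is the stride-to-stride fluctuation around the trend. The regressor
is stride *index*, not elapsed time: stride series are conventionally
plotted and modeled against stride number, and the two regressors are nearly
proportional anyway since stride time varies by only a few percent. An
`elapsed` option exists for sensitivity analysis.

**2. AR(2) fitting.** The detrended series is modeled as
$$y_t = \delta + \phi_1 y_{t-1} + \phi_2 y_{t-2} + \varepsilon_t,$$
with $\varepsilon_t$ white noise (`fit_ar2()`). Order 2 is the smallest
order whose coefficient plane distinguishes oscillatory from non-oscillatory
stable dynamics; `correlogram()` provides the ACF/PACF diagnostics that
justify it (an AR(2) PACF cuts off after lag 2). The model assumes the
detrended fluctuations are covariance-stationary with linear short-memory
dynamics; it does not capture long-range (fractal) correlation structure,
heavy-tailed innovations, or regime switching.

**3. Triangle placement.** The process is stationary iff both roots of
$z^2 - \phi_1 z - \phi_2$ lie inside the unit circle, equivalently iff
$\phi_1 + \phi_2 < 1$, $\phi_2 - \phi_1 < 1$, $|\phi_2| < 1$ — the
*stationarity triangle* with vertices $(-2,-1)$, $(2,-1)$, $(0,1)$. Inside
it, complex roots (discriminant $\phi_1^2 + 4\phi_2 < 0$) give damped
oscillatory dynamics; real roots give non-oscillatory decay with two time
constants. The scalar stability statistic is the Euclidean distance from
$(\phi_1, \phi_2)$ to the triangle centroid $(0, -1/3)$
(`ar_distance()`), which sits inside the oscillatory region.

The oscillatory boundary is sometimes drawn as a "semicircle"; the
mathematically exact boundary is the parabola $\phi_2 = -\phi_1^2/4$ (zero
discriminant), and that is what `ar2_region()` implements and what
`plot_triangle()` draws, because the discriminant criterion *is* what
oscillatory response means dynamically. A grid test verifies that the
inequality classification agrees everywhere with the characteristic-root
criterion.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `n_strides` | generator | 250 | a five-minute walk at ~1.2 s/stride |
| detrend regressor | `detrend_linear` | `index` | stride-series convention |
| outlier rule | `remove_outliers` | **disabled**, $k = 3$ MAD | the literal procedure (detrend, fit) is the default; hallway turnaround strides can be removed for sensitivity analysis |
| fit method | `fit_ar2` | `cls` | conditional least squares matches the regression form of the model including $\delta$; `yule_walker` is cross-checked in tests |
| boundary `tol` | `ar2_region` | $10^{-9}$ | ties within `tol` of a boundary are labelled `boundary` rather than forced into a region |
| ellipse mode | `coverage_ellipse` | `empirical` | "encloses 95% of the subjects" is an empirical statement, not a parametric confidence region; `gaussian` ($\chi^2_2$ scaling) is available |
| t-test variant | `two_sample_ttest` | `welch` | group SDs differ; Welch is the safer default, pooled kept for sensitivity |
| classifier threshold | `classify_by_distance` | midpoint of group mean distances | the disease group sits nearer the centroid; the direction is fixed, not learned |

$\delta$ is retained in the CLS regression even though detrended residuals
have mean $\approx 0$ (so $\hat\delta \approx 0$); dropping it would change
nothing material but including it matches the model as written. `sigma2`
from CLS is the unbiased residual variance (RSS over $n_\mathrm{eff} - 3$);
from Yule–Walker it is the implied innovation variance.

## The synthetic cohort generator: a stated world

`default_cohort_specs()` fixes one two-group world, chosen to match the
published control/HD group summaries and **not** revisited after seeing test
results:

* 16 control-like subjects: $\phi_1 \sim N(0.4, 0.1^2)$,
  $\phi_2 \sim N(0.1, 0.1^2)$, mean stride time $N(1.1, 0.1^2)$ s,
  innovation SD 0.03 s;
* 20 HD-like subjects: $\phi_1 \sim N(0.1, 0.2^2)$,
  $\phi_2 \sim N(0.0, 0.1^2)$, mean stride time $N(1.2, 0.2^2)$ s,
  innovation SD 0.08 s;
* 250 strides per subject; coefficient draws rejection-sampled into the
  stationarity triangle; stride means truncated below at a 0.4 s
  physiological floor; Gaussian innovations; 200-step burn-in before the
  retained segment.

The innovation SDs are the one genuinely free choice: the source summaries
do not report them. The values 0.03/0.08 s were chosen once so that the
within-subject fluctuation reproduces the printed stride-time SD ordering
(healthy gait fluctuates a few hundredths of a second per stride; HD gait
several times more).

Per-subject seeds are counter-based (`master_seed + i`), so enlarging a
cohort does not reshuffle existing subjects; the innovation stream uses a
fixed large offset from the same counter so parameter draws and noise never
share RNG states. Tests that average over cohort replicates space their
master seeds so the counter ranges of different replicates cannot overlap.

**What a green test establishes — and what it does not.** The generator
emulates exactly the statistical structure the analysis assumes: linear
trend plus stationary Gaussian AR(2), with normal between-subject
heterogeneity. Real stride series additionally contain turnaround artifacts
from hallway protocols, missteps, possible long-range fractal correlations,
and non-Gaussian innovations. Green tests therefore establish correctness of
the estimator and pipeline under the model's own assumptions, and
statistical power under the published effect sizes — not that real
accession data will reproduce the published table. The pipeline's
`gaitndd_dir` mode exists so that a reader with a local copy of the public
stride-interval database can run that comparison themselves.

## Numerical choices

* **Exact collinearity in CLS.** A noiseless geometric recursion makes the
  two lag columns exactly proportional; the pivoted least-squares solution
  drops one lag and its coefficient is reported as 0 (so $y_t = 0.5
  y_{t-1}$ fits as $(0.5, 0)$). Rank below 2 (constant residuals) is a
  degenerate-fit error.
* **Boundary ties.** Region classification uses a $10^{-9}$ half-width band
  labelled `boundary`; grid comparisons against the root criterion exclude
  those ties and points whose root modulus is within $10^{-9}$ of 1.
* **Characteristic-root convention.** Roots of $z^2 - \phi_1 z - \phi_2$,
  stationary iff modulus < 1 (the inverse-root convention is equivalent;
  one is fixed to avoid sign confusion).
* **MAD scaling.** The outlier rule uses the SD-consistent constant 1.4826;
  a zero MAD (constant series) removes nothing.
* **Empirical ellipse radius.** The smallest Mahalanobis radius whose
  enclosed fraction reaches the target, i.e. the $\lceil cn \rceil$-th
  smallest squared distance; boundary points count as inside.
* **Truncation floors.** Stride means are resampled (not clipped) above
  0.4 s; rejection sampling aborts with a parameterization error after
  10,000 draws rather than looping forever.

## Design choices where the design was open

* **Which foot?** The source analysis never states whether left, right, or
  averaged stride intervals were modeled. Default `left`, with `right` and
  `mean` selectable.
* **Classification procedure.** Accuracy/sensitivity/specificity are
  reported in the source without a stated procedure or values. The
  distance-threshold classifier here is a declared reconstruction and labels
  itself as such in its output.
* **Multiple testing.** None applied — raw per-metric p-values are
  reported, matching the source's presentation.
* **Innovations.** Gaussian; the model only requires white noise, but
  alternative innovation families are out of scope.

## Limitations

* The AR(2) model ignores long-range correlation structure (the DFA-style
  scaling exponent is a complementary, not competing, statistic and is out
  of scope here).
* Group-level conclusions from the synthetic world inherit its normality
  assumptions; real cohorts may be skewed or contain outlying subjects.
* The distance statistic collapses two coefficients to one number; two
  subjects at equal distance may sit in different regions. Region labels
  and the triangle plot should be read together with it.
* Extra group labels (`als`, `park`) flow through the pipeline mechanically;
  no claims are made about their discrimination.
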