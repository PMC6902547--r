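#' Plot subjects on the AR(2) stationarity triangle
#'
#' Draws the stationarity triangle, shades the oscillatory region (bounded
#' above by the discriminant parabola \eqn{\phi_2 = -\phi_1^2/4}), marks the
#' centroid (0, -1/3), plots each subject's fitted coefficient pair coloured
#' by group, and optionally overlays per-group 95% coverage ellipses.
#'
#' @param fits data frame with columns `phi1`, `phi2`, `group_label` (the
#'   fits table written by [run_pipeline]).
#' @param ellipses draw per-group coverage ellipses (groups with >= 3
#'   subjects only).
#' @param ellipse_mode passed to [coverage_ellipse].
#' @param coverage_target passed to [coverage_ellipse].
#' @param file optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @param main plot title.
#' @return Invisibly, the list of per-group [coverage_ellipse] objects (or
#'   `NULL` where not computable).
#' @export
plot_triangle <- function(fits,
                          ellipses = TRUE,
                          ellipse_mode = "empirical",
                          coverage_target = 0.95,
                          file = NULL,
                          main = "AR(2) stationarity triangle") {
  stopifnot(all(c("phi1", "phi2", "group_label") %in% names(fits)))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 750, res = 120)
    on.exit(grDevices::dev.off())
  }
  geom <- triangle_geometry()
  groups <- sort(unique(fits$group_label))
  cols <- grDevices::hcl.colors(max(length(groups), 2L), "Dark 3")[seq_along(groups)]
  names(cols) <- groups

  graphics::plot(NA, xlim = c(-2.3, 2.3), ylim = c(-1.3, 1.3),
                 xlab = expression(phi[1] ~ "(AR1)"),
                 ylab = expression(phi[2] ~ "(AR2)"),
                 main = main, asp = 1)
  # oscillatory region: below the parabola, above the triangle base
  px <- seq(-2, 2, length.out = 401)
  graphics::polygon(c(px, rev(px)), c(-px^2 / 4, rep(-1, length(px))),
                    col = grDevices::adjustcolor("grey70", 0.4), border = NA)
  graphics::polygon(geom$vertices[, 1L], geom$vertices[, 2L], border = "black")
  graphics::lines(px, -px^2 / 4, lty = 2)
  graphics::points(geom$centroid[1L], geom$centroid[2L], pch = 3, cex = 1.4)

  ell_out <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    sub <- fits[fits$group_label == g, , drop = FALSE]
    graphics::points(sub$phi1, sub$phi2, pch = 19, col = cols[[g]])
    if (ellipses && nrow(sub) >= 3L) {
      ell <- tryCatch(
        coverage_ellipse(sub[, c("phi1", "phi2")],
                         coverage_target = coverage_target,
                         mode = ellipse_mode),
        gait_error = function(e) NULL
      )
      if (!is.null(ell)) {
        graphics::lines(ellipse_outline(ell), col = cols[[g]], lwd = 2)
        ell_out[[g]] <- ell
      }
    }
  }
  graphics::legend("topright", legend = c(groups, "oscillatory region", "centroid"),
                   col = c(cols, "grey50", "black"),
                   pch = c(rep(19, length(groups)), 15, 3), bty = "n")
  invisible(ell_out)
}
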