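# Basic diagnostic plots (base graphics).

GAIT_COLORS <- c(walk = "#88c999", trot = "#7fa8d9", gallop = "#e8b36b",
                 bound = "#d98a8a", unclassified = "grey85", none = "white")

#' Plot a bifurcation diagram
#'
#' Phase differences against the drive parameter, one panel per phase
#' difference, points colored by gait label; up- and down-sweep branches are
#' drawn with different symbols so hysteresis regions are visible.
#'
#' @param x a `cpg_bifurcation`.
#' @param vars which phase differences to draw.
#' @param ... unused.
#' @export
plot.cpg_bifurcation <- function(x, vars = c("hind_lr", "fore_lr",
                                             "homolateral", "diagonal"),
                                 ...) {
  st <- x$steps[x$steps$accepted, ]
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    graphics::plot(st$alpha, st[[v]], pch = ifelse(st$direction == "up", 16, 1),
                   col = GAIT_COLORS[st$gait], ylim = c(0, 1),
                   xlab = expression(alpha), ylab = v, cex = 0.6)
  }
  invisible(x)
}

#' Plot flexor-center outputs of a trajectory
#'
#' @param x a `cpg_trajectory` recording the four flexor centers.
#' @param from,to time window, ms.
#' @param ... unused.
#' @export
plot.cpg_trajectory <- function(x, from = NULL, to = NULL, ...) {
  flex <- intersect(limb_flexors(NULL), colnames(x$V))
  sel <- rep(TRUE, length(x$t))
  if (!is.null(from)) sel <- sel & x$t >= from
  if (!is.null(to)) sel <- sel & x$t <= to
  old <- graphics::par(mfrow = c(length(flex), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (id in flex) {
    graphics::plot(x$t[sel], output_activity(x$V[sel, id]), type = "l",
                   xlab = "t (ms)", ylab = names(flex)[flex == id],
                   ylim = c(0, 1))
    graphics::abline(h = 0.1, lty = 3)
  }
  invisible(x)
}
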