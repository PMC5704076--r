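#' Plot a simulated trace
#'
#' Time courses of alpha, beta and gamma (top three panels) and, when the
#' trace contains an obstacle experiment, the contact/removal epoch marked
#' by vertical lines.
#'
#' @param x A \code{leg_trace}.
#' @param which Either "time" (angle time courses) or "state"
#'   (beta-gamma state diagram; pre-contact loop in red, post-removal in
#'   blue, following the usual colour convention).
#' @param ... Unused.
#' @export
plot.leg_trace <- function(x, which = c("time", "state"), ...) {
  which <- match.arg(which)
  ev <- attr(x, "events")
  if (which == "time") {
    op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
    on.exit(graphics::par(op))
    ts <- x$time_ms / 1000
    for (ang in c("alpha_deg", "beta_deg", "gamma_deg")) {
      graphics::plot(ts, x[[ang]], type = "l",
                     xlab = "time (s)",
                     ylab = sub("_deg", " (deg)", ang))
      if (!is.null(ev$t_contact)) {
        graphics::abline(v = ev$t_contact / 1000, lty = 2, col = "red")
        graphics::abline(v = ev$t_removal / 1000, lty = 2, col = "blue")
      }
    }
  } else {
    if (!is.null(ev$t_contact)) {
      pre <- x[x$time_ms < ev$t_contact, ]
      post <- x[x$time_ms > ev$t_removal, ]
      graphics::plot(pre$beta_deg, pre$gamma_deg, type = "l", col = "red",
                     xlim = range(x$beta_deg), ylim = range(x$gamma_deg),
                     xlab = "beta (deg)", ylab = "gamma (deg)")
      graphics::lines(post$beta_deg, post$gamma_deg, col = "blue")
      graphics::legend("bottomright", c("before placement", "after removal"),
                       col = c("red", "blue"), lty = 1, bty = "n")
    } else {
      graphics::plot(x$beta_deg, x$gamma_deg, type = "l",
                     xlab = "beta (deg)", ylab = "gamma (deg)")
    }
  }
  invisible(x)
}
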