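#' Generate a synthetic trace fixture
#'
#' Constructs small synthetic angle traces exhibiting, by construction, the
#' phenomena the analysis layer is designed to detect.  This makes the
#' analysis functions testable independently of the simulator.  The
#' construction labels are embedded as attributes.
#'
#' Kinds:
#' \describe{
#'   \item{triangle-loop}{beta-gamma limit cycle tracing a triangle.}
#'   \item{rectangle-loop}{beta-gamma limit cycle tracing a rectangle.}
#'   \item{alternating}{gamma oscillation whose cycle amplitudes alternate
#'     large/small (period-2-like envelope).}
#'   \item{cessation}{gamma oscillates, then stops (flat at a high value)
#'     after \code{params$t_stop}.}
#'   \item{stretched-bobbing}{gamma nearly constant and high (stretched
#'     leg) while beta keeps oscillating: only up-down movements.}
#' }
#'
#' @param kind Fixture kind, see Details.
#' @param params Named list of overrides: \code{duration} (ms),
#'   \code{period} (ms), \code{noise} (deg, sd of added jitter),
#'   \code{t_stop} (ms, cessation), \code{amp_high}/\code{amp_low}
#'   (alternating), \code{round_frac} (corner rounding of loop fixtures,
#'   as a fraction of the edge length), \code{dt} (ms).
#' @param seed Integer seed used only when \code{noise > 0}.
#' @return A \code{leg_trace} with attribute \code{fixture} recording the
#'   construction labels.
#' @examples
#' fx <- make_fixture("rectangle-loop")
#' classify_loop(cbind(fx$beta_deg, fx$gamma_deg))$label
#' @export
make_fixture <- function(kind = c("triangle-loop", "rectangle-loop",
                                  "alternating", "cessation",
                                  "stretched-bobbing"),
                         params = list(), seed = 1L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown fixture kind: ", kind))
  p <- list(duration = 10000, period = 1000, noise = 0, t_stop = 5000,
            amp_high = 40, amp_low = 24, round_frac = 0, dt = 5)
  p[names(params)] <- params
  t <- seq(0, p$duration, by = p$dt)
  ncyc <- p$duration / p$period
  phase <- (t %% p$period) / p$period

  loop_trace <- function(verts) {
    # closed polygon traversed at constant speed, optionally rounded
    v <- rbind(verts, verts[1, ])
    seg <- sqrt(rowSums(diff(v)^2))
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    pos <- phase * total
    b <- stats::approx(s, v[, 1], pos, rule = 2)$y
    g <- stats::approx(s, v[, 2], pos, rule = 2)$y
    if (p$round_frac > 0) {
      w <- max(1L, round(p$round_frac * p$period / p$dt))
      k <- rep(1 / w, w)
      pad <- function(x) as.numeric(stats::filter(
        c(x[(length(x) - w + 1):length(x)], x, x[1:w]), k, sides = 2))[
          (w + 1):(w + length(x))]
      b <- pad(b); g <- pad(g)
    }
    cbind(b, g)
  }

  labels <- list(kind = kind)
  if (kind == "triangle-loop") {
    bg <- loop_trace(rbind(c(30, 170), c(-5, 170), c(-5, 85)))
    beta <- bg[, 1]; gamma <- bg[, 2]
    labels$loop_class <- "triangular"
  } else if (kind == "rectangle-loop") {
    bg <- loop_trace(rbind(c(30, 170), c(-5, 170), c(-5, 85), c(30, 85)))
    beta <- bg[, 1]; gamma <- bg[, 2]
    labels$loop_class <- "quadrilateral"
  } else if (kind == "alternating") {
    # half-wave bumps over a common baseline so that the peak-to-trough
    # drops equal the alternating bump heights by construction
    amp <- ifelse((floor(t / p$period) %% 2) == 0, p$amp_high, p$amp_low)
    gamma <- 100 + amp * pmax(0, sin(2 * pi * t / p$period))
    beta <- 12 + 15 * sin(2 * pi * t / p$period)
    labels$alternating <- TRUE
    labels$depth <- (p$amp_high - p$amp_low) / p$amp_high
  } else if (kind == "cessation") {
    gamma <- ifelse(t < p$t_stop,
                    130 + 40 * sin(2 * pi * t / p$period), 168)
    beta <- 12 + 15 * sin(2 * pi * t / p$period)
    labels$cessation_start <- p$t_stop
  } else {  # stretched-bobbing
    gamma <- rep(160, length(t))
    beta <- 12 + 15 * sin(2 * pi * t / p$period)
    labels$gamma_ceased <- TRUE
    labels$beta_ceased <- FALSE
  }

  if (p$noise > 0) {
    set.seed(seed)
    beta <- beta + stats::rnorm(length(t), sd = p$noise)
    gamma <- gamma + stats::rnorm(length(t), sd = p$noise)
  }
  gamma <- pmin(180, pmax(0.5, gamma))
  geom <- default_leg_config()$geometry
  tr <- data.frame(time_ms = t, beta_deg = beta, gamma_deg = gamma,
                   alpha_deg = compute_alpha(beta, gamma, geom))
  attr(tr, "preset") <- paste0("fixture:", kind)
  attr(tr, "config_hash") <- "fixture"
  attr(tr, "events") <- list()
  attr(tr, "fixture") <- labels
  class(tr) <- c("leg_trace", "data.frame")
  tr
}
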