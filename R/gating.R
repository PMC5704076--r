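#' Two-valued threshold gate on a joint angle
#'
#' The sensory coupling between the two local networks reduces each joint
#' angle to a two-valued synaptic conductance: the conductance takes its
#' high value when the angle is at or above the threshold and its low value
#' below it (no intermediate outputs, no hysteresis; ties go to high).
#'
#' @param angle Angle(s), deg (vectorised).
#' @param thr Threshold, deg.
#' @param g_high,g_low Conductance values, \code{g_high >= g_low >= 0}.
#' @param polarity +1 (default): high when \code{angle >= thr};
#'   -1 reverses the mapping.
#' @return Conductance value(s), each equal to \code{g_high} or
#'   \code{g_low}.
#' @examples
#' gate_conductance(c(82, 83, 84), 83, 1, 0)  # 0 1 1
#' @export
gate_conductance <- function(angle, thr, g_high, g_low, polarity = 1) {
  if (g_low < 0 || g_high < g_low)
    stop("need g_high >= g_low >= 0")
  above <- angle >= thr
  if (polarity < 0) above <- !above
  ifelse(above, g_high, g_low)
}

#' Classify the gating regime of a gamma threshold on a trace
#'
#' With the threshold below the floor of the angle's oscillation the gate
#' value never changes after the first cycle ("tonic" regime: the
#' conductance remains permanently at one value, e.g. gamma_thr = 83 deg
#' under the default search rhythm).  With the threshold inside the
#' oscillation band the gate switches at least once per cycle ("switching"
#' regime, e.g. gamma_thr = 145 deg).
#'
#' @param angle Numeric vector: the angle time series (deg).
#' @param time Matching time grid, ms.
#' @param thr Threshold, deg.
#' @param polarity Gate polarity, see \code{\link{gate_conductance}}.
#' @return "tonic" or "switching".
#' @export
gating_regime <- function(angle, time, thr, polarity = 1) {
  stopifnot(length(angle) == length(time), length(angle) > 2)
  gate <- gate_conductance(angle, thr, 1, 0, polarity)
  cyc <- extract_cycles(angle, time)
  if (length(cyc) == 0) {
    # no oscillation: the gate is necessarily constant
    return("tonic")
  }
  if (length(cyc) < 3)
    stop("trace too short: need at least 3 oscillation cycles, got ",
         length(cyc))
  t_first <- cyc[[1]]$t_end
  idx <- which(time > t_first)
  changes <- sum(diff(gate[idx]) != 0)
  if (changes == 0) "tonic" else "switching"
}
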