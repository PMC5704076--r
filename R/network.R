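#' @useDynLib sticksearch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical unit ordering used throughout the package and the C++ engine
unit_labels <- function() {
  c("C3", "C4", "C5", "C6",
    paste0("IN", 7:18),
    "MN(LF)", "MN(LS)", "MN(DF)", "MN(DS)",
    "MN(EF)", "MN(ES)", "MN(FF)", "MN(FS)")
}

mn_labels <- function() unit_labels()[17:24]

# multiplier classes for the reactivation schedule:
# fast_LD = fast levator/depressor, slow = all slow MNs, fast_EF = fast
# extensor/flexor
mn_classes <- function() {
  c("MN(LF)" = "fast_LD", "MN(LS)" = "slow",
    "MN(DF)" = "fast_LD", "MN(DS)" = "slow",
    "MN(EF)" = "fast_EF", "MN(ES)" = "slow",
    "MN(FF)" = "fast_EF", "MN(FS)" = "slow")
}

#' Reference wiring of the two local networks
#'
#' The fixed synaptic topology of the model: the two half-centre CPG pairs
#' (C3-C4 for the levator-depressor system, C5-C6 for the extensor-flexor
#' system), the eight premotor interneurons relaying each CPG cell to the
#' antagonist's motoneurons, the eight motoneurons, and the four gating
#' interneurons (IN11, IN12, IN17, IN18) acting directly on the CPG cells.
#' IN12 carries the gamma-signal conductance \code{g_gamma} and IN18 the
#' beta-signal conductance \code{g_beta}.
#'
#' Each CPG cell excites the premotor interneurons that inhibit the
#' motoneurons of its \emph{antagonist}: C3 (levator cell) silences the
#' depressor MNs through IN9/IN10 while the levator MNs are released, and
#' conversely for C4 through IN7/IN8; the extensor-flexor side is analogous
#' with C5/C6 and IN13-IN16.
#'
#' @param config A \code{leg_config}; conductance magnitudes are taken from
#'   its \code{network} section.
#' @return A data.frame with columns \code{source}, \code{target},
#'   \code{sign} ("excitatory"/"inhibitory") and \code{conductance}.
#' @export
wiring_table <- function(config = default_leg_config()) {
  n <- config$network
  syn <- function(source, target, sign, conductance)
    data.frame(source = source, target = target, sign = sign,
               conductance = conductance, stringsAsFactors = FALSE)
  rbind(
    # half-centre mutual inhibition
    syn("C3", "C4", "inhibitory", n$w_c34),
    syn("C4", "C3", "inhibitory", n$w_c43),
    syn("C5", "C6", "inhibitory", n$w_c56),
    syn("C6", "C5", "inhibitory", n$w_c65),
    # CPG -> premotor interneurons (excitatory)
    syn("C4", "IN7",  "excitatory", n$w_cpg_in),
    syn("C4", "IN8",  "excitatory", n$w_cpg_in),
    syn("C3", "IN9",  "excitatory", n$w_cpg_in),
    syn("C3", "IN10", "excitatory", n$w_cpg_in),
    syn("C6", "IN13", "excitatory", n$w_cpg_in),
    syn("C6", "IN14", "excitatory", n$w_cpg_in),
    syn("C5", "IN15", "excitatory", n$w_cpg_in),
    syn("C5", "IN16", "excitatory", n$w_cpg_in),
    # premotor interneurons -> motoneurons (inhibitory)
    syn("IN7",  "MN(LF)", "inhibitory", n$w_in_mn),
    syn("IN8",  "MN(LS)", "inhibitory", n$w_in_mn),
    syn("IN9",  "MN(DF)", "inhibitory", n$w_in_mn),
    syn("IN10", "MN(DS)", "inhibitory", n$w_in_mn),
    syn("IN13", "MN(EF)", "inhibitory", n$w_in_mn),
    syn("IN14", "MN(ES)", "inhibitory", n$w_in_mn),
    syn("IN15", "MN(FF)", "inhibitory", n$w_in_mn),
    syn("IN16", "MN(FS)", "inhibitory", n$w_in_mn),
    # gating interneurons -> CPG cells (inhibitory)
    syn("IN11", "C4", "inhibitory", n$w_gate_cpg),
    syn("IN12", "C3", "inhibitory", n$w_gate_cpg),
    syn("IN17", "C5", "inhibitory", n$w_gate_cpg),
    syn("IN18", "C6", "inhibitory", n$w_gate_cpg)
  )
}

#' Build the neuronal network model
#'
#' Assembles the full network: 2 CPG half-centre pairs (4 cells), 12
#' interneurons (IN7-IN18), 8 motoneurons, the central drives, and the
#' synaptic wiring (see \code{\link{wiring_table}}).  The returned object is
#' consumed by the simulation engine and can be audited against the fixed
#' topology.
#'
#' @param config A \code{leg_config}.
#' @return An object of class \code{leg_network} with elements
#'   \code{units} (data.frame: label, type), \code{synapses} (data.frame),
#'   \code{drives} (named list), and \code{gating_inputs} (the sensory
#'   conductance slots on IN12 and IN18).
#' @examples
#' net <- build_network(leg_config())
#' table(net$units$type)
#' @export
build_network <- function(config = default_leg_config()) {
  validate_config(config)
  n <- config$network
  labels <- unit_labels()
  units <- data.frame(
    label = labels,
    type = c(rep("cpg", 4), rep("interneuron", 12), rep("motoneuron", 8)),
    stringsAsFactors = FALSE)

  synapses <- wiring_table(config)
  if (!is.null(n$extra_synapses)) {
    ex <- n$extra_synapses
    need <- c("source", "target", "sign", "conductance")
    if (!all(need %in% names(ex)))
      stop("extra_synapses needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(unique(c(ex$source, ex$target)), labels)
    if (length(bad))
      stop("unknown unit label(s) in configuration: ",
           paste(bad, collapse = ", "))
    if (!all(ex$sign %in% c("excitatory", "inhibitory")))
      stop("synapse sign must be 'excitatory' or 'inhibitory'")
    synapses <- rbind(synapses, ex[, need])
  }
  if (any(synapses$conductance < 0))
    stop("synaptic conductances must be non-negative")

  drives <- list(
    g_mn = n$g_mn,
    g_app = c(C3 = n$g_app3, C4 = n$g_app4, C5 = n$g_app5, C6 = n$g_app6),
    g_d = c(IN7 = n$g_d7, IN8 = n$g_d8, IN9 = n$g_d9, IN10 = n$g_d10,
            IN13 = n$g_d13, IN14 = n$g_d14, IN15 = n$g_d15, IN16 = n$g_d16))

  model <- list(
    units = units,
    synapses = synapses,
    drives = drives,
    gating_inputs = list(
      g_gamma = list(target = "IN12", sign = "inhibitory",
                     scale = n$w_sens_gamma),
      g_beta = list(target = "IN18", sign = "excitatory",
                    scale = n$w_sens_beta)),
    config = config)
  class(model) <- c("leg_network", "list")
  model
}

#' @export
print.leg_network <- function(x, ...) {
  cat("<leg_network>: ", nrow(x$units), "units (",
      sum(x$units$type == "cpg"), "CPG cells,",
      sum(x$units$type == "interneuron"), "INs,",
      sum(x$units$type == "motoneuron"), "MNs ),",
      nrow(x$synapses), "synapses\n")
  invisible(x)
}

# --- internal: network state/derivative in plain R ---------------------------
# Reference implementation of the same equations the C++ engine integrates
# (network half only, gates and multipliers supplied externally).  Used by
# step_units() and as a cross-check in the tests.

network_drive_vector <- function(model) {
  n <- model$config$network
  d <- numeric(24)
  d[1:4] <- model$drives$g_app
  d[5:8] <- -model$drives$g_d[1:4]       # IN7..IN10
  d[9] <- n$bias_in11
  d[10] <- n$bias_in12
  d[11:14] <- -model$drives$g_d[5:8]     # IN13..IN16
  d[15] <- n$bias_in17
  d[16] <- n$bias_in18
  d
}

network_weight_arrays <- function(model) {
  labels <- unit_labels()
  src <- match(model$synapses$source, labels) - 1L
  dst <- match(model$synapses$target, labels) - 1L
  w <- model$synapses$conductance *
    ifelse(model$synapses$sign == "inhibitory", -1, 1)
  list(src = src, dst = dst, w = w)
}

#' Unit outputs from a network state
#'
#' @param model A \code{leg_network}.
#' @param state Network state vector as used by \code{\link{step_units}}.
#' @return Named numeric vector of the 24 unit outputs, each in [0, 1].
#' @export
unit_outputs <- function(model, state) {
  n <- model$config$network
  sig <- function(x) 1 / (1 + exp(-x))
  v <- state[seq(1, 8, by = 2)]
  out <- c(sig((v - n$theta_cpg) / n$slope_cpg),
           sig((state[9:20] - n$theta_in) / n$slope_in),
           sig((state[21:28] - n$theta_mn) / n$slope_mn))
  names(out) <- unit_labels()
  out
}

network_deriv <- function(model, state, external) {
  n <- model$config$network
  out <- unname(unit_outputs(model, state))
  inp <- network_drive_vector(model)
  wa <- network_weight_arrays(model)
  for (k in seq_along(wa$w))
    inp[wa$dst[k] + 1L] <- inp[wa$dst[k] + 1L] + wa$w[k] * out[wa$src[k] + 1L]
  inp[10] <- inp[10] - n$w_sens_gamma * external$g_gamma  # IN12
  inp[16] <- inp[16] + n$w_sens_beta * external$g_beta    # IN18
  cls <- unname(mn_classes())
  mult <- external$mult[cls]
  inp[17:24] <- inp[17:24] + n$g_mn * mult

  d <- numeric(28)
  v <- state[seq(1, 8, by = 2)]
  a <- state[seq(2, 8, by = 2)]
  d[seq(1, 8, by = 2)] <- (-v + inp[1:4] - unname(n$b) * a) / n$tau_v
  d[seq(2, 8, by = 2)] <- (-a + out[1:4]) / unname(n$tau_a)
  d[9:20] <- (-state[9:20] + inp[5:16]) / n$tau_in
  d[21:28] <- (-state[21:28] + inp[17:24]) / n$tau_mn
  d
}

#' Advance the network state by one integration step
#'
#' Pure-R reference integrator for the neuronal half of the model (classic
#' fixed-step 4th-order scheme), with the sensory gate conductances and
#' motoneuron drive multipliers supplied as external inputs.  Intended for
#' inspection and verification at small problem sizes; full simulations use
#' the compiled engine.
#'
#' @param model A \code{leg_network}.
#' @param state Numeric state vector of length 28: (v, a) pairs for
#'   C3, C4, C5, C6, then first-order states for IN7..IN18 and the eight
#'   motoneurons.  \code{\link{network_initial_state}} provides the standard
#'   initial condition.
#' @param external List with \code{g_beta}, \code{g_gamma} (gate conductance
#'   values) and \code{mult} (named multipliers for classes
#'   \code{fast_LD}, \code{slow}, \code{fast_EF}).
#' @param dt Time step in ms, in (0, 1].
#' @return The updated state vector.
#' @export
step_units <- function(model, state, external = list(), dt = 0.1) {
  stopifnot(inherits(model, "leg_network"))
  if (!(dt > 0 && dt <= 1)) stop("dt must be in (0, 1] ms")
  if (length(state) != 28 || any(!is.finite(state))) {
    bad <- which(!is.finite(state))
    stop("non-finite network state",
         if (length(bad)) paste0(" at index ", bad[1]) else "")
  }
  ext <- list(g_beta = 0, g_gamma = 0,
              mult = c(fast_LD = 1, slow = 1, fast_EF = 1))
  ext[names(external)] <- external
  k1 <- network_deriv(model, state, ext)
  k2 <- network_deriv(model, state + dt / 2 * k1, ext)
  k3 <- network_deriv(model, state + dt / 2 * k2, ext)
  k4 <- network_deriv(model, state + dt * k3, ext)
  out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))[1]
    stop("integration produced a non-finite state (index ", bad, ")")
  }
  out
}

#' Standard initial network state
#'
#' All states start at the quiescent point (zero), with a fixed small
#' offset added to the fast variable of C3 so the half-centres leave the
#' symmetric state deterministically.  No random numbers are used anywhere
#' in the core model.
#'
#' @param config A \code{leg_config}.
#' @return Numeric vector of length 28.
#' @export
network_initial_state <- function(config = default_leg_config()) {
  s <- numeric(28)
  s[1] <- config$init$c3_offset
  s
}

#' Integrate the network (reference implementation)
#'
#' Repeatedly applies \code{\link{step_units}}; returns unit outputs on a
#' stored time grid.  Quadratic-time R loop, intended for short validation
#' runs only.
#'
#' @inheritParams step_units
#' @param duration Total time, ms.
#' @param store_every Storage interval, ms.
#' @return A list with \code{time} and \code{outputs} (matrix, one column
#'   per unit).
#' @export
network_integrate <- function(model, duration, dt = 0.5,
                              external = list(), store_every = 5,
                              state = network_initial_state(model$config)) {
  n_steps <- round(duration / dt)
  stride <- max(1L, round(store_every / dt))
  keep <- seq(0L, n_steps, by = stride)
  outs <- matrix(NA_real_, nrow = length(keep), ncol = 24,
                 dimnames = list(NULL, unit_labels()))
  tgrid <- keep * dt
  row <- 1L
  for (step in 0:n_steps) {
    if (step %% stride == 0L) {
      outs[row, ] <- unit_outputs(model, state)
      row <- row + 1L
    }
    if (step < n_steps) state <- step_units(model, state, external, dt)
  }
  list(time = tgrid, outputs = outs)
}

#' Effective motoneuron drive under per-class overrides
#'
#' The uniform central motoneuron drive \code{g_mn} scaled by drive
#' multipliers in [0, 1] per motoneuron class.  Multiplier 0 silences the
#' class (the obstacle-contact condition); multiplier 1 reproduces nominal
#' drive.
#'
#' @param model A \code{leg_network}.
#' @param overrides Named numeric vector/list with any of \code{fast_LD},
#'   \code{slow}, \code{fast_EF}; missing classes default to 1.
#' @return Named numeric vector of effective drives, one per motoneuron.
#' @export
motoneuron_drive <- function(model, overrides = NULL) {
  stopifnot(inherits(model, "leg_network"))
  mult <- c(fast_LD = 1, slow = 1, fast_EF = 1)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(mult))
    if (length(bad))
      stop("unknown motoneuron class(es): ", paste(bad, collapse = ", "))
    if (any(overrides < 0 | overrides > 1))
      stop("drive multipliers must lie in [0, 1]")
    mult[names(overrides)] <- overrides
  }
  cls <- mn_classes()
  stats::setNames(model$drives$g_mn * unname(mult[cls]), names(cls))
}
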