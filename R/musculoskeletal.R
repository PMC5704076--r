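#' Construct a muscle pool
#'
#' A muscle pool is one fast or slow muscle group of an antagonistic pair,
#' with first-order activation dynamics, a recruitment fraction capping its
#' activation, an active gain pulling the joint towards the pool's fully
#' contracted angle, and a weak passive stiffness pulling towards its rest
#' angle (the residual rigidity that holds posture when the motoneurons
#' fall silent).
#'
#' @param role One of "levator", "depressor", "extensor", "flexor".
#' @param speed "fast" or "slow".
#' @param n_units Number of motoneuron/fibre units in the pool.  The
#'   extensor pools have a single unit each (one slow and one fast extensor
#'   motoneuron), so no recruitment gradation is possible there; the fast
#'   levator and depressor pools have several units.
#' @param active_fraction Recruited fraction of the pool, in [0, 1].
#' @param activation Current activation, in [0, 1].
#' @param gain Active torque gain (deg/ms per unit activation per deg of
#'   angle deficit).
#' @param tau_on,tau_off Activation/deactivation time constants, ms.
#'   Deactivation is faster than activation, so that silencing the drive
#'   leaves posture to the passive rigidity almost immediately.
#' @param theta_contract Joint angle (deg) the fully active pool pulls
#'   towards.
#' @param passive_stiffness Passive stiffness gain (deg/ms per deg).
#' @param theta_rest Passive rest angle, deg.
#' @return An object of class \code{muscle_pool}.
#' @export
muscle_pool <- function(role = c("levator", "depressor", "extensor", "flexor"),
                        speed = c("fast", "slow"),
                        n_units = 1, active_fraction = 1, activation = 0,
                        gain = 0.004, tau_on = 25, tau_off = 3,
                        theta_contract = 0, passive_stiffness = 1e-4,
                        theta_rest = 0) {
  role <- match.arg(role)
  speed <- match.arg(speed)
  if (role == "extensor" && n_units != 1)
    stop("extensor pools have a single motoneuron (n_units = 1)")
  stopifnot(n_units >= 1, active_fraction >= 0, active_fraction <= 1,
            activation >= 0, activation <= 1, gain >= 0,
            passive_stiffness >= 0, tau_on > 0, tau_off > 0)
  p <- list(role = role, speed = speed, n_units = as.integer(n_units),
            active_fraction = active_fraction, activation = activation,
            gain = gain, tau_on = tau_on, tau_off = tau_off,
            theta_contract = theta_contract,
            passive_stiffness = passive_stiffness, theta_rest = theta_rest)
  class(p) <- c("muscle_pool", "list")
  p
}

joint_of <- function(pool) {
  if (pool$role %in% c("levator", "depressor")) "CTr" else "FTi"
}

#' Advance a muscle pool by one time step
#'
#' Activation relaxes towards \code{mn_output * active_fraction} with the
#' pool's activation time constant (the faster deactivation constant is
#' used when the target is below the current activation).  Activation stays
#' in [0, 1] and can never exceed the recruited fraction in steady state.
#'
#' @param pool A \code{muscle_pool}.
#' @param mn_output Motoneuron output in [0, 1].
#' @param dt Time step, ms.
#' @return The updated pool.
#' @export
muscle_step <- function(pool, mn_output, dt) {
  stopifnot(inherits(pool, "muscle_pool"),
            mn_output >= 0, mn_output <= 1, dt > 0)
  target <- mn_output * pool$active_fraction
  tau <- if (target > pool$activation) pool$tau_on else pool$tau_off
  a <- pool$activation + dt * (target - pool$activation) / tau
  pool$activation <- min(1, max(0, a))
  pool
}

#' Net torque of an antagonistic muscle pair
#'
#' Active contributions pull the joint towards each pool's contracted
#' angle in proportion to its activation; passive stiffness pulls towards
#' each pool's rest angle regardless of activation.  With both activations
#' zero the torque vanishes exactly at the passive equilibrium and is
#' restoring (opposite in sign to the displacement) elsewhere.
#'
#' @param agonist,antagonist \code{muscle_pool}s acting on the same joint.
#' @param angle Current joint angle, deg.
#' @return Net angular rate contribution (deg/ms).
#' @export
joint_torque <- function(agonist, antagonist, angle) {
  stopifnot(inherits(agonist, "muscle_pool"),
            inherits(antagonist, "muscle_pool"))
  if (joint_of(agonist) != joint_of(antagonist))
    stop("pools act on different joints (",
         joint_of(agonist), " vs ", joint_of(antagonist), ")")
  act <- function(p) p$gain * p$activation * (p$theta_contract - angle)
  pas <- function(p) p$passive_stiffness * (p$theta_rest - angle)
  act(agonist) + act(antagonist) + pas(agonist) + pas(antagonist)
}

#' Advance the joint angles by one time step
#'
#' Overdamped first-order joint dynamics: angle rates are proportional to
#' the net torques (no inertia, no gravity).  The FTi angle gamma is
#' clamped to (0, 180] with zero rate at the stretched stop.
#'
#' @param state List/vector with \code{beta} and \code{gamma} (deg).
#' @param torque_ctr,torque_fti Net torques (deg/ms) on the CTr and FTi
#'   joints.
#' @param dt Time step in ms, in (0, 1].
#' @return Updated state list with \code{beta}, \code{gamma}.
#' @export
joint_step <- function(state, torque_ctr, torque_fti, dt) {
  if (!(dt > 0 && dt <= 1)) stop("dt must be in (0, 1] ms")
  beta <- state$beta + dt * torque_ctr
  gamma <- state$gamma + dt * torque_fti
  gamma <- min(180, max(0.5, gamma))
  list(beta = beta, gamma = gamma)
}

#' Tarsus elevation angle from the joint angles
#'
#' Computes alpha, the angle from horizontal of the line connecting the
#' CTr pivot to the tarsus (leg tip).  The femur is elevated by beta above
#' horizontal and the tibia deviates downward from the femur line by
#' (180 - gamma) degrees, so that gamma = 180 is a fully stretched leg and
#' smaller gamma flexes the tibia below the femur.  alpha is a derived
#' quantity: it is always recomputed from beta, gamma and the segment
#' lengths, never integrated independently.
#'
#' @param beta Femur elevation angle, deg (vectorised).
#' @param gamma Interior femur-tibia angle, deg, in (0, 180] (vectorised).
#' @param geometry List with \code{femur_length} and \code{tibia_length}
#'   (both > 0).
#' @return alpha in degrees.
#' @examples
#' compute_alpha(0, 90, list(femur_length = 1, tibia_length = 1))  # -45
#' compute_alpha(12, 180, list(femur_length = 10, tibia_length = 8))  # 12
#' @export
compute_alpha <- function(beta, gamma,
                          geometry = default_leg_config()$geometry) {
  if (any(gamma <= 0 | gamma > 180))
    stop("gamma must lie in (0, 180] degrees")
  lf <- geometry$femur_length
  lt <- geometry$tibia_length
  if (lf <= 0 || lt < 0) stop("segment lengths must be positive")
  dir <- (beta - (180 - gamma)) * pi / 180
  b <- beta * pi / 180
  x <- lf * cos(b) + lt * cos(dir)
  y <- lf * sin(b) + lt * sin(dir)
  atan2(y, x) * 180 / pi
}
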