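trace_columns <- function() {
  c("time_ms", "beta_deg", "gamma_deg", "alpha_deg", "g_beta", "g_gamma",
    "C3", "C4", "C5", "C6", paste0("IN", 7:18),
    "MN_LF", "MN_LS", "MN_DF", "MN_DS", "MN_EF", "MN_ES", "MN_FF", "MN_FS",
    "mult_slow", "mult_fast_ef", "mult_fast_ld",
    "af_levator", "af_depressor")
}

# assemble the parameter list consumed by the compiled engine
engine_pars <- function(config, duration, po = NA_real_, arm_time = 0,
                        dur_lev = 1, dur_dep = 1,
                        mult_free = c(fast_LD = 1, slow = 1, fast_EF = 1),
                        mult_step_time = rep(NA_real_, 3),
                        mult_step_value = rep(1, 3),
                        gate_mode = c(beta = 0L, gamma = 0L),
                        gate_fix = c(beta = 0, gamma = 0),
                        gate_sq_period = 1000,
                        init_state = numeric(0),
                        dt = NULL) {
  model <- build_network(config)
  wa <- network_weight_arrays(model)
  n <- config$network
  list(
    network = list(
      tau_v = n$tau_v, tau_a = n$tau_a,
      theta_cpg = n$theta_cpg, slope_cpg = n$slope_cpg,
      tau_in = n$tau_in, theta_in = n$theta_in, slope_in = n$slope_in,
      tau_mn = n$tau_mn, theta_mn = n$theta_mn, slope_mn = n$slope_mn,
      b = unname(n$b), g_mn = n$g_mn,
      syn_src = as.integer(wa$src), syn_dst = as.integer(wa$dst),
      syn_w = as.numeric(wa$w),
      drive = network_drive_vector(model),
      w_sens_beta = n$w_sens_beta, w_sens_gamma = -n$w_sens_gamma,
      mn_class = c(0L, 1L, 0L, 1L, 2L, 1L, 2L, 1L)),
    muscle = config$muscle,
    geometry = config$geometry,
    gating = list(
      beta_thr = config$gating$beta_thr, gamma_thr = config$gating$gamma_thr,
      g_beta_high = config$gating$g_beta_high,
      g_beta_low = config$gating$g_beta_low,
      g_gamma_high = config$gating$g_gamma_high,
      g_gamma_low = config$gating$g_gamma_low,
      polarity_beta = as.integer(config$gating$polarity_beta),
      polarity_gamma = as.integer(config$gating$polarity_gamma),
      gate_mode_beta = as.integer(gate_mode[["beta"]]),
      gate_mode_gamma = as.integer(gate_mode[["gamma"]]),
      gate_fix_beta = gate_fix[["beta"]], gate_fix_gamma = gate_fix[["gamma"]],
      gate_sq_period = gate_sq_period),
    integration = list(
      dt = if (is.null(dt)) config$integration$dt else dt,
      store_every = config$integration$store_every,
      duration = duration),
    init = list(beta0 = config$init$beta0, gamma0 = config$init$gamma0,
                c3_offset = config$init$c3_offset, state = init_state),
    protocol = list(
      po = po, arm_time = arm_time,
      contact_duration = config$protocol$contact_duration,
      slow_ramp = config$protocol$slow_ramp,
      fast_ef_delay = config$protocol$fast_ef_delay,
      dur_lev = dur_lev, dur_dep = dur_dep,
      quantized = as.integer(isTRUE(config$protocol$quantized_recruitment)),
      n_units_lev = as.integer(config$muscle$n_units[1]),
      n_units_dep = as.integer(config$muscle$n_units[3]),
      mult_free = as.numeric(mult_free[c("fast_LD", "slow", "fast_EF")]),
      mult_step_time = as.numeric(mult_step_time),
      mult_step_value = as.numeric(mult_step_value))
  )
}

as_leg_trace <- function(res, config, events = list()) {
  tr <- as.data.frame(res$trace)
  names(tr) <- trace_columns()
  attr(tr, "config") <- config
  attr(tr, "preset") <- config$preset
  attr(tr, "config_hash") <- config_hash(config)
  attr(tr, "events") <- events
  attr(tr, "final_state") <- res$final_state
  class(tr) <- c("leg_trace", "data.frame")
  tr
}

#' Simulate the unperturbed search rhythm
#'
#' Integrates the full model (network, muscles, joints, threshold gates)
#' with no obstacle, from the standard deterministic initial condition.
#'
#' @param config A \code{leg_config}.
#' @param duration Simulated time, ms.
#' @param mult Optional constant motoneuron drive multipliers, named by
#'   class (\code{fast_LD}, \code{slow}, \code{fast_EF}), each in [0, 1].
#' @param mult_step Optional list \code{list(class =, time =, value =)}
#'   applying a stepped multiplier change at a given time.
#' @param init_state Optional full 38-element engine state to start from
#'   (as stored in the \code{final_state} attribute of a previous trace).
#' @param dt Integration step override, ms.
#' @param gate_override Optional list to decouple a gate from the angle:
#'   \code{list(gamma = list(mode = "fixed", value = 1))} or
#'   \code{list(gamma = list(mode = "square", period = 1000))}.
#' @return A \code{leg_trace}: data frame of the sampled time course
#'   (angles, gate values, unit outputs, drive multipliers, recruitment
#'   fractions) with the configuration and events as attributes.
#' @examples
#' \donttest{
#' tr <- run_search(leg_config(), duration = 4000)
#' range(tr$gamma_deg)
#' }
#' @export
run_search <- function(config = default_leg_config(), duration = 10000,
                       mult = NULL, mult_step = NULL, init_state = numeric(0),
                       dt = NULL, gate_override = NULL) {
  validate_config(config)
  mult_free <- c(fast_LD = 1, slow = 1, fast_EF = 1)
  if (!is.null(mult)) {
    mult <- unlist(mult)
    bad <- setdiff(names(mult), names(mult_free))
    if (length(bad)) stop("unknown multiplier class: ", paste(bad, collapse = ", "))
    if (any(mult < 0 | mult > 1)) stop("multipliers must lie in [0, 1]")
    mult_free[names(mult)] <- mult
  }
  step_time <- rep(NA_real_, 3)
  step_value <- rep(1, 3)
  if (!is.null(mult_step)) {
    cls <- match(mult_step$class, c("fast_LD", "slow", "fast_EF"))
    if (is.na(cls)) stop("unknown multiplier class: ", mult_step$class)
    step_time[cls] <- mult_step$time
    step_value[cls] <- mult_step$value
  }
  gate_mode <- c(beta = 0L, gamma = 0L)
  gate_fix <- c(beta = 0, gamma = 0)
  gate_sq <- 1000
  for (gname in names(gate_override)) {
    ov <- gate_override[[gname]]
    if (ov$mode == "fixed") {
      gate_mode[[gname]] <- 1L
      gate_fix[[gname]] <- ov$value
    } else if (ov$mode == "square") {
      gate_mode[[gname]] <- 2L
      gate_sq <- ov$period
    } else stop("unknown gate override mode: ", ov$mode)
  }
  pars <- engine_pars(config, duration, mult_free = mult_free,
                      mult_step_time = step_time, mult_step_value = step_value,
                      gate_mode = gate_mode, gate_fix = gate_fix,
                      gate_sq_period = gate_sq,
                      init_state = init_state, dt = dt)
  res <- simulate_leg_cpp(pars)
  as_leg_trace(res, config)
}

#' @export
print.leg_trace <- function(x, ...) {
  ev <- attr(x, "events")
  cat("<leg_trace> ", nrow(x), " samples over ",
      round(max(x$time_ms) / 1000, 2), " s (preset ",
      attr(x, "preset"), ")\n", sep = "")
  cat("  beta  [", round(min(x$beta_deg), 1), ",",
      round(max(x$beta_deg), 1), "] deg\n")
  cat("  gamma [", round(min(x$gamma_deg), 1), ",",
      round(max(x$gamma_deg), 1), "] deg\n")
  cat("  alpha [", round(min(x$alpha_deg), 1), ",",
      round(max(x$alpha_deg), 1), "] deg\n")
  if (length(ev)) {
    fmt <- vapply(ev, function(v)
      if (is.numeric(v)) format(round(v, 1)) else as.character(v),
      character(1))
    cat("  events:", paste(names(fmt), "=", fmt, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.leg_trace <- function(object, transient = 2000, ...) {
  st <- oscillation_stats(object, transient = transient)
  print(object)
  cat("  post-transient ranges (transient =", transient, "ms):\n")
  for (a in c("alpha", "beta", "gamma"))
    cat(sprintf("    %-5s [%6.1f, %6.1f] deg\n", a,
                st$ranges[[a]][1], st$ranges[[a]][2]))
  if (is.finite(st$period))
    cat("  period:", round(st$period), "ms\n")
  invisible(st)
}
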