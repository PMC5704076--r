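#' Default model configuration
#'
#' Returns the full nested configuration of the one-leg search-movement
#' model: network drives and synaptic strengths, gating thresholds and
#' conductance pairs, muscle and geometry parameters, the obstacle protocol
#' (recruitment ramps, reactivation schedule) and analysis settings.  All
#' time constants are in ms, angles in degrees, conductances and forces in
#' relative (dimensionless) units.
#'
#' The defaults are the frozen calibration of the package: with the
#' canonical threshold preset \code{gamma_thr = 145}, \code{beta_thr = 16}
#' they produce an autonomous search rhythm with beta in approximately
#' [-5, 30] degrees and gamma in approximately [85, 170] degrees.
#'
#' @return A nested list of class \code{leg_config}.
#' @export
default_leg_config <- function() {
  cfg <- list(
    preset = "g145_b16",
    integration = list(
      dt = 0.1,           # RK4 step, ms
      store_every = 5     # trace sampling interval, ms
    ),
    geometry = list(
      femur_length = 10,  # mm
      tibia_length = 10   # mm
    ),
    network = list(
      # CPG cells: fast activity variable v with slow recovery variable a
      tau_v = 40,
      tau_a = c(C3 = 600, C4 = 600, C5 = 600, C6 = 950),
      b = c(C3 = 2.5, C4 = 2.5, C5 = 2.0, C6 = 5.0),
      theta_cpg = 1.0, slope_cpg = 0.1,
      # central drives
      g_app3 = 3.0, g_app4 = 3.0, g_app5 = 3.5, g_app6 = 2.6,
      g_d7 = 0, g_d8 = 0, g_d9 = 0, g_d10 = 0,
      g_d13 = 0, g_d14 = 0, g_d15 = 0, g_d16 = 0,
      g_mn = 6,
      # synaptic strengths (all >= 0; signs fixed by the wiring)
      w_c34 = 1.6, w_c43 = 1.4,   # LD half-centre mutual inhibition
      w_c56 = 1.1, w_c65 = 2.0,   # EF half-centre mutual inhibition
      w_cpg_in = 6,               # CPG -> premotor IN excitation
      w_in_mn = 6,                # premotor IN -> MN inhibition
      w_gate_cpg = 1.8,             # IN11/12/17/18 -> CPG inhibition
      bias_in11 = 0, bias_in12 = 4, bias_in17 = 0, bias_in18 = 0,
      w_sens_beta = 8,            # beta signal -> IN18 (excitatory)
      w_sens_gamma = 8,           # gamma signal -> IN12 (inhibitory)
      # first-order units
      tau_in = 10, theta_in = 3, slope_in = 0.25,
      tau_mn = 5, theta_mn = 4, slope_mn = 0.5,
      extra_synapses = NULL
    ),
    gating = list(
      gamma_thr = 145, beta_thr = 16,
      g_beta_high = 1, g_beta_low = 0,
      g_gamma_high = 1, g_gamma_low = 0,
      # +1: conductance takes its high value when the angle >= threshold
      polarity_beta = 1, polarity_gamma = 1
    ),
    muscle = list(
      # pool order: lev fast, lev slow, dep fast, dep slow,
      #             ext fast, ext slow, flx fast, flx slow
      q = c(0.006, 5e-04, 0.004, 5e-04, 0.0045, 3e-04, 0.018, 3e-04),
      tau_on = c(25, 120, 25, 120, 25, 120, 25, 120),
      tau_off = c(3, 3, 3, 3, 3, 3, 3, 3),
      theta_c = c(33, 33, -14, -14, 172, 172, 84, 84),
      k_pass = rep(1e-04, 8),
      theta_rest = c(10, 10, 10, 10, 130, 130, 130, 130),
      n_units = c(5, 1, 5, 1, 1, 1, 1, 1)
    ),
    protocol = list(
      contact_duration = 100,  # ms, obstacle contact epoch (< 100 ms bound)
      slow_ramp = 200,         # ms, slow-MN reactivation ramp
      fast_ef_delay = 0,       # ms, fast extensor/flexor reactivation delay
      base_duration = 4000,    # ms, fast lev/dep full recruitment at rf = 1
      quantized_recruitment = FALSE,
      ramps = list(
        # figure-derived placeholder endpoints; overridable
        A = list(
          levator   = list(rf0 = 1, po0 = -40, rf1 = 3, po1 = 25),
          depressor = list(rf0 = 3, po0 = -40, rf1 = 1, po1 = 25)
        ),
        B = list(
          levator   = list(rf0 = 1, po0 = -40, rf1 = 2, po1 = 25),
          depressor = list(rf0 = 2, po0 = -40, rf1 = 1, po1 = 25)
        )
      )
    ),
    analysis = list(
      cessation_floor = 2,      # deg
      cessation_min_dur = 500,  # ms
      rdp_tol = 0.05,           # fraction of loop bounding-box diagonal
      smooth_frac = 0.05,       # peak-detection smoothing, fraction of period
      alternation_min_pairs = 4,
      alternation_rel_diff = 0.1
    ),
    init = list(beta0 = 10, gamma0 = 130, c3_offset = 0.05)
  )
  class(cfg) <- c("leg_config", "list")
  cfg
}

#' Canonical threshold presets
#'
#' The six canonical (gamma_thr, beta_thr) pairs used throughout the
#' simulations: gamma_thr in \{83, 145\} degrees crossed with beta_thr in
#' \{-4, 4, 16\} degrees.
#'
#' @return A data.frame with columns \code{name}, \code{gamma_thr},
#'   \code{beta_thr}.
#' @export
canonical_presets <- function() {
  g <- c(83, 145)
  b <- c(-4, 4, 16)
  grid <- expand.grid(beta_thr = b, gamma_thr = g)[, 2:1]
  grid$name <- sprintf("g%d_b%d", grid$gamma_thr, grid$beta_thr)
  grid[, c("name", "gamma_thr", "beta_thr")]
}

#' Build a model configuration
#'
#' Starts from \code{\link{default_leg_config}} and applies a named preset
#' and/or explicit overrides.  Unknown keys are rejected.
#'
#' @param preset Name of a canonical preset (see
#'   \code{\link{canonical_presets}}), or \code{NULL} to keep the default.
#' @param ... Named overrides as nested lists, e.g.
#'   \code{gating = list(beta_thr = 4)}.
#' @return A \code{leg_config} object.
#' @examples
#' cfg <- leg_config(preset = "g83_b4")
#' cfg$gating$gamma_thr
#' @export
leg_config <- function(preset = NULL, ...) {
  cfg <- default_leg_config()
  if (!is.null(preset)) {
    pr <- canonical_presets()
    i <- match(preset, pr$name)
    if (is.na(i))
      stop("unknown preset '", preset, "'; available: ",
           paste(pr$name, collapse = ", "))
    cfg$preset <- preset
    cfg$gating$gamma_thr <- pr$gamma_thr[i]
    cfg$gating$beta_thr <- pr$beta_thr[i]
  }
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  validate_config(cfg)
  cfg
}

# recursive merge rejecting keys absent from the template
merge_config <- function(cfg, over, path = character()) {
  if (is.null(names(over)) || any(names(over) == ""))
    stop("configuration overrides must be fully named (at ",
         paste(path, collapse = "$"), ")")
  for (k in names(over)) {
    here <- paste(c(path, k), collapse = "$")
    if (!k %in% names(cfg))
      stop("unknown configuration key: ", here)
    if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]])) && is.list(over[[k]])) {
      cfg[[k]] <- merge_config(cfg[[k]], over[[k]], c(path, k))
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  tmpl <- default_leg_config()
  extra <- setdiff(names(cfg), names(tmpl))
  if (length(extra))
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  with(cfg$integration, {
    if (!(dt > 0 && dt <= 1)) stop("integration dt must be in (0, 1] ms")
  })
  g <- cfg$gating
  if (g$g_beta_high < g$g_beta_low || g$g_gamma_high < g$g_gamma_low)
    stop("gate high conductance must be >= low conductance")
  if (any(unlist(g[c("g_beta_high", "g_beta_low",
                     "g_gamma_high", "g_gamma_low")]) < 0))
    stop("gate conductances must be non-negative")
  drv <- cfg$network[c("g_app3", "g_app4", "g_app5", "g_app6",
                       "g_d7", "g_d8", "g_d9", "g_d10",
                       "g_d13", "g_d14", "g_d15", "g_d16", "g_mn")]
  if (any(unlist(drv) < 0)) stop("central drives must be non-negative")
  m <- cfg$muscle
  if (any(lengths(m[c("q", "tau_on", "tau_off", "theta_c",
                      "k_pass", "theta_rest", "n_units")]) != 8))
    stop("muscle parameter vectors must have length 8")
  if (any(m$q < 0) || any(m$k_pass < 0)) stop("muscle gains must be >= 0")
  if (cfg$geometry$femur_length <= 0 || cfg$geometry$tibia_length <= 0)
    stop("segment lengths must be positive")
  if (cfg$protocol$contact_duration > 100)
    stop("contact_duration must be <= 100 ms")
  invisible(cfg)
}

#' @export
print.leg_config <- function(x, ...) {
  cat("<leg_config>\n")
  cat("  preset:     ", x$preset, "\n")
  cat("  thresholds:  gamma_thr =", x$gating$gamma_thr,
      "deg, beta_thr =", x$gating$beta_thr, "deg\n")
  cat("  integration: dt =", x$integration$dt, "ms, stored every",
      x$integration$store_every, "ms\n")
  cat("  geometry:    femur", x$geometry$femur_length, "mm, tibia",
      x$geometry$tibia_length, "mm\n")
  invisible(x)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML.  Reading validates the structure
#' against the package template, so files with unknown keys are rejected;
#' a round trip through \code{write_config}/\code{read_config} is lossless.
#'
#' @param cfg A \code{leg_config} object.
#' @param path File path.
#' @return \code{read_config} returns a \code{leg_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  x <- unclass(cfg)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- merge_config(default_leg_config(), x)
  # vectors lose names through YAML lists; restore canonical shapes
  for (k in c("b", "tau_a"))
    cfg$network[[k]] <- stats::setNames(as.numeric(unlist(cfg$network[[k]])),
                                        c("C3", "C4", "C5", "C6"))
  for (k in c("q", "tau_on", "tau_off", "theta_c", "k_pass",
              "theta_rest", "n_units"))
    cfg$muscle[[k]] <- as.numeric(unlist(cfg$muscle[[k]]))
  if (!"extra_synapses" %in% names(cfg$network))
    cfg$network["extra_synapses"] <- list(NULL)
  class(cfg) <- c("leg_config", "list")
  validate_config(cfg)
  cfg
}

#' @keywords internal
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 15)),
             collapse = "\n")
  # small deterministic FNV-1a hash; no external digest dependency
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
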