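#' Recruitment slow-down factor at an obstacle position
#'
#' Linear interpolation of the recruitment factor rf between two known
#' endpoints: \deqn{rf = (rf1 - rf0)/(PO1 - PO0) (PO - PO0) + rf0,}
#' floored at 1.  rf is the factor by which the recruitment of the fast
#' levator and depressor muscles is slowed down during the transition
#' period; rf = 1 is the normal recruitment rate, rf = 2 means recruitment
#' proceeds twice as slowly.  Linear extrapolation outside [PO0, PO1] is
#' permitted (still floored at 1).
#'
#' @param po Obstacle position(s) on the alpha axis, deg (vectorised).
#' @param ramp List with \code{rf0}, \code{po0}, \code{rf1}, \code{po1}.
#' @return rf value(s), each >= 1.
#' @examples
#' recruitment_factor(0, list(rf0 = 1, po0 = -40, rf1 = 3, po1 = 25))
#' @export
recruitment_factor <- function(po, ramp) {
  need <- c("rf0", "po0", "rf1", "po1")
  if (!all(need %in% names(ramp)))
    stop("ramp needs components: ", paste(need, collapse = ", "))
  if (ramp$po0 == ramp$po1)
    stop("ramp endpoints must differ (po0 != po1)")
  rf <- (ramp$rf1 - ramp$rf0) / (ramp$po1 - ramp$po0) * (po - ramp$po0) +
    ramp$rf0
  pmax(rf, 1)
}

# interpolation set: B for high beta thresholds, A for low ones
interpolation_set <- function(beta_thr) if (beta_thr > 10) "B" else "A"

ramps_for <- function(config) {
  config$protocol$ramps[[interpolation_set(config$gating$beta_thr)]]
}

#' Reactivation schedule after obstacle removal
#'
#' Drive multipliers and recruitment fractions as a function of the time
#' since obstacle removal: the fast extensor and flexor motoneurons are
#' reactivated immediately (after \code{fast_ef_delay}, default 0); all
#' slow motoneurons ramp to full drive within \code{slow_ramp} ms (default
#' 200); the fast levator and depressor pools are gradually re-recruited,
#' their active fraction ramping linearly over
#' \code{base_duration * rf} ms.  During contact all multipliers are 0.
#'
#' @param t_since_removal Time since removal, ms (>= 0; vectorised).
#' @param schedule List with \code{slow_ramp}, \code{fast_ef_delay},
#'   \code{dur_lev}, \code{dur_dep} (ms).
#' @return A data.frame with columns \code{fast_ef}, \code{slow},
#'   \code{fast_ld} (drive multipliers) and \code{af_levator},
#'   \code{af_depressor} (recruited fractions).
#' @export
staged_reactivation <- function(t_since_removal, schedule) {
  stopifnot(all(t_since_removal >= 0))
  t <- t_since_removal
  data.frame(
    fast_ef = as.numeric(t >= schedule$fast_ef_delay),
    slow = pmin(1, t / schedule$slow_ramp),
    fast_ld = rep(1, length(t)),
    af_levator = pmin(1, t / schedule$dur_lev),
    af_depressor = pmin(1, t / schedule$dur_dep))
}

#' Detect the first obstacle contact in a recorded trace
#'
#' Scans the tarsus angle alpha for its first downward crossing of the
#' obstacle position PO (an obstacle below the tarsus path blocks downward
#' motion only).
#'
#' @param trace A \code{leg_trace} or data.frame with \code{time_ms} and
#'   \code{alpha_deg}.
#' @param po Obstacle position, deg.
#' @param after Ignore crossings before this time, ms.
#' @return Contact time, ms (linearly interpolated between samples).
#' @export
detect_contact <- function(trace, po, after = 0) {
  t <- trace$time_ms
  a <- trace$alpha_deg
  idx <- which(t >= after)
  t <- t[idx]; a <- a[idx]
  cross <- which(a[-length(a)] > po & a[-1] <= po)
  if (!length(cross))
    stop(sprintf(
      "no contact: alpha never crossed PO = %g downward (alpha range [%.1f, %.1f])",
      po, min(a), max(a)))
  i <- cross[1]
  # linear interpolation of the crossing time
  frac <- (a[i] - po) / (a[i] - a[i + 1])
  t[i] + frac * (t[i + 1] - t[i])
}

#' Run the obstacle perturbation/recovery experiment
#'
#' Simulates the full protocol: (1) unperturbed search rhythm until the
#' tarsus angle alpha first crosses the obstacle position PO moving
#' downward (detection is armed only after \code{arm_time} so the rhythm is
#' established); (2) a contact epoch of \code{contact_duration} ms during
#' which all motoneuron drives are silenced and the joint angles are held
#' by the passive muscle rigidity; (3) removal, followed by the staged
#' reactivation: fast extensor/flexor immediately, slow motoneurons within
#' the slow ramp, and gradual recruitment of the fast levator/depressor
#' pools slowed down by the obstacle-position dependent factor rf
#' (\code{\link{recruitment_factor}}, interpolation set A for
#' beta_thr <= 6 deg, set B for beta_thr > 10 deg).
#'
#' @param config A \code{leg_config}.
#' @param po Obstacle position on the alpha axis, deg.
#' @param pre_duration Minimum rhythm-establishment time before contact
#'   detection is armed, ms.
#' @param post_duration Recovery time simulated after removal, ms.
#' @param validate If TRUE (default), first verifies that the
#'   configuration produces an autonomous rhythm (>= 3 cycles in the
#'   pre-contact epoch) and raises an error naming the gating regime
#'   otherwise.
#' @return A \code{leg_trace} with events \code{t_contact},
#'   \code{t_removal}, \code{t_full_recruitment} and the rf values used.
#' @export
run_obstacle_experiment <- function(config, po, pre_duration = 9000,
                                    post_duration = 12000, validate = TRUE) {
  validate_config(config)
  ramps <- ramps_for(config)
  rf_lev <- recruitment_factor(po, ramps$levator)
  rf_dep <- recruitment_factor(po, ramps$depressor)
  base <- config$protocol$base_duration
  dur_lev <- base * rf_lev
  dur_dep <- base * rf_dep

  duration <- pre_duration + 3000 + config$protocol$contact_duration +
    post_duration
  pars <- engine_pars(config, duration, po = po, arm_time = pre_duration,
                      dur_lev = dur_lev, dur_dep = dur_dep)
  res <- simulate_leg_cpp(pars)

  if (is.na(res$t_contact))
    stop(sprintf(
      "no contact: alpha never crossed PO = %g downward within %g ms (alpha range [%.1f, %.1f])",
      po, duration, res$alpha_range[1], res$alpha_range[2]))

  events <- list(t_contact = res$t_contact, t_removal = res$t_removal,
                 t_full_recruitment = res$t_removal + max(dur_lev, dur_dep),
                 rf_levator = rf_lev, rf_depressor = rf_dep,
                 interpolation_set = interpolation_set(config$gating$beta_thr))
  tr <- as_leg_trace(res, config, events)

  if (validate) {
    pre <- tr[tr$time_ms < res$t_contact, ]
    cyc <- extract_cycles(pre$beta_deg, pre$time_ms)
    if (length(cyc) < 3) {
      regime <- gating_regime(pre$gamma_deg, pre$time_ms,
                              config$gating$gamma_thr)
      stop("no autonomous rhythm before contact (", length(cyc),
           " cycles; gamma gating regime: ", regime, ")")
    }
  }
  tr
}

#' Sweep obstacle positions and threshold presets
#'
#' Runs \code{\link{run_obstacle_experiment}} for every combination of
#' obstacle position and threshold preset and summarises each run with the
#' analysis-layer descriptors: state-diagram loop class before contact and
#' after removal, cessation flags for beta and gamma in the post-removal
#' epoch, and the alternating-amplitude flag for gamma.  Individual run
#' failures are recorded in the \code{error} column and the sweep
#' continues.
#'
#' @param config Base configuration (thresholds are overridden per preset).
#' @param po_values Numeric vector of obstacle positions, deg.
#' @param presets Character vector of preset names
#'   (see \code{\link{canonical_presets}}), or "all".
#' @param ... Passed to \code{\link{run_obstacle_experiment}}.
#' @return A data.frame with one row per (preset, PO) pair.
#' @export
run_po_sweep <- function(config = default_leg_config(), po_values,
                         presets = "all", ...) {
  if (identical(presets, "all")) presets <- canonical_presets()$name
  stopifnot(length(po_values) >= 1, length(presets) >= 1)
  rows <- list()
  for (pr in presets) {
    cfg <- leg_config(preset = pr)
    cfg$protocol <- config$protocol
    cfg$muscle <- config$muscle
    cfg$network <- config$network
    for (po in po_values) {
      row <- data.frame(preset = pr, gamma_thr = cfg$gating$gamma_thr,
                        beta_thr = cfg$gating$beta_thr, po = po,
                        pre_class = NA_character_, post_class = NA_character_,
                        gamma_cessation = NA, beta_cessation = NA,
                        gamma_alternating = NA,
                        rf_levator = NA_real_, rf_depressor = NA_real_,
                        t_contact = NA_real_, error = NA_character_,
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        tr <- run_obstacle_experiment(cfg, po, ...)
        d <- recovery_descriptors(tr)
        row[names(d)] <- d
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Summary descriptors of an obstacle-experiment trace
#'
#' @param trace A \code{leg_trace} from
#'   \code{\link{run_obstacle_experiment}}.
#' @param settle Time after removal discarded before testing for
#'   steady alternating amplitude, ms.
#' @param transient Initial start-up time excluded from the pre-contact
#'   epoch, ms.
#' @return A one-row data.frame of descriptors.
#' @export
recovery_descriptors <- function(trace, settle = 0, transient = 3000) {
  ev <- attr(trace, "events")
  if (is.null(ev$t_contact)) stop("trace has no contact event")
  cfg <- attr(trace, "config")
  pre <- trace[trace$time_ms >= transient & trace$time_ms < ev$t_contact, ]
  post <- trace[trace$time_ms > ev$t_removal + settle, ]
  pre_loop <- average_loop(pre$beta_deg, pre$gamma_deg, pre$time_ms)
  post_loop <- average_loop(post$beta_deg, post$gamma_deg, post$time_ms,
                            last = 3)
  cls <- function(lp) {
    if (is.null(lp)) return(NA_character_)
    tryCatch(classify_loop(lp, tol = cfg$analysis$rdp_tol)$label,
             error = function(e) NA_character_)
  }
  floor_ <- cfg$analysis$cessation_floor
  mind <- cfg$analysis$cessation_min_dur
  gces <- detect_cessation(post$gamma_deg, post$time_ms, floor_, mind)
  bces <- detect_cessation(post$beta_deg, post$time_ms, floor_, mind)
  galt <- detect_alternating_amplitude(post$gamma_deg, post$time_ms)
  data.frame(pre_class = cls(pre_loop), post_class = cls(post_loop),
             gamma_cessation = nrow(gces) > 0, beta_cessation = nrow(bces) > 0,
             gamma_alternating = isTRUE(galt$flag),
             rf_levator = ev$rf_levator, rf_depressor = ev$rf_depressor,
             t_contact = ev$t_contact, stringsAsFactors = FALSE)
}

#' Posture hold under complete motoneuron silencing
#'
#' Measures how long the passive muscle rigidity keeps both joint angles
#' within a tolerance of their values at silencing onset.  The leg is
#' simulated to a typical mid-cycle pose of the established search rhythm
#' (midway between a beta minimum and the following beta maximum, after the
#' start-up transient), all motoneuron drive multipliers are then set to 0,
#' and the simulation continues until either angle has drifted by more than
#' \code{tol} degrees.
#'
#' @param config A \code{leg_config}.
#' @param tol Drift tolerance, deg.
#' @param warmup Rhythm-establishment run length used to locate the pose,
#'   ms.
#' @param horizon Maximum silenced time simulated, ms.
#' @return List with \code{hold_ms} (time until the tolerance is first
#'   exceeded; \code{horizon} if never), \code{pose_time},
#'   \code{beta0}, \code{gamma0}, and the silenced \code{trace}.
#' @export
silencing_hold_time <- function(config = default_leg_config(), tol = 2,
                                warmup = 10000, horizon = 3000) {
  tr <- run_search(config, duration = warmup)
  w <- tr$time_ms >= 4000
  cyc <- extract_cycles(tr$beta_deg[w], tr$time_ms[w])
  if (length(cyc) < 2) stop("no established rhythm to sample a pose from")
  t0 <- tr$time_ms[w][cyc[[1]]$idx[1]]
  seg <- tr[tr$time_ms >= t0, ]
  i_min <- which.min(seg$beta_deg[seq_len(min(nrow(seg), 400))])
  after <- seg[i_min:nrow(seg), ]
  i_max <- which.max(after$beta_deg[seq_len(min(nrow(after), 400))])
  pose_time <- (after$time_ms[1] + after$time_ms[i_max]) / 2

  poised <- run_search(config, duration = pose_time)
  state <- attr(poised, "final_state")
  silenced <- run_search(config, duration = horizon,
                         mult = c(fast_LD = 0, slow = 0, fast_EF = 0),
                         init_state = state)
  beta0 <- silenced$beta_deg[1]
  gamma0 <- silenced$gamma_deg[1]
  over <- which(abs(silenced$beta_deg - beta0) > tol |
                abs(silenced$gamma_deg - gamma0) > tol)
  hold <- if (length(over)) silenced$time_ms[over[1]] else horizon
  list(hold_ms = hold, pose_time = pose_time, beta0 = beta0,
       gamma0 = gamma0, trace = silenced)
}
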