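# Shared helpers: short canonical runs are cached per test session so the
# suite does not repeat identical deterministic simulations.

.sim_cache <- new.env(parent = emptyenv())

cached_search <- function(preset = "g145_b16", duration = 16000, ...) {
  key <- paste(preset, duration, ...)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- run_search(leg_config(preset = preset),
                                    duration = duration, ...)
  .sim_cache[[key]]
}

cached_obstacle <- function(preset, po, ...) {
  key <- paste("obst", preset, po, ...)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- run_obstacle_experiment(leg_config(preset = preset),
                                                 po = po, ...)
  .sim_cache[[key]]
}

# canonical classification protocol: 16 s run, first 4 s discarded,
# cycle-averaged loop
canonical_loop_class <- function(preset) {
  tr <- cached_search(preset)
  w <- tr$time_ms >= 4000
  classify_loop(average_loop(tr$beta_deg[w], tr$gamma_deg[w],
                             tr$time_ms[w]))$label
}
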