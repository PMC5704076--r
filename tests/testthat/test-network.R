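# Independent reference copy of the wiring (source, target, sign), written
# out by hand so the audit does not depend on the generating code.
reference_wiring <- function() {
  txt <- "
C3   C4      inhibitory
C4   C3      inhibitory
C5   C6      inhibitory
C6   C5      inhibitory
C4   IN7     excitatory
C4   IN8     excitatory
C3   IN9     excitatory
C3   IN10    excitatory
C6   IN13    excitatory
C6   IN14    excitatory
C5   IN15    excitatory
C5   IN16    excitatory
IN7  MN(LF)  inhibitory
IN8  MN(LS)  inhibitory
IN9  MN(DF)  inhibitory
IN10 MN(DS)  inhibitory
IN13 MN(EF)  inhibitory
IN14 MN(ES)  inhibitory
IN15 MN(FF)  inhibitory
IN16 MN(FS)  inhibitory
IN11 C4      inhibitory
IN12 C3      inhibitory
IN17 C5      inhibitory
IN18 C6      inhibitory"
  read.table(text = txt, col.names = c("source", "target", "sign"),
             stringsAsFactors = FALSE)
}

test_that("network counts and wiring match the fixed topology sign-for-sign", {
  net <- build_network(leg_config())
  expect_equal(sum(net$units$type == "cpg"), 4)
  expect_equal(sum(net$units$type == "interneuron"), 12)
  expect_equal(sum(net$units$type == "motoneuron"), 8)
  ref <- reference_wiring()
  got <- net$synapses[, c("source", "target", "sign")]
  key <- function(d) sort(paste(d$source, d$target, d$sign))
  expect_equal(key(got), key(ref))
  expect_true(all(net$synapses$conductance >= 0))
  # sensory conductance slots
  expect_equal(net$gating_inputs$g_gamma$target, "IN12")
  expect_equal(net$gating_inputs$g_beta$target, "IN18")
})

test_that("unknown unit labels in extra synapses raise a configuration error", {
  cfg <- leg_config()
  cfg$network$extra_synapses <- data.frame(
    source = "C9", target = "C3", sign = "excitatory", conductance = 1)
  expect_error(build_network(cfg), "unknown unit label")
})

test_that("zero central drive gives a quiescent network fixed point", {
  cfg <- leg_config(network = list(g_app3 = 0, g_app4 = 0, g_app5 = 0,
                                   g_app6 = 0, g_mn = 0, bias_in12 = 0))
  model <- build_network(cfg)
  s <- network_initial_state(cfg)
  # relax, then verify a further step leaves the state unchanged
  for (i in 1:400) s <- step_units(model, s, dt = 1)
  s2 <- step_units(model, s, dt = 0.5)
  expect_lt(max(abs(s2 - s)), 1e-6)
  expect_true(all(unit_outputs(model, s) < 1e-3))
})

test_that("strong central inhibition of IN7 silences it throughout", {
  cfg <- leg_config(network = list(g_d7 = 20))
  tr <- run_search(cfg, duration = 4000)
  expect_lt(max(tr$IN7), 1e-3)
})

test_that("R reference integrator agrees with the compiled engine", {
  cfg <- leg_config()
  model <- build_network(cfg)
  ref <- network_integrate(model, duration = 800, dt = 0.5,
                           external = list(g_beta = 1, g_gamma = 1))
  # engine run with fixed gates and muscles detached from the network
  cfg2 <- leg_config(muscle = list(q = rep(0, 8), k_pass = rep(0, 8)))
  tr <- run_search(cfg2, duration = 800, dt = 0.5,
                   gate_override = list(beta = list(mode = "fixed", value = 1),
                                        gamma = list(mode = "fixed", value = 1)))
  for (u in c("C3", "C4", "C5", "C6", "IN12", "MN_LF")) {
    ref_col <- sub("MN_LF", "MN(LF)", u)
    expect_equal(tr[[u]], unname(ref$outputs[, ref_col]), tolerance = 1e-8,
                 label = paste("unit", u))
  }
})

test_that("CPG half-centre cells oscillate in anti-phase", {
  tr <- cached_search("g145_b16")
  w <- tr$time_ms >= 4000
  c3 <- tr$C3[w] - mean(tr$C3[w])
  c4 <- tr$C4[w] - mean(tr$C4[w])
  # anti-phase: strong negative instantaneous correlation, and the
  # cross-correlation is maximal near half the period
  expect_lt(cor(c3, c4), -0.5)
  cc <- stats::ccf(c3, c4, lag.max = 250, plot = FALSE)
  lag_best <- cc$lag[which.max(cc$acf)] * 5  # samples are 5 ms apart
  period <- oscillation_stats(tr, transient = 4000)$period
  expect_gt(abs(lag_best), 0.25 * period)
  expect_lt(abs(lag_best), 0.75 * period)
})

test_that("a square-wave gated gamma conductance phase-locks the LD CPG", {
  cfg <- leg_config()
  tr <- run_search(cfg, duration = 16000,
                   gate_override = list(gamma = list(mode = "square",
                                                     period = 1400)))
  w <- tr$time_ms >= 4000
  cyc <- extract_cycles(tr$beta_deg[w], tr$time_ms[w])
  expect_gte(length(cyc), 3)
  periods <- vapply(cyc, `[[`, numeric(1), "duration")
  # periodic and locked to the gate period
  expect_lt(stats::sd(periods) / mean(periods), 0.05)
  expect_lt(abs(mean(periods) - 1400) / 1400, 0.05)
})

test_that("identical configuration and dt give bit-identical traces", {
  a <- run_search(leg_config(), duration = 2000)
  b <- run_search(leg_config(), duration = 2000)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("motoneuron drive multipliers scale the uniform drive per class", {
  model <- build_network(leg_config())
  base <- motoneuron_drive(model)
  expect_true(all(base == model$drives$g_mn))
  half <- motoneuron_drive(model, c(fast_LD = 0.5))
  expect_equal(unname(half[c("MN(LF)", "MN(DF)")]), rep(3, 2))
  expect_equal(unname(half[c("MN(LS)", "MN(EF)")]), rep(6, 2))
  expect_error(motoneuron_drive(model, c(fast_LD = 1.5)), "\\[0, 1\\]")
  expect_error(motoneuron_drive(model, c(turbo = 1)), "unknown motoneuron class")
})

test_that("silencing all classes kills MN output; stepping fast EF back on revives it", {
  # all multipliers zero: outputs decay to (numerically) zero
  tr0 <- run_search(leg_config(), duration = 1500,
                    mult = c(fast_LD = 0, slow = 0, fast_EF = 0))
  late <- tr0[tr0$time_ms > 500, grep("^MN_", names(tr0))]
  expect_lt(max(as.matrix(late)), 1e-3)
  # fast extensor/flexor stepped 0 -> 1 at t0: MN(EF) rises promptly
  tr1 <- run_search(leg_config(), duration = 3000,
                    mult = c(fast_EF = 0),
                    mult_step = list(class = "fast_EF", time = 2000, value = 1))
  before <- max(tr1$MN_EF[tr1$time_ms > 1000 & tr1$time_ms < 2000])
  after <- max(tr1$MN_EF[tr1$time_ms > 2000 & tr1$time_ms < 2200])
  expect_lt(before, 1e-3)
  expect_gt(after, 0.5)
})
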