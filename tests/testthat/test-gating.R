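test_that("the gate is two-valued with ties going to the high value", {
  expect_equal(gate_conductance(84, 83, 1, 0), 1)
  expect_equal(gate_conductance(83, 83, 1, 0), 1)  # tie-break
  expect_equal(gate_conductance(82.999, 83, 1, 0), 0)
  angles <- seq(-40, 180, by = 0.37)
  g <- gate_conductance(angles, 90, 2.5, 0.5)
  expect_setequal(unique(g), c(0.5, 2.5))
  expect_error(gate_conductance(10, 5, 1, 2), "g_high >= g_low")
})

test_that("raising the threshold can only convert high outputs to low", {
  angles <- runif(200, -30, 190)
  thrs <- sort(runif(10, -10, 180))
  prev <- gate_conductance(angles, thrs[1], 1, 0)
  for (th in thrs[-1]) {
    cur <- gate_conductance(angles, th, 1, 0)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("gating regime separates tonic from switching thresholds", {
  t <- seq(0, 8000, by = 5)
  gamma <- 127.5 + 42.5 * sin(2 * pi * t / 1000)  # oscillates in [85, 170]
  expect_equal(gating_regime(gamma, t, 83), "tonic")
  expect_equal(gating_regime(gamma, t, 145), "switching")
  expect_equal(gating_regime(rep(150, length(t)), t, 145), "tonic")
  short <- t < 1800
  expect_error(gating_regime(gamma[short], t[short], 145), "too short")
})

test_that("simulated default traces reproduce the two driving regimes", {
  tr <- cached_search("g145_b16")
  w <- tr$time_ms >= 4000
  expect_equal(gating_regime(tr$gamma_deg[w], tr$time_ms[w], 83), "tonic")
  expect_equal(gating_regime(tr$gamma_deg[w], tr$time_ms[w], 145), "switching")
  # the engine's own gate column matches gate_conductance on the angles
  expect_equal(tr$g_gamma,
               gate_conductance(tr$gamma_deg, 145, 1, 0))
})
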