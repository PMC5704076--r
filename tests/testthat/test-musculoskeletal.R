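test_that("muscle activation relaxes to the recruited target and stays capped", {
  for (af in c(0, 0.25, 0.5, 1)) {
    p <- muscle_pool("levator", "fast", n_units = 5, active_fraction = af)
    for (i in 1:2000) p <- muscle_step(p, mn_output = 1, dt = 1)
    expect_equal(p$activation, af, tolerance = 1e-6,
                 label = paste("steady activation at fraction", af))
  }
  # decay to zero without drive
  p <- muscle_pool("flexor", "slow", activation = 0.9)
  for (i in 1:500) p <- muscle_step(p, 0, dt = 1)
  expect_lt(p$activation, 1e-6)
})

test_that("extensor pools are restricted to a single motoneuron unit", {
  expect_error(muscle_pool("extensor", "fast", n_units = 3), "single")
  expect_silent(muscle_pool("extensor", "slow", n_units = 1))
})

test_that("antagonistic joint torque is symmetric, restoring, and signed", {
  lev <- muscle_pool("levator", "fast", gain = 0.004, theta_contract = 30,
                     passive_stiffness = 1e-4, theta_rest = 10)
  dep <- muscle_pool("depressor", "fast", gain = 0.004, theta_contract = -10,
                     passive_stiffness = 1e-4, theta_rest = 10)
  # symmetric configuration, equal activations, midrange angle: zero torque
  lev$activation <- dep$activation <- 0.5
  mid <- (30 - 10) / 2 + 10 / 2  # angle where active pulls cancel: solve
  # solve q*a*(30 - x) + q*a*(-10 - x) + 2k*(10 - x) = 0
  x <- (0.004 * 0.5 * (30 - 10) + 2e-4 * 10) / (0.004 * 0.5 * 2 + 2e-4)
  expect_equal(joint_torque(lev, dep, x), 0, tolerance = 1e-12)
  # passive-only: restoring towards rest
  lev$activation <- dep$activation <- 0
  expect_gt(joint_torque(lev, dep, 0), 0)   # below rest -> positive torque
  expect_lt(joint_torque(lev, dep, 25), 0)  # above rest -> negative torque
  expect_equal(joint_torque(lev, dep, 10), 0, tolerance = 1e-12)
  # depressor alone drives beta downward
  dep$activation <- 1
  expect_lt(joint_torque(lev, dep, 15), 0)
  # pools from different joints are rejected
  ext <- muscle_pool("extensor", "fast")
  expect_error(joint_torque(lev, ext, 10), "different joints")
})

test_that("joint dynamics are first order with a stop at the stretched position", {
  s <- list(beta = 10, gamma = 130)
  expect_equal(joint_step(s, 0, 0, 0.5), s)
  # constant positive FTi torque runs gamma into the 180-degree stop
  s <- list(beta = 0, gamma = 170)
  for (i in 1:4000) s <- joint_step(s, 0, 0.05, 0.5)
  expect_equal(s$gamma, 180)
  # sinusoidal torque: first-order response with known gain and phase
  om <- 2 * pi / 1000  # rad/ms
  dt <- 0.05
  tt <- seq(0, 20000, by = dt)
  k <- 0.01  # restoring gain used to build the torque: T = -k*x + sin(om t)
  x <- 0
  xs <- numeric(length(tt))
  for (i in seq_along(tt)) {
    xs[i] <- x
    s <- joint_step(list(beta = x, gamma = 130), -k * x + sin(om * tt[i]), 0, dt)
    x <- s$beta
  }
  # closed-form steady state amplitude 1/sqrt(k^2 + om^2)
  amp <- (max(xs[tt > 10000]) - min(xs[tt > 10000])) / 2
  expect_equal(amp, 1 / sqrt(k^2 + om^2), tolerance = 0.01)
})

test_that("alpha kinematics satisfy the exact identities", {
  geom <- list(femur_length = 10, tibia_length = 10)
  # collinear femur + tibia: alpha equals beta, exactly
  for (b in seq(-40, 40, by = 7))
    expect_equal(compute_alpha(b, 180, geom), b, tolerance = 1e-12)
  # degenerate tibia: alpha -> beta
  expect_equal(compute_alpha(17, 95, list(femur_length = 10,
                                          tibia_length = 1e-9)), 17,
               tolerance = 1e-6)
  # planar trigonometry oracle: femur horizontal, tibia straight down
  expect_equal(compute_alpha(0, 90, geom), -45, tolerance = 1e-12)
  # independent oracle: explicit planar construction over a grid
  oracle <- function(b, g, lf, lt) {
    fe <- c(lf * cospi(b / 180), lf * sinpi(b / 180))
    dir <- (b - (180 - g)) / 180
    tip <- fe + c(lt * cospi(dir), lt * sinpi(dir))
    atan2(tip[2], tip[1]) * 180 / pi
  }
  for (b in c(-20, 0, 25)) for (g in c(40, 95, 179)) {
    expect_equal(compute_alpha(b, g, geom), oracle(b, g, 10, 10),
                 tolerance = 1e-12)
  }
  expect_error(compute_alpha(0, 181, geom), "gamma")
  expect_error(compute_alpha(0, 0, geom), "gamma")
})

test_that("alpha is bounded between the flexed and stretched directions", {
  geom <- list(femur_length = 10, tibia_length = 8)
  grid <- expand.grid(b = seq(-30, 40, by = 5), g = seq(30, 180, by = 10))
  a <- compute_alpha(grid$b, grid$g, geom)
  expect_true(all(a <= grid$b + 1e-9))
  expect_true(all(a >= grid$b - (180 - grid$g) - 1e-9))
})
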