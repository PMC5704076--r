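test_that("recruitment factor interpolates linearly with a floor at 1", {
  ramp <- list(rf0 = 1, po0 = -40, rf1 = 3, po1 = 25)
  expect_equal(recruitment_factor(-40, ramp), 1)
  expect_equal(recruitment_factor(25, ramp), 3)
  expect_equal(recruitment_factor(-7.5, ramp), 2)
  # floor: extrapolation below rf = 1 is clamped
  down <- list(rf0 = 3, po0 = -40, rf1 = 1, po1 = 25)
  expect_equal(recruitment_factor(60, down), 1)
  expect_error(recruitment_factor(0, list(rf0 = 1, po0 = 5, rf1 = 2, po1 = 5)),
               "differ")
})

test_that("rf is exactly linear between endpoints (collinearity)", {
  ramp <- list(rf0 = 1.2, po0 = -30, rf1 = 2.8, po1 = 20)
  po <- c(-10, 0, 10)
  rf <- recruitment_factor(po, ramp)
  slope1 <- (rf[2] - rf[1]) / (po[2] - po[1])
  slope2 <- (rf[3] - rf[2]) / (po[3] - po[2])
  expect_equal(slope1, slope2, tolerance = 1e-14)
})

test_that("staged reactivation follows the schedule and its ordering", {
  sched <- list(slow_ramp = 200, fast_ef_delay = 0,
                dur_lev = 4000, dur_dep = 8000)
  r0 <- staged_reactivation(0, sched)
  expect_equal(r0$fast_ef, 1)  # immediate
  expect_equal(r0$slow, 0)
  expect_equal(r0$af_levator, 0)
  expect_equal(staged_reactivation(200, sched)$slow, 1)
  expect_equal(staged_reactivation(4000, sched)$af_depressor, 0.5)
  # ordering: fast EF full <= slow full <= fast LD full, for every rf >= 1
  for (rf in c(1, 1.5, 2, 3)) {
    s <- list(slow_ramp = 200, fast_ef_delay = 0,
              dur_lev = 4000 * rf, dur_dep = 4000 * rf)
    t_ef <- 0
    t_slow <- 200
    t_ld <- 4000 * rf
    expect_true(t_ef <= t_slow && t_slow <= t_ld)
    expect_equal(staged_reactivation(t_ld, s)$af_levator, 1)
    expect_lt(staged_reactivation(t_ld - 1, s)$af_levator, 1)
  }
})

test_that("doubling rf exactly doubles the time to full recruitment", {
  s1 <- list(slow_ramp = 200, fast_ef_delay = 0, dur_lev = 4000,
             dur_dep = 4000)
  s2 <- list(slow_ramp = 200, fast_ef_delay = 0, dur_lev = 8000,
             dur_dep = 8000)
  tt <- seq(0, 8000, by = 100)
  a1 <- staged_reactivation(tt, s1)$af_levator
  a2 <- staged_reactivation(2 * tt, s2)$af_levator
  expect_equal(a1, a2, tolerance = 1e-14)
})

test_that("contact detection finds the first downward crossing", {
  t <- seq(0, 5000, by = 1)
  tr <- data.frame(time_ms = t, alpha_deg = 20 * sin(2 * pi * t / 1000))
  # first downward zero-crossing of a sine starting at 0 is at T/2
  expect_equal(detect_contact(tr, 0), 500, tolerance = 1)
  expect_error(detect_contact(tr, -50), "no contact.*range")
})

test_that("offline contact scan matches the engine's contact event", {
  tr <- cached_obstacle("g145_b16", 0)
  ev <- attr(tr, "events")
  t_off <- detect_contact(tr, 0, after = 9000)
  expect_lt(abs(t_off - ev$t_contact), 10)
})

test_that("interpolation set is chosen by the beta threshold", {
  expect_equal(attr(cached_obstacle("g145_b16", 0), "events")$interpolation_set,
               "B")
  expect_equal(attr(cached_obstacle("g83_b4", 0), "events")$interpolation_set,
               "A")
})

test_that("the obstacle experiment freezes posture and silences MNs on contact", {
  tr <- cached_obstacle("g145_b16", 0)
  ev <- attr(tr, "events")
  contact <- tr[tr$time_ms > ev$t_contact + 10 & tr$time_ms < ev$t_removal, ]
  expect_lt(max(abs(diff(contact$beta_deg))), 1e-9)
  expect_lt(max(abs(diff(contact$gamma_deg))), 1e-9)
  expect_lt(diff(range(contact$beta_deg)), 2)
  expect_lt(diff(range(contact$gamma_deg)), 2)
  # every MN output <= 1e-3 during the late contact epoch
  late <- contact[contact$time_ms > ev$t_contact + 40,
                  grep("^MN_", names(contact))]
  expect_lt(max(as.matrix(late)), 1e-3)
  expect_equal(max(contact$mult_slow), 0)
})

test_that("the pre-contact epoch carries an established rhythm", {
  tr <- cached_obstacle("g145_b16", 0)
  ev <- attr(tr, "events")
  pre <- tr[tr$time_ms < ev$t_contact, ]
  expect_gte(length(extract_cycles(pre$beta_deg, pre$time_ms)), 3)
  # post-removal beta oscillation grows in amplitude over time
  post <- tr[tr$time_ms > ev$t_removal, ]
  cyc <- extract_cycles(post$beta_deg, post$time_ms)
  amps <- vapply(cyc, `[[`, numeric(1), "amplitude")
  expect_gt(amps[length(amps)], amps[1])
})

test_that("an unreachable obstacle position raises a no-contact error", {
  expect_error(run_obstacle_experiment(leg_config(), po = -80,
                                       pre_duration = 3000,
                                       post_duration = 500),
               "no contact.*alpha range")
})

test_that("the PO sweep returns a complete, reproducible table", {
  pos <- c(-10, 10)
  prs <- c("g83_b4", "g145_b16")
  a <- run_po_sweep(po_values = pos, presets = prs, post_duration = 4000)
  b <- run_po_sweep(po_values = pos, presets = prs, post_duration = 4000)
  expect_equal(nrow(a), 4)
  expect_true(all(is.na(a$error)))
  expect_identical(a, b)
})
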