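test_that("cycle extraction counts sine periods and ignores flat traces", {
  t <- seq(0, 10000, by = 5)
  cyc <- extract_cycles(20 * sin(2 * pi * t / 1000), t)
  expect_true(length(cyc) %in% 8:10)
  expect_equal(mean(vapply(cyc, `[[`, numeric(1), "duration")), 1000,
               tolerance = 0.01)
  expect_length(extract_cycles(rep(5, 100), seq_len(100)), 0)
})

test_that("simulated search cycles have consistent periods", {
  tr <- cached_search("g145_b16")
  w <- tr$time_ms >= 4000
  cyc <- extract_cycles(tr$beta_deg[w], tr$time_ms[w])
  periods <- vapply(cyc, `[[`, numeric(1), "duration")
  expect_gte(length(periods), 3)
  expect_lt((max(periods) - min(periods)) / mean(periods), 0.1)
  # independent oracle: peak-to-peak intervals on the raw trace
  pk <- sticksearch:::find_peaks(tr$beta_deg[w], tr$time_ms[w])
  peak_iv <- diff(tr$time_ms[w][pk$imax])
  expect_equal(mean(periods), mean(peak_iv), tolerance = 0.05)
})

test_that("loop classification labels the constructed fixture suite 100%", {
  cases <- expand.grid(kind = c("triangle-loop", "rectangle-loop"),
                       round_frac = c(0, 0.04, 0.08),
                       noise = c(0, 0.5, 1), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    fx <- make_fixture(cases$kind[i],
                       params = list(round_frac = cases$round_frac[i],
                                     noise = cases$noise[i]),
                       seed = i)
    got <- classify_loop(cbind(fx$beta_deg, fx$gamma_deg))$label
    expect_equal(got, attr(fx, "fixture")$loop_class,
                 label = sprintf("%s (round %.2f, noise %.1f)",
                                 cases$kind[i], cases$round_frac[i],
                                 cases$noise[i]))
  }
})

test_that("loop classification is invariant to translation and scaling", {
  fx <- make_fixture("triangle-loop", params = list(round_frac = 0.04))
  lp <- cbind(fx$beta_deg, fx$gamma_deg)
  base <- classify_loop(lp)
  for (tf in list(lp * 4, lp + 200, lp * 0.25 - 30)) {
    got <- classify_loop(tf)
    expect_equal(got$label, base$label)
    expect_equal(got$vertex_count, base$vertex_count)
  }
})

test_that("degenerate loops are recognised and tiny inputs rejected", {
  t <- seq(0, 6000, by = 5)
  bob <- make_fixture("stretched-bobbing")
  cl <- classify_loop(cbind(bob$beta_deg, bob$gamma_deg))
  expect_equal(cl$label, "degenerate-line")
  quiet <- cbind(rep(10, 300) + 1e-4 * seq_len(300), rep(160, 300))
  expect_equal(classify_loop(quiet)$label, "quiescent")
  expect_error(classify_loop(rbind(c(1, 2), c(1, 2))), "3 distinct")
})

test_that("cessation detection finds quiescent intervals and nothing else", {
  t <- seq(0, 10000, by = 5)
  const <- detect_cessation(rep(150, length(t)), t)
  expect_equal(nrow(const), 1)
  expect_equal(const$t_start, 0)
  expect_equal(const$t_end, 10000)
  sine <- detect_cessation(130 + 20 * sin(2 * pi * t / 1000), t)
  expect_equal(nrow(sine), 0)
  fx <- make_fixture("cessation", params = list(t_stop = 5000))
  ces <- detect_cessation(fx$gamma_deg, fx$time_ms)
  expect_gte(nrow(ces), 1)
  expect_lt(abs(ces$t_start[1] - 5000), 600)
  expect_equal(ces$t_end[nrow(ces)], 10000)
  # idempotent / deterministic
  expect_identical(ces, detect_cessation(fx$gamma_deg, fx$time_ms))
})

test_that("alternation rule follows the amplitude-sequence definition", {
  expect_false(alternation_from_amplitudes(c(10, 10, 10, 10, 10, 10))$flag)
  res <- alternation_from_amplitudes(c(10, 6, 10, 6, 10, 6))
  expect_true(res$flag)
  expect_equal(res$depth, 0.4)
  expect_true(is.na(alternation_from_amplitudes(c(10, 6, 10))$flag))
  # monotone growth does not alternate
  expect_false(alternation_from_amplitudes(c(2, 4, 6, 8, 10, 12, 14))$flag)
})

test_that("alternating fixture is detected; steady noisy sines are not", {
  fx <- make_fixture("alternating", params = list(amp_high = 40, amp_low = 24))
  res <- detect_alternating_amplitude(fx$gamma_deg, fx$time_ms)
  expect_true(res$flag)
  expect_equal(res$depth, attr(fx, "fixture")$depth, tolerance = 0.05)
  # fixed-amplitude sine with 1% noise: majority of draws must be negative
  t <- seq(0, 12000, by = 5)
  flags <- vapply(1:20, function(s) {
    set.seed(s)
    x <- 130 + 40 * sin(2 * pi * t / 1000) + rnorm(length(t), sd = 0.4)
    isTRUE(detect_alternating_amplitude(x, t)$flag)
  }, logical(1))
  expect_lt(mean(flags), 0.5)
})

test_that("oscillation statistics report ranges and periods", {
  t <- seq(0, 10000, by = 5)
  om <- 2 * pi / 800
  tr <- data.frame(time_ms = t,
                   beta_deg = 10 + 15 * sin(om * t),
                   gamma_deg = 130 + 30 * sin(om * t),
                   alpha_deg = 0)
  st <- oscillation_stats(tr)
  expect_equal(st$ranges$beta, c(-5, 25), tolerance = 1e-3)
  expect_equal(st$period, 800, tolerance = 0.01)
  flat <- data.frame(time_ms = t, beta_deg = 10, gamma_deg = 150,
                     alpha_deg = 5)
  st0 <- oscillation_stats(flat)
  expect_equal(diff(st0$ranges$gamma), 0)
  expect_true(is.na(st0$period))
})
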