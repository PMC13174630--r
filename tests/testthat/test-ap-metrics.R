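test_that("AP detection on constructed traces", {
  # constant subthreshold trace -> no events
  t <- seq(0, 5, by = 0.001)
  expect_length(detect_aps(rep(-60, length(t)), t)$times, 0)
  # three square spikes crossing 0 mV at t = 1, 2, 3 s
  tr <- spike_trace(5, c(1, 2, 3))
  got <- detect_aps(tr$vm, tr$time, threshold = 0)$times
  expect_length(got, 3)
  expect_equal(got, c(1, 2, 3), tolerance = 2e-3)
  # subthreshold oscillations (peaking below 0 mV) yield no events
  osc <- -40 + 15 * sin(2 * pi * 2 * t)
  expect_length(detect_aps(osc, t)$times, 0)
  # non-uniform grid is an error
  expect_error(detect_aps(c(-60, -60, 10, 10), c(0, 1, 3, 7)), "uniform")
})

test_that("detection settings act as documented", {
  tr <- spike_trace(4, c(1, 2), width_ms = 10) # brief excursions
  expect_length(detect_aps(tr$vm, tr$time)$times, 0)      # fail min_duration
  expect_length(detect_aps(tr$vm, tr$time, min_duration = 5)$times, 2)
  low <- spike_trace(4, c(1, 2), peak = -5)               # no overshoot
  expect_length(detect_aps(low$vm, low$time)$times, 0)
  expect_length(detect_aps(low$vm, low$time, min_peak = -10)$times, 2)
  # refractory merges close pairs
  close_tr <- spike_trace(4, c(1, 1.05), width_ms = 45)
  expect_length(detect_aps(close_tr$vm, close_tr$time)$times, 1)
})

test_that("ap_train enforces ordering and refractory invariants", {
  expect_error(ap_train(c(2, 1)), "increasing")
  expect_error(ap_train(c(1, 1.01)), "refractory")
  expect_length(ap_train(numeric(0))$times, 0)
})

test_that("firing metrics match brute-force computation", {
  # perfectly periodic 2 Hz train
  m <- firing_metrics(ap_train(seq(0.5, 9.5, by = 0.5)), c(0, 10))
  expect_equal(m$rate, 2)
  expect_equal(m$cv, 0)
  expect_equal(m$class, "moderate")
  # alternating 0.4 / 0.6 s intervals vs independent enumeration
  times <- cumsum(rep(c(0.4, 0.6), 10))
  m2 <- firing_metrics(ap_train(times), c(0, 11))
  o <- brute_metrics(times)
  expect_equal(m2$rate, o$rate)
  expect_equal(m2$cv, o$cv)
  # class bands
  expect_equal(firing_metrics(ap_train(seq(1/3, 10, by = 1/3)), c(0, 10))$class, "fast")
  expect_equal(firing_metrics(ap_train(seq(2, 10, by = 2)), c(0, 10))$class, "slow")
  expect_equal(firing_metrics(ap_train(numeric(0)), c(0, 10))$class, "dormant")
  # 0/1 AP: rate = count/window, CV undefined
  m1 <- firing_metrics(ap_train(5), c(0, 10))
  expect_equal(m1$rate, 0.1)
  expect_true(is.na(m1$cv))
  expect_error(firing_metrics(ap_train(1), c(5, 5)), "window")
})

test_that("metrics are invariant under time translation", {
  times <- cumsum(rep(c(0.3, 0.5, 0.4), 8))
  m0 <- firing_metrics(ap_train(times), c(0, 10))
  m1 <- firing_metrics(ap_train(times + 100), c(100, 110))
  expect_equal(m0$rate, m1$rate)
  expect_equal(m0$cv, m1$cv)
  expect_equal(m0$n_aps, m1$n_aps)
})

test_that("capture criterion behaves exactly at the 0.1 Hz boundary", {
  mk <- function(rate) ap_train(seq(1 / rate, 10, by = 1 / rate))
  w <- c(0, 10)
  expect_true(capture_test(mk(2.05), 2, w))    # within 0.1 Hz
  expect_false(capture_test(mk(2.15), 2, w))   # |delta| = 0.15
  expect_true(capture_test(mk(2.09), 2, w))    # just inside the boundary
  expect_false(capture_test(mk(2.11), 2, w))   # just outside
  expect_false(capture_test(ap_train(numeric(0)), 1, w)) # empty train
  expect_false(capture_test(ap_train(5), 1, w))          # single AP
  # symmetry of the tolerance: captured(F, mean) == captured(mean, F)
  for (f in c(1.95, 2, 2.08, 2.2)) {
    expect_equal(capture_test(mk(f), 2, w), capture_test(mk(2), f, w))
  }
})

test_that("burst firing is flagged for depolarizing-phase clustering", {
  # APs only near sine peaks (phase 0.25) across 5 cycles of 0.5 Hz
  f <- 0.5
  tt <- (0:4) / f + 0.25 / f
  expect_true(burst_detect(ap_train(tt), f, epoch_start = 0,
                           window = c(0, 10)))
  # uniformly spaced captured train -> no burst
  unif <- ap_train(seq(0.25, 10, by = 0.5))
  expect_false(burst_detect(unif, 2, epoch_start = 0, window = c(0, 10)))
  # empty train -> no burst
  expect_false(burst_detect(ap_train(numeric(0)), 1))
})

test_that("resonance spectrum captures at matched frequencies and grows with amplitude", {
  p <- cell_params()
  # empty frequency list -> empty spectrum
  expect_equal(nrow(resonance_spectrum(p, 25, numeric(0))), 0)
  sp <- resonance_spectrum(p, c(25, 50), c(2, 3), epoch = 8)
  expect_equal(nrow(sp), 4)
  expect_true(all(c("amplitude", "frequency", "captured") %in% names(sp)))
  # the basal model fires ~2.5 Hz intrinsically; a 50 pA drive at 3 Hz is
  # within its resonance spectrum
  expect_true(sp$captured[sp$amplitude == 50 & sp$frequency == 3])
  # larger amplitude captures a superset of the smaller amplitude's set
  cap25 <- sp$frequency[sp$amplitude == 25 & sp$captured]
  cap50 <- sp$frequency[sp$amplitude == 50 & sp$captured]
  expect_true(all(cap25 %in% cap50))
  sp_span <- spectrum_span(sp)
  expect_true(all(diff(sp_span$n_captured) >= 0))
})

test_that("dormant model is entrained at low frequency and bursts when it cannot follow", {
  pd <- dormant_params()
  sp <- resonance_spectrum(pd, c(25, 50), c(1, 2), epoch = 8)
  expect_true(all(sp$captured))   # awakened and 1:1 captured
  # at 0.5 Hz and strong drive the cell fires clusters during the
  # depolarizing half-cycles instead of following 1:1
  sim <- simulate_cell(pd, stimulus_trace(sine_segment(50, 0.5, 10)),
                       duration = 10)
  train <- detect_aps(sim$V_m, sim$time)
  expect_false(capture_test(train, 0.5, c(2, 10)))
  expect_true(burst_detect(train, 0.5, epoch_start = 0, window = c(2, 10)))
})
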