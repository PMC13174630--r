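test_that("generators are pure functions of (spec, seed)", {
  sp <- movie_spec(dims = c(60, 24, 24), n_lcrs = 8, n_waves = 1,
                   n_flashes = 1)
  a <- synth_movie(sp, seed = 4)
  b <- synth_movie(sp, seed = 4)
  expect_identical(a$movie$stack, b$movie$stack)
  expect_identical(a$truth, b$truth)
  c <- synth_movie(sp, seed = 5)
  expect_false(identical(a$movie$stack, c$movie$stack))
  # and the caller's RNG stream is untouched
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(synth_movie(sp, seed = 4)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero events and zero noise give an exactly rank-1 movie", {
  sp <- movie_spec(dims = c(80, 16, 16), n_waves = 0, n_lcrs = 0,
                   n_flashes = 0, noise_sd = 0)
  sm <- synth_movie(sp, seed = 1)
  nm <- normalize_movie(sm$movie)
  g <- subtract_global_component(nm)
  expect_lt(max(abs(g$residual$stack)), 1e-6 * max(nm$stack))
  expect_equal(nrow(sm$truth), 0)
})

test_that("inserted events are comparable in magnitude to the global transient", {
  sp <- movie_spec(dims = c(150, 32, 32), n_waves = 0, n_flashes = 0,
                   n_lcrs = 6, noise_sd = 0, event_amp = 1, apct_amp = 1)
  # separate the two signals with the same seed: events-only movie vs
  # transient-only movie (the generator inserts the same events either way)
  sp_ev <- sp; sp_ev$apct_amp <- 0
  sp_ap <- sp; sp_ap$n_lcrs <- 0
  ev_peak <- max(synth_movie(sp_ev, seed = 6)$movie$stack / sp$baseline - 1)
  apct_peak <- max(synth_movie(sp_ap, seed = 6)$movie$stack / sp$baseline - 1)
  expect_equal(ev_peak, apct_peak, tolerance = 0.05)
})

test_that("generated LCR areas follow the requested distribution", {
  set.seed(11)
  n <- 1e4
  x <- rlnorm(n, log(20), 0.5)
  ks <- suppressWarnings(stats::ks.test(x, plnorm, log(20), 0.5))
  expect_gt(ks$p.value, 0.01)
  # GPD sampler against its closed-form CDF
  g <- rgpd(n, scale = 10, shape = 0.3)
  pgpd <- function(q) 1 - (1 + 0.3 * q / 10)^(-1 / 0.3)
  ks2 <- suppressWarnings(stats::ks.test(g, pgpd))
  expect_gt(ks2$p.value, 0.01)
  # shape 0 reduces to the exponential
  e <- rgpd(n, scale = 2, shape = 0)
  ks3 <- suppressWarnings(stats::ks.test(e, pexp, 1 / 2))
  expect_gt(ks3$p.value, 0.01)
})

test_that("paired Vm/Ca generator produces the requested coupling and lag", {
  s0 <- synth_vm_ca(duration = 20, coupling = 0, noise_sd = 0.4, seed = 3)
  xc0 <- vm_ca_crosscorr(s0$vm, s0$ca, s0$time, max_lag = 300)
  expect_lt(abs(xc0$peak), 0.15)
  s1 <- synth_vm_ca(duration = 20, coupling = 1, lag = 50, noise_sd = 0.05,
                    seed = 3)
  xc1 <- vm_ca_crosscorr(s1$vm, s1$ca, s1$time, max_lag = 300)
  expect_gt(xc1$peak, 0.9)
  expect_equal(xc1$peak_lag_ms, 50, tolerance = 10)
  # expected cross-correlation peak increases with coupling strength
  peaks <- vapply(c(0.2, 0.5, 0.9), function(cp) {
    mean(vapply(1:4, function(sd) {
      s <- synth_vm_ca(duration = 20, coupling = cp, noise_sd = 0.4,
                       seed = sd)
      vm_ca_crosscorr(s$vm, s$ca, s$time, max_lag = 300)$peak
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("inserted APs dominate the correlation regardless of coupling", {
  # windows containing APs correlate strongly even at zero coupling,
  # motivating the subthreshold guard
  s <- synth_vm_ca(duration = 20, coupling = 0, noise_sd = 0.4,
                   ap_times = seq(2, 19, by = 1), seed = 5)
  xc <- vm_ca_crosscorr(s$vm, s$ca, s$time, window = c(1, 20), max_lag = 300)
  expect_gt(abs(xc$peak), 0.5)
})

test_that("gamma-interval AP trains meet their targets", {
  # cv = 0: exactly periodic
  tr <- synth_ap_train(2, cv = 0, duration = 10)
  expect_equal(diff(tr$times), rep(0.5, 19))
  # closed-form oracle for gamma intervals with shape k = 1/cv^2:
  # per-beat frequency 1/X has mean rate*k/(k-1) and CV 1/sqrt(k-2)
  rate <- 2; cv <- 0.3; k <- 1 / cv^2
  tr2 <- synth_ap_train(rate, cv = cv, duration = 500, seed = 21)
  m <- firing_metrics(tr2, c(0, 500))
  n <- m$n_aps
  exp_rate <- rate * k / (k - 1)
  exp_cv <- 1 / sqrt(k - 2)
  se_rate <- exp_rate * exp_cv / sqrt(n)
  expect_lt(abs(m$rate - exp_rate), 3 * se_rate)
  expect_lt(abs(m$cv - exp_cv), 3 * exp_cv / sqrt(n))
  # duration shorter than one period
  expect_length(synth_ap_train(0.1, cv = 0, duration = 5)$times, 0)
})
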