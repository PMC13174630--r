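test_that("dF/F0 normalization on constructed movies", {
  # constant movie -> all zeros
  m <- ca_movie(array(100, c(10, 8, 8)))
  n <- normalize_movie(m)
  expect_true(all(n$stack == 0))
  # pixel with F0 = 100 and peak 150 -> peak dF/F0 = 0.5
  st <- array(100, c(20, 8, 8))
  st[10, 3, 3] <- 150
  n2 <- normalize_movie(ca_movie(st))
  expect_equal(max(n2$stack), 0.5)
  expect_equal(which.max(n2$stack[, 3, 3]), 10)
  # all-zero movie is an error
  expect_error(normalize_movie(ca_movie(array(0, c(5, 8, 8)))), "F0")
})

test_that("movies round-trip through multi-page TIFF", {
  sp <- movie_spec(dims = c(12, 16, 16), n_waves = 1, n_lcrs = 3,
                   n_flashes = 0)
  mv <- synth_movie(sp, seed = 2)$movie
  f <- tempfile(fileext = ".tif")
  write_ca_tiff(mv, f)
  back <- read_ca_tiff(f, frame_interval = mv$frame_interval,
                       pixel_size = mv$pixel_size)
  expect_equal(dim(back$stack), dim(mv$stack))
  # writeTIFF rescales to [0,1]; correlation must be essentially exact
  expect_gt(cor(as.vector(back$stack), as.vector(mv$stack)), 0.9999)
})

test_that("global-component subtraction removes exactly rank-1 movies", {
  tc <- 1 + sin(seq(0, 6 * pi, length.out = 40))
  map <- outer(seq(0.5, 1, length.out = 8), seq(1, 2, length.out = 9))
  st <- array(outer(tc, as.vector(map)), c(40, 8, 9))
  g <- subtract_global_component(ca_movie(st))
  expect_lt(max(abs(g$residual$stack)), 1e-6 * max(st))
  expect_gt(g$var_share[1], 0.999)
  # constant (zero after normalization) movie is degenerate
  expect_error(subtract_global_component(
    normalize_movie(ca_movie(array(7, c(10, 8, 8))))), "rank-0")
})

test_that("subtraction separates local events from the global transient", {
  sp <- movie_spec(dims = c(150, 32, 32), n_waves = 0, n_flashes = 0,
                   n_lcrs = 12, noise_sd = 0.02)
  sm <- synth_movie(sp, seed = 5)
  nm <- normalize_movie(sm$movie)
  g <- subtract_global_component(nm)
  # energy of the global flash pattern in the residual is < 10% of original
  tc_true <- vapply(seq_len(dim(nm$stack)[1]),
                    function(t) mean(nm$stack[t, , ]), numeric(1))
  proj <- function(stack) {
    flat <- matrix(stack, nrow = dim(stack)[1])
    as.numeric(crossprod(flat, tc_true - mean(tc_true)))
  }
  expect_lt(sum(proj(g$residual$stack)^2), 0.1 * sum(proj(nm$stack)^2))
  # inserted-event energy survives in the residual (>= 80%): regenerate the
  # pure event signal (same seed, no global flash, no noise) as ground truth
  sp0 <- sp; sp0$apct_amp <- 0; sp0$noise_sd <- 0
  ev_only <- synth_movie(sp0, seed = 5)
  pure <- ev_only$movie$stack / sp$baseline - 1
  ev_energy <- function(stack) {
    flat <- matrix(stack, nrow = dim(stack)[1])
    tot <- 0
    for (j in seq_len(nrow(sm$truth))) {
      fr <- sm$truth$start_frame[j]:sm$truth$end_frame[j]
      tot <- tot + sum(flat[fr, sm$footprints[[j]]]^2)
    }
    tot
  }
  expect_gt(ev_energy(g$residual$stack), 0.8 * ev_energy(pure))
  # re-extracting from the residual captures a strictly smaller share
  g2 <- subtract_global_component(g$residual)
  expect_lt(g2$var_share[1], g$var_share[1])
})

test_that("LCR detection on constructed residuals", {
  # zero residual -> no events
  zero <- ca_movie(array(rnorm(20 * 16 * 16, 0, 1e-3), c(20, 16, 16)),
                   signed = TRUE)
  expect_equal(nrow(detect_lcrs(zero)), 0)
  # one stationary 30 px^2 event
  st <- array(rnorm(60 * 24 * 24, 0, 0.02), c(60, 24, 24))
  foot <- as.matrix(expand.grid(y = 9:14, x = 9:13))       # 30 px
  for (fr in 25:29) st[cbind(fr, foot[, 1], foot[, 2])] <- 1
  ev <- detect_lcrs(ca_movie(st, signed = TRUE), k_mad = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$path_area_px, 30, tolerance = 0.2)
  expect_equal(ev$start_frame, 25)
  expect_equal(ev$end_frame, 29)
  # a propagating wave sweeping ~10x the area
  st2 <- array(rnorm(60 * 24 * 48, 0, 0.02), c(60, 24, 48))
  for (k in 0:9) {
    xs <- (3 + 4 * k):(3 + 4 * k + 7)
    for (x in xs) st2[20 + k, 10:16, x] <- 1
  }
  ev2 <- detect_lcrs(ca_movie(st2, signed = TRUE), k_mad = 5)
  expect_equal(nrow(ev2), 1)
  expect_gt(ev2$path_area_px / 30, 8)
  expect_lt(ev2$path_area_px / 30, 12)
})

test_that("detector meets precision/recall >= 0.9 on the seeded suite", {
  for (sd in 1:3) {
    sp <- movie_spec() # defaults: peak SNR = event_amp/noise_sd = 20 >= 5
    sm <- synth_movie(sp, seed = sd)
    nm <- normalize_movie(sm$movie)
    g <- subtract_global_component(nm)
    ev <- detect_lcrs(g$residual)
    pr <- lcr_match(ev, sm$truth, sm$footprints, sp$dims[2])
    expect_gte(pr$recall, 0.9)
    expect_gte(pr$precision, 0.9)
  }
})

test_that("L-moment ratios match closed-form values", {
  set.seed(101)
  expect_lt(abs(l_kurtosis(runif(1e5))), 0.01)          # uniform: tau4 = 0
  expect_equal(l_kurtosis(rexp(1e5)), 1 / 6, tolerance = 0.06) # exponential
  expect_error(l_kurtosis(rep(3, 10)), "degenerate")
  expect_error(l_moments(1:3), "at least 4")
  # location/scale invariance
  x <- rlnorm(5000)
  expect_equal(l_kurtosis(7 + 3 * x), l_kurtosis(x), tolerance = 1e-12)
  # l_moments lambda1 is the mean
  expect_equal(l_moments(x)[["lambda1"]], mean(x))
})

test_that("mean-excess curves distinguish exponential and heavy tails", {
  set.seed(202)
  x <- rexp(5e4)
  me <- mean_excess_curve(x, thresholds = c(0.5, 1, 2, 3))
  expect_true(all(abs(me$mean_excess - 1) < 0.1))   # memoryless: e(u) = 1
  # threshold above the sample maximum is undefined
  me2 <- mean_excess_curve(x, thresholds = max(x) + 1)
  expect_true(is.na(me2$mean_excess))
  # generalized Pareto, shape 0.3: e(u) increases with slope xi/(1-xi)
  g <- rgpd(1e5, scale = 1, shape = 0.3)
  meg <- mean_excess_curve(g, thresholds = c(0.5, 1, 2, 4))
  expect_true(all(diff(meg$mean_excess) > 0))
  slope <- coef(lm(meg$mean_excess ~ meg$threshold))[2]
  expect_equal(unname(slope), 0.3 / 0.7, tolerance = 0.15)
})

test_that("lcr_stats bundles tau4 with histogram and mean excess", {
  set.seed(9)
  s <- lcr_stats(rlnorm(2000, log(20), 0.5))
  expect_gt(s$tau4, 0.1)
  expect_equal(sum(s$log_hist$count), 2000)
  expect_error(lcr_stats(c(1, -2, 3)), "positive")
})

test_that("Vm-Ca cross-correlation on constructed pairs", {
  t <- seq(0, 10, by = 0.001)
  x <- sin(2 * pi * 0.7 * t) + 0.1 * sin(2 * pi * 3.1 * t)
  # identical traces: peak 1 at lag 0
  xc <- vm_ca_crosscorr(x, x, t, max_lag = 200)
  expect_equal(xc$peak, 1, tolerance = 1e-6)
  expect_equal(xc$peak_lag_ms, 0)
  # independent white noise: small peak
  set.seed(33)
  xc2 <- vm_ca_crosscorr(rnorm(10000), rnorm(10000), seq(0, 9.999, 0.001),
                         max_lag = 100)
  expect_lt(abs(xc2$peak), 0.1)
  # delayed copy plus small noise: peak near 1 at ~+50 ms
  set.seed(34)
  lagk <- 50
  y <- c(rep(0, lagk), head(x, -lagk)) + rnorm(length(x), 0, 0.05)
  xc3 <- vm_ca_crosscorr(x, y, t, max_lag = 300)
  expect_gt(xc3$peak, 0.9)
  expect_equal(xc3$peak_lag_ms, 50, tolerance = 5)
})

test_that("the subthreshold guard rejects windows containing APs", {
  s <- synth_vm_ca(duration = 10, coupling = 0.9, ap_times = c(4, 6),
                   seed = 8)
  expect_error(
    vm_ca_crosscorr(s$vm, s$ca, s$time, window = c(0, 5),
                    subthreshold = TRUE, ap_times = s$ap_times),
    "before the first AP")
  ok <- vm_ca_crosscorr(s$vm, s$ca, s$time, window = c(0, 3.9),
                        subthreshold = TRUE, ap_times = s$ap_times)
  expect_true(abs(ok$peak) <= 1 + 1e-9)
})
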