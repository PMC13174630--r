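# Seeded synthetic-data generators: Ca movies with ground truth, paired
# subthreshold Vm/Ca traces, and AP trains.

#' Specification of a synthetic Ca movie
#'
#' Describes a movie composed of a baseline, a rank-1 global AP-induced Ca
#' transient (APCT) signal (one smooth spatial gain map x one periodic
#' transient time course), three patterns of local background events, and
#' i.i.d. Gaussian noise. The three patterns mirror the background signals
#' seen in intact SAN tissue: (1) cell-width Ca waves propagating along the
#' cell axis (50-150 um/s), (2) small fast LCRs lasting a few frames, and
#' (3) incoherent AP-like flashes: cell-sized footprints with APCT kinetics
#' but timing out of synchrony with the global transient.
#'
#' @param dims `c(T, H, W)` movie dimensions.
#' @param frame_interval frame interval, ms.
#' @param pixel_size pixel size, um.
#' @param apct_rate global transient rate, Hz.
#' @param apct_rise,apct_decay APCT kinetics, ms.
#' @param apct_amp peak dF/F0 of the global transient.
#' @param n_waves,n_lcrs,n_flashes event counts per pattern.
#' @param wave_speed propagation speed range, um/s.
#' @param lcr_duration fast-LCR duration range, frames.
#' @param event_amp peak dF/F0 of inserted events; defaults to the APCT
#'   amplitude, since in SAN tissue local background signals rival the
#'   global flash in magnitude.
#' @param area_dist `"lognormal"` or `"gpd"`: distribution of LCR footprint
#'   areas.
#' @param area_meanlog,area_sdlog lognormal parameters (log px^2).
#' @param gpd_scale,gpd_shape generalized-Pareto parameters.
#' @param noise_sd SD of the additive Gaussian noise (dF/F0 units).
#' @param baseline baseline intensity (counts).
#' @return a `movie_spec` object.
#' @export
movie_spec <- function(dims = c(200, 64, 64), frame_interval = 10,
                       pixel_size = 2, apct_rate = 2, apct_rise = 30,
                       apct_decay = 120, apct_amp = 1,
                       n_waves = 4, n_lcrs = 25, n_flashes = 3,
                       wave_speed = c(50, 150), lcr_duration = c(2, 6),
                       event_amp = 1, area_dist = c("lognormal", "gpd"),
                       area_meanlog = log(20), area_sdlog = 0.5,
                       gpd_scale = 10, gpd_shape = 0.3,
                       noise_sd = 0.05, baseline = 100) {
  area_dist <- match.arg(area_dist)
  if (length(dims) != 3 || dims[1] < 2 || dims[2] < 8 || dims[3] < 8)
    stop("dims must be c(T, H, W) with T >= 2 and H, W >= 8")
  if (any(c(apct_rate, n_waves, n_lcrs, n_flashes, noise_sd) < 0))
    stop("rates, counts and noise SD must be >= 0")
  structure(as.list(environment()), class = "movie_spec")
}

#' Generate a synthetic Ca movie with ground truth
#'
#' Pure function of `(spec, seed)`: the same seed always gives the same
#' movie. Returns the movie together with a truth table recording every
#' inserted event (pattern, frames, footprint, true path area) and the
#' global APCT times, for detector validation.
#'
#' @param spec a `movie_spec`.
#' @param seed integer seed.
#' @return list with `movie` (a `ca_movie`), `truth` (data.frame: one row
#'   per inserted event), `apct_times` (s), and `footprints` (list of pixel
#'   index vectors into the H x W plane).
#' @export
synth_movie <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "movie_spec"))
  withr_seed(as.integer(seed), synth_movie_impl(spec))
}

synth_movie_impl <- function(spec) {
  Tn <- spec$dims[1]; H <- spec$dims[2]; W <- spec$dims[3]
  dt_s <- spec$frame_interval / 1000
  tt <- (seq_len(Tn) - 1) * dt_s

  # rank-1 global APCT: smooth spatial gain map x periodic transient
  gain <- outer(gauss_profile(H), gauss_profile(W))
  gain <- 0.4 + 0.6 * gain / max(gain)
  period <- 1 / spec$apct_rate
  apct_times <- if (period / 2 <= max(tt))
    seq(period / 2, max(tt), by = period) else numeric(0)
  tc <- if (length(apct_times))
    rowSums(vapply(apct_times, function(t0)
      transient_kernel(tt, t0, spec$apct_rise / 1000, spec$apct_decay / 1000),
      numeric(Tn)))
  else numeric(Tn)
  tc <- spec$apct_amp * tc / max(tc, 1e-12)
  dff <- outer(tc, as.vector(gain)) # T x (H*W)

  truth <- list(); footprints <- list(); ev <- 0

  add_event <- function(frames, foot_idx, amps) {
    # amps: matrix frames x length(foot_idx) of dF/F0 added
    for (k in seq_along(frames)) {
      dff[frames[k], foot_idx] <<- dff[frames[k], foot_idx] + amps[k, ]
    }
  }

  draw_area <- function() {
    a <- if (spec$area_dist == "lognormal")
      rlnorm(1, spec$area_meanlog, spec$area_sdlog)
    else rgpd(1, spec$gpd_scale, spec$gpd_shape)
    max(4, round(a))
  }

  # pattern 2: small fast LCRs (stationary compact footprints)
  for (i in seq_len(spec$n_lcrs)) {
    area <- draw_area()
    foot <- disc_footprint(H, W, area)
    dur <- sample(spec$lcr_duration[1]:spec$lcr_duration[2], 1)
    f0 <- sample(seq_len(max(1, Tn - dur)), 1)
    frames <- f0:min(f0 + dur - 1, Tn)
    prof <- sin(pi * seq_along(frames) / (length(frames) + 1))
    amps <- outer(prof * spec$event_amp, rep(1, length(foot)))
    add_event(frames, foot, amps)
    ev <- ev + 1
    truth[[ev]] <- data.frame(pattern = "lcr", start_frame = min(frames),
                              end_frame = max(frames),
                              path_area_px = length(foot))
    footprints[[ev]] <- foot
  }

  # pattern 1: propagating cell-width waves along the x axis
  for (i in seq_len(spec$n_waves)) {
    speed <- runif(1, spec$wave_speed[1], spec$wave_speed[2]) # um/s
    px_per_frame <- max(1, round(speed * dt_s / spec$pixel_size))
    len <- sample(20:min(40, W - 2), 1)          # cell length, px
    wid <- sample(3:6, 1)                        # cell width, px
    x0 <- sample(seq_len(W - len), 1)
    y0 <- sample(seq_len(H - wid), 1)
    nfr <- min(ceiling(len / px_per_frame), Tn)
    f0 <- sample(seq_len(max(1, Tn - nfr)), 1)
    nfr <- min(nfr, Tn - f0 + 1)
    cols <- lapply(seq_len(nfr), function(k) {
      xs <- x0 + seq_len(min(k * px_per_frame, len)) - 1
      as.vector(outer(y0 + seq_len(wid) - 1, xs,
                      function(y, x) (x - 1) * H + y))
    })
    foot <- unique(unlist(cols))
    frames <- f0:(f0 + nfr - 1)
    for (k in seq_along(frames))
      dff[frames[k], cols[[k]]] <- dff[frames[k], cols[[k]]] + spec$event_amp
    ev <- ev + 1
    truth[[ev]] <- data.frame(pattern = "wave", start_frame = min(frames),
                              end_frame = max(frames),
                              path_area_px = length(foot))
    footprints[[ev]] <- foot
  }

  # pattern 3: incoherent AP-like flashes (cell-local, APCT kinetics,
  # jittered timing)
  for (i in seq_len(spec$n_flashes)) {
    len <- sample(15:min(30, W - 2), 1); wid <- sample(3:6, 1)
    x0 <- sample(seq_len(W - len), 1); y0 <- sample(seq_len(H - wid), 1)
    foot <- as.vector(outer(y0 + seq_len(wid) - 1, x0 + seq_len(len) - 1,
                            function(y, x) (x - 1) * H + y))
    t0 <- runif(1, 0, max(tt))
    kern <- transient_kernel(tt, t0, spec$apct_rise / 1000,
                             spec$apct_decay / 1000)
    frames <- which(kern > 0.05)
    if (length(frames) < 2) next
    amps <- outer(spec$event_amp * kern[frames] / max(kern), rep(1, length(foot)))
    add_event(frames, foot, amps)
    ev <- ev + 1
    truth[[ev]] <- data.frame(pattern = "flash", start_frame = min(frames),
                              end_frame = max(frames),
                              path_area_px = length(foot))
    footprints[[ev]] <- foot
  }

  dff <- dff + matrix(rnorm(Tn * H * W, 0, spec$noise_sd), Tn)
  counts <- spec$baseline * (1 + dff)
  counts[counts < 0] <- 0
  movie <- ca_movie(array(counts, c(Tn, H, W)), spec$frame_interval,
                    spec$pixel_size)
  truth <- if (ev) do.call(rbind, truth) else
    data.frame(pattern = character(0), start_frame = integer(0),
               end_frame = integer(0), path_area_px = numeric(0))
  list(movie = movie, truth = truth, apct_times = apct_times,
       footprints = footprints)
}

gauss_profile <- function(n) exp(-((seq_len(n) - (n + 1) / 2)^2) / (n / 2)^2)

transient_kernel <- function(tt, t0, rise_s, decay_s) {
  k <- numeric(length(tt))
  up <- tt >= t0
  k[up] <- (1 - exp(-(tt[up] - t0) / rise_s)) * exp(-(tt[up] - t0) / decay_s)
  k
}

# compact disc-like footprint of ~area px at a random position; returns
# linear indices into the H x W plane (column-major)
disc_footprint <- function(H, W, area) {
  r <- max(1, sqrt(area / pi))
  cx <- runif(1, r + 1, W - r); cy <- runif(1, r + 1, H - r)
  xs <- pmax(1, floor(cx - r - 1)):pmin(W, ceiling(cx + r + 1))
  ys <- pmax(1, floor(cy - r - 1)):pmin(H, ceiling(cy + r + 1))
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$x - cx)^2 + (g$y - cy)^2
  g <- g[order(d2), ][seq_len(min(area, nrow(g))), ]
  (g$x - 1) * H + g$y
}

#' Generalized-Pareto deviates
#'
#' Inverse-CDF sampling: x = scale * ((1-u)^(-shape) - 1)/shape for
#' shape != 0 (exponential with the given scale at shape = 0).
#'
#' @param n number of draws.
#' @param scale scale parameter (> 0).
#' @param shape shape parameter xi (>= 0 heavy-tailed; 0 = exponential).
#' @export
rgpd <- function(n, scale = 1, shape = 0) {
  u <- runif(n)
  if (abs(shape) < 1e-12) -scale * log(1 - u)
  else scale * ((1 - u)^(-shape) - 1) / shape
}

#' Paired subthreshold Vm/Ca traces
#'
#' Generates a latent band-limited fluctuation (Gaussian noise smoothed with
#' a Gaussian kernel of SD `smooth_ms`); Vm = latent + independent noise,
#' Ca = coupling x (latent delayed by `lag`) + independent noise. Optional
#' AP/Ca-transient pairs are inserted at `ap_times`, giving the strong
#' AP-dominated correlation that motivates the subthreshold-window guard in
#' [vm_ca_crosscorr()].
#'
#' @param duration s.
#' @param dt sample interval, ms.
#' @param coupling coupling strength in `[0, 1]`.
#' @param lag Ca delay, ms.
#' @param noise_sd independent noise SD (in units of the latent SD).
#' @param smooth_ms latent smoothness (Gaussian kernel SD, ms).
#' @param ap_times optional AP times, s.
#' @param seed integer seed.
#' @return list with `time` (s), `vm`, `ca`, `latent`, `ap_times`.
#' @export
synth_vm_ca <- function(duration = 10, dt = 1, coupling = 0.8, lag = 50,
                        noise_sd = 0.3, smooth_ms = 50, ap_times = NULL,
                        seed = 1L) {
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  withr_seed(as.integer(seed), {
    n <- round(duration * 1000 / dt)
    tt <- (seq_len(n) - 1) * dt / 1000
    ks <- max(1, round(smooth_ms / dt))
    kern <- dnorm(seq(-3 * ks, 3 * ks), sd = ks)
    kern <- kern / sum(kern)
    pad <- length(kern)
    z <- rnorm(n + 2 * pad)
    latent <- as.numeric(stats::filter(z, kern, sides = 2))
    latent <- latent[pad + seq_len(n)]
    latent <- (latent - mean(latent)) / sd(latent)
    shift <- round(lag / dt)
    delayed <- c(rep(latent[1], shift), head(latent, n - shift))
    vm <- latent + rnorm(n, 0, noise_sd)
    ca <- coupling * delayed + rnorm(n, 0, noise_sd)
    if (!is.null(ap_times)) {
      for (t0 in ap_times) {
        vm <- vm + 20 * transient_kernel(tt, t0, 0.002, 0.05)
        ca <- ca + 10 * transient_kernel(tt, t0 + lag / 1000, 0.01, 0.15)
      }
    }
    list(time = tt, vm = vm, ca = ca, latent = latent,
         ap_times = if (is.null(ap_times)) numeric(0) else ap_times)
  })
}

#' Synthetic AP train with gamma-distributed intervals
#'
#' Inter-AP intervals are gamma with mean `1/rate` and coefficient of
#' variation `cv` (`cv = 0` gives an exactly periodic train).
#'
#' @param rate mean firing rate, Hz (> 0).
#' @param cv coefficient of variation of the intervals (>= 0).
#' @param duration train duration, s.
#' @param seed integer seed.
#' @return an `ap_train`.
#' @export
synth_ap_train <- function(rate, cv = 0, duration = 10, seed = 1L) {
  if (rate <= 0) stop("rate must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  mu <- 1 / rate
  times <- withr_seed(as.integer(seed), {
    if (cv == 0) {
      if (mu > duration) numeric(0) else seq(mu, duration, by = mu)
    } else {
      shape <- 1 / cv^2
      n_guess <- max(10, ceiling(duration * rate * 2 + 10))
      iv <- rgamma(n_guess, shape = shape, scale = mu / shape)
      while (sum(iv) < duration)
        iv <- c(iv, rgamma(n_guess, shape = shape, scale = mu / shape))
      tt <- cumsum(iv)
      tt[tt <= duration]
    }
  })
  ap_train(times)
}
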