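# AP detection, firing metrics, one-to-one capture, resonance spectra.

#' Detect action potentials in a membrane-potential trace
#'
#' An AP is an upward crossing of `threshold` whose excursion above threshold
#' (i) reaches a peak above `min_peak` (true SAN APs overshoot 0 mV, while
#' subthreshold oscillations and brief noise-driven excursions do not) and
#' (ii) lasts at least `min_duration` ms (the model's AP duration at -20 mV
#' is 70-95 ms, an order of magnitude longer than noise-driven crossings),
#' with successive APs separated by at least `refractory` ms. All four
#' settings are configuration keys.
#'
#' @param vm membrane potential, mV, sampled on a uniform time grid.
#' @param time sample times, s (uniform grid).
#' @param threshold upstroke detection threshold, mV.
#' @param refractory minimum separation of AP upstrokes, ms.
#' @param min_peak minimum peak, mV, for an excursion to count as an AP.
#' @param min_duration minimum time above `threshold`, ms.
#' @return an `ap_train`: list with `times` (upstroke times, s, strictly
#'   increasing) and the detection settings.
#' @export
detect_aps <- function(vm, time, threshold = -20, refractory = 80,
                       min_peak = 0, min_duration = 40) {
  if (length(vm) != length(time)) stop("vm and time must have equal length")
  if (refractory <= 0) stop("refractory must be > 0")
  if (length(time) > 2) {
    dtv <- diff(time)
    if (max(dtv) - min(dtv) > 1e-6 * stats::median(dtv))
      stop("time grid must be uniform")
  }
  above <- vm > threshold
  ups <- which(diff(above) == 1) + 1
  times <- numeric(0)
  last <- -Inf
  n <- length(vm)
  for (i in ups) {
    j <- i
    while (j < n && above[j + 1]) j <- j + 1
    dur_ms <- (time[min(j + 1, n)] - time[i]) * 1000
    if (dur_ms >= min_duration && max(vm[i:j]) > min_peak &&
        (time[i] - last) * 1000 >= refractory) {
      times <- c(times, time[i])
      last <- time[i]
    }
  }
  ap_train(times, threshold = threshold, refractory = refractory,
           min_peak = min_peak, min_duration = min_duration)
}

#' Construct an AP train from upstroke times
#'
#' @param times AP upstroke times, s (strictly increasing).
#' @param threshold,refractory,min_peak,min_duration detection settings
#'   recorded with the train.
#' @return an `ap_train` object.
#' @export
ap_train <- function(times, threshold = -20, refractory = 80, min_peak = 0,
                     min_duration = 40) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("AP times must be strictly increasing")
  if (length(times) > 1 && any(diff(times) * 1000 < refractory - 1e-9))
    stop("AP times closer than the refractory period")
  structure(list(times = times,
                 settings = list(threshold = threshold,
                                 refractory = refractory,
                                 min_peak = min_peak,
                                 min_duration = min_duration)),
            class = "ap_train")
}

#' @export
print.ap_train <- function(x, ...) {
  cat("<ap_train> ", length(x$times), " APs",
      if (length(x$times) > 1)
        sprintf(", span %.2f-%.2f s", min(x$times), max(x$times)), "\n",
      sep = "")
  invisible(x)
}

#' Firing metrics over a window
#'
#' Mean frequency is the mean of per-beat instantaneous frequencies (1/IBI)
#' of the inter-AP intervals inside the window, and CV = SD/mean of those
#' frequencies; with fewer than 2 intervals the rate falls back to
#' count/window and CV is `NA`. Population class uses the standard bands:
#' fast > 2.5 Hz, moderate 1-2.5 Hz, slow < 1 Hz, dormant = no APs.
#'
#' @param train an `ap_train`.
#' @param window numeric length-2, `c(t0, t1)` in s.
#' @param cv_on `"frequency"` (default) or `"interval"`: compute CV over
#'   per-beat frequencies or over the intervals themselves.
#' @return a `firing_metrics` list: `rate` (Hz), `cv`, `class`, `n_aps`.
#' @export
firing_metrics <- function(train, window, cv_on = c("frequency", "interval")) {
  stopifnot(inherits(train, "ap_train"))
  cv_on <- match.arg(cv_on)
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(t0, t1) with t1 > t0")
  tt <- train$times[train$times >= window[1] & train$times <= window[2]]
  n <- length(tt)
  if (n >= 3) {
    f <- 1 / diff(tt)
    x <- if (cv_on == "frequency") f else diff(tt)
    rate <- mean(f)
    cv <- sd(x) / mean(x)
  } else if (n == 2) {
    rate <- 1 / diff(tt)
    cv <- NA_real_
  } else {
    rate <- n / diff(window)
    cv <- NA_real_
  }
  cls <- if (n == 0) "dormant"
         else if (rate > 2.5) "fast"
         else if (rate >= 1) "moderate"
         else "slow"
  structure(list(rate = unname(rate), cv = unname(cv), class = cls, n_aps = n,
                 window = window),
            class = "firing_metrics")
}

#' @export
print.firing_metrics <- function(x, ...) {
  cat(sprintf("<firing_metrics> %.3g Hz (%s), CV = %s, n = %d APs\n",
              x$rate, x$class,
              if (is.na(x$cv)) "NA" else sprintf("%.3g", x$cv), x$n_aps))
  invisible(x)
}

#' One-to-one capture test
#'
#' A train is captured by a sine stimulus of frequency `F` if its mean firing
#' frequency over the window matches `F` within `tol` (0.1 Hz) and at least
#' two APs occurred.
#'
#' @param train an `ap_train`.
#' @param F stimulus frequency, Hz.
#' @param window evaluation window, s (should start after a settle time
#'   inside the sine epoch).
#' @param tol capture tolerance, Hz.
#' @return logical flag.
#' @export
capture_test <- function(train, F, window, tol = 0.1) {
  m <- firing_metrics(train, window)
  isTRUE(m$n_aps >= 2 && abs(m$rate - F) <= tol)
}

#' Burst-firing test within a sine epoch
#'
#' Flags epochs in which APs cluster in the depolarizing half-cycles of the
#' sine wave (>= `frac` of APs during depolarizing phase) while at least one
#' hyperpolarizing half-cycle is silent. Phase is computed
#' relative to `epoch_start`, where the sine is `a*sin(2*pi*F*(t -
#' epoch_start))`: depolarizing half-cycles are those with positive sine.
#'
#' @param train an `ap_train`.
#' @param F sine frequency, Hz.
#' @param epoch_start epoch start time, s.
#' @param window evaluation window, s.
#' @param frac minimum fraction of APs in depolarizing half-cycles.
#' @return logical flag (`FALSE` for an empty train).
#' @export
burst_detect <- function(train, F, epoch_start = 0, window = NULL,
                         frac = 0.9) {
  stopifnot(inherits(train, "ap_train"))
  tt <- train$times
  if (!is.null(window)) tt <- tt[tt >= window[1] & tt <= window[2]]
  if (!length(tt)) return(FALSE)
  phase <- ((tt - epoch_start) * F) %% 1
  depol <- phase < 0.5
  if (mean(depol) < frac) return(FALSE)
  # at least one hyperpolarizing half-cycle without APs, among cycles spanned
  if (is.null(window)) window <- range(tt)
  cyc0 <- floor((window[1] - epoch_start) * F)
  cyc1 <- floor((window[2] - epoch_start) * F)
  cycles <- cyc0:cyc1
  hyper_has_ap <- vapply(cycles, function(k) {
    lo <- epoch_start + (k + 0.5) / F
    hi <- epoch_start + (k + 1) / F
    any(tt >= lo & tt < hi)
  }, logical(1))
  any(!hyper_has_ap)
}

#' Resonance spectrum over amplitude x frequency grids
#'
#' Runs one sine epoch per (amplitude, frequency) pair through
#' [simulate_cell()] and applies [capture_test()] after a settle time,
#' returning the full grid of capture flags. The captured frequency span per
#' amplitude is the cell's resonance spectrum at that amplitude.
#'
#' @param params a `cell_params` object.
#' @param amplitudes sine amplitudes, pA.
#' @param freqs sine frequencies, Hz.
#' @param epoch epoch duration, s.
#' @param settle settle time before the capture window, s.
#' @param dt integration step, ms.
#' @param tol capture tolerance, Hz.
#' @param ... further arguments to [detect_aps()].
#' @return a data.frame with columns `amplitude`, `frequency`, `captured`,
#'   `rate`, `n_aps`, of class `resonance_spectrum`.
#' @export
resonance_spectrum <- function(params, amplitudes, freqs, epoch = 10,
                               settle = 2, dt = 0.01, tol = 0.1, ...) {
  stopifnot(inherits(params, "cell_params"))
  grid <- expand.grid(amplitude = amplitudes, frequency = freqs,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) {
    out <- data.frame(amplitude = numeric(0), frequency = numeric(0),
                      captured = logical(0), rate = numeric(0),
                      n_aps = integer(0))
    class(out) <- c("resonance_spectrum", "data.frame")
    return(out)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$amplitude[i]; f <- grid$frequency[i]
    sim <- tryCatch(
      simulate_cell(params, stimulus_trace(sine_segment(a, f, epoch)),
                    duration = epoch, dt = dt),
      error = function(e) stop("simulation failed at (a = ", a, " pA, F = ",
                               f, " Hz): ", conditionMessage(e)))
    train <- detect_aps(sim$V_m, sim$time, ...)
    win <- c(settle, epoch)
    m <- firing_metrics(train, win)
    data.frame(amplitude = a, frequency = f,
               captured = capture_test(train, f, win, tol = tol),
               rate = m$rate, n_aps = m$n_aps)
  })
  out <- do.call(rbind, res)
  class(out) <- c("resonance_spectrum", "data.frame")
  out
}

#' Captured frequency span per amplitude
#'
#' @param spec a `resonance_spectrum`.
#' @return data.frame with per-amplitude lowest/highest captured frequency
#'   and count of captured frequencies.
#' @export
spectrum_span <- function(spec) {
  stopifnot(inherits(spec, "resonance_spectrum"))
  do.call(rbind, lapply(split(spec, spec$amplitude), function(d) {
    cf <- d$frequency[d$captured]
    data.frame(amplitude = d$amplitude[1],
               f_low = if (length(cf)) min(cf) else NA_real_,
               f_high = if (length(cf)) max(cf) else NA_real_,
               n_captured = length(cf))
  }))
}
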