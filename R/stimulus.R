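# Injected-current protocols: sine epochs and zero-mean sample-and-hold noise.

#' Stimulus segments
#'
#' A stimulus trace is an ordered list of segments tiling `[0, duration]`.
#' Three kinds exist: `quiet_segment()` (zero current), `sine_segment()` and
#' `noise_segment()`.
#'
#' Amplitude convention: for sine segments `a` is the one-direction (peak)
#' amplitude, so the waveform is `a * sin(2*pi*F*t)` with peak-to-peak `2a`;
#' this convention is isolated here so the alternative reading (peak `2a`) is
#' a one-line change. For noise segments the waveform is piecewise constant
#' over `hold` ms intervals, each value drawn independently and uniformly
#' from `[-a, a]` (zero mean, SD `a/sqrt(3)`), giving band-limited white
#' noise with a flat spectrum far beyond the cell's sub-10-Hz resonance band.
#'
#' @param a amplitude, pA (one-direction; >= 0).
#' @param F sine frequency, Hz (> 0).
#' @param duration segment duration, s (> 0).
#' @param hold noise hold interval, ms (> 0).
#' @param seed optional integer seed making the noise segment reproducible on
#'   its own; if `NA` the values are drawn from the surrounding RNG stream
#'   (e.g. the `seed` given to [simulate_cell()]).
#' @return a `stim_segment` object.
#' @export
sine_segment <- function(a, F, duration) {
  if (!is.numeric(a) || a < 0) stop("amplitude must be >= 0")
  if (!is.numeric(F) || F <= 0) stop("frequency must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(kind = "sine", a = a, F = F, duration = duration),
            class = "stim_segment")
}

#' @rdname sine_segment
#' @export
noise_segment <- function(a, duration, hold = 1, seed = NA) {
  if (!is.numeric(a) || a < 0) stop("amplitude must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  if (hold <= 0) stop("hold interval must be > 0")
  structure(list(kind = "noise", a = a, duration = duration, hold = hold,
                 seed = seed),
            class = "stim_segment")
}

#' @rdname sine_segment
#' @export
quiet_segment <- function(duration) {
  if (duration <= 0) stop("duration must be > 0")
  structure(list(kind = "none", duration = duration), class = "stim_segment")
}

#' Build a stimulus trace from segments
#'
#' @param ... `stim_segment` objects (or a single list of them), played back
#'   to back starting at t = 0.
#' @return a `stimulus_trace` object.
#' @export
stimulus_trace <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && !inherits(segs[[1]], "stim_segment"))
    segs <- segs[[1]]
  if (!all(vapply(segs, inherits, logical(1), "stim_segment")))
    stop("all arguments must be stim_segment objects")
  t0 <- c(0, cumsum(vapply(segs, `[[`, numeric(1), "duration")))
  structure(list(segments = segs, t0 = t0[-length(t0)],
                 duration = t0[length(t0)]),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat("<stimulus_trace> ", length(x$segments), " segment(s), ",
      x$duration, " s total\n", sep = "")
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    lab <- switch(s$kind,
      none = "quiet",
      sine = sprintf("sine  a=%g pA, F=%g Hz", s$a, s$F),
      noise = sprintf("noise a=%g pA, hold=%g ms", s$a, s$hold))
    cat(sprintf("  [%6.2f, %6.2f) s  %s\n", x$t0[i], x$t0[i] + s$duration, lab))
  }
  invisible(x)
}

# Compile a stimulus trace for the C++ integrator.  Draws the noise values:
# per-segment seeds (if given) are honoured without disturbing the caller's
# RNG stream; segments with seed = NA consume the current stream.
compile_stimulus <- function(trace, duration_s) {
  if (is.null(trace)) trace <- stimulus_trace(quiet_segment(duration_s))
  segs <- trace$segments
  n <- length(segs)
  m <- matrix(0, n, 7) # kind t0 t1 a F hold offset (times ms)
  vals <- numeric(0)
  for (i in seq_len(n)) {
    s <- segs[[i]]
    t0 <- trace$t0[i] * 1000
    t1 <- t0 + s$duration * 1000
    kind <- match(s$kind, c("none", "sine", "noise")) - 1
    a <- if (kind == 0) 0 else s$a
    F <- if (kind == 1) s$F else 0
    hold <- if (kind == 2) s$hold else 1
    off <- length(vals)
    if (kind == 2) {
      nv <- ceiling((t1 - t0) / hold - 1e-9)
      v <- if (!is.na(s$seed)) {
        withr_seed(s$seed, runif(nv, -s$a, s$a))
      } else {
        runif(nv, -s$a, s$a)
      }
      vals <- c(vals, v)
    }
    m[i, ] <- c(kind, t0, t1, a, F, hold, off)
  }
  list(seg = m, vals = vals)
}

# evaluate with a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a stimulus trace
#'
#' Pure evaluation of the waveform on a time grid; noise segments must carry
#' their own `seed` to be reproducible here (segments with `seed = NA` are
#' drawn once and cached on first call).
#'
#' @param trace a `stimulus_trace`.
#' @param t times, s.
#' @return current values, pA.
#' @export
sample_stimulus <- function(trace, t) {
  stopifnot(inherits(trace, "stimulus_trace"))
  out <- numeric(length(t))
  for (i in seq_along(trace$segments)) {
    s <- trace$segments[[i]]
    t0 <- trace$t0[i]
    t1 <- t0 + s$duration
    in_seg <- t >= t0 & t < t1
    if (!any(in_seg)) next
    tt <- t[in_seg] - t0
    out[in_seg] <- switch(s$kind,
      none = 0,
      sine = s$a * sin(2 * pi * s$F * tt),
      noise = {
        nv <- ceiling(s$duration * 1000 / s$hold - 1e-9)
        if (is.null(s$values)) {
          if (is.na(s$seed))
            stop("noise segment without a seed cannot be sampled reproducibly")
          s$values <- withr_seed(s$seed, runif(nv, -s$a, s$a))
          trace$segments[[i]] <- s
        }
        idx <- pmin(floor(tt * 1000 / s$hold) + 1, nv)
        s$values[idx]
      })
  }
  out
}

#' Standard stimulus protocols
#'
#' Builders for the protocols used throughout the study:
#' * `protocol_noise_run(a)`: quiet 10 s, zero-mean noise 10 s, quiet tail
#'   (default 5 s) -- noise applied from 10 to 20 s;
#' * `protocol_sine_sweep(a, freqs)`: consecutive sine epochs at the default
#'   frequencies 0.5, 1, 2, 3, 4, 5, 6 Hz (each `epoch` s, configurable;
#'   pass a finer grid, e.g. 0.25-Hz steps, via `freqs`);
#' * `sine_amplitudes()` and `noise_amplitudes()`: the standard amplitude
#'   series, 10/20/25/50 pA (sine) and 25/31.25/62.5/125 pA (noise).
#'
#' @param a amplitude, pA.
#' @param tail quiet tail duration, s.
#' @param hold,seed passed to [noise_segment()].
#' @param freqs sine frequencies, Hz.
#' @param epoch duration of each sine epoch, s.
#' @return a `stimulus_trace` (or numeric vector for the amplitude series).
#' @export
protocol_noise_run <- function(a, tail = 5, hold = 1, seed = NA) {
  stimulus_trace(quiet_segment(10),
                 noise_segment(a, 10, hold = hold, seed = seed),
                 quiet_segment(tail))
}

#' @rdname protocol_noise_run
#' @export
protocol_sine_sweep <- function(a, freqs = c(0.5, 1, 2, 3, 4, 5, 6),
                                epoch = 10) {
  if (!length(freqs)) stop("freqs must be non-empty")
  stimulus_trace(lapply(freqs, function(f) sine_segment(a, f, epoch)))
}

#' @rdname protocol_noise_run
#' @export
sine_amplitudes <- function() c(10, 20, 25, 50)

#' @rdname protocol_noise_run
#' @export
noise_amplitudes <- function() c(25, 31.25, 62.5, 125)

#' Export a stimulus waveform as CSV
#'
#' @param trace a `stimulus_trace` (noise segments need seeds).
#' @param path output file.
#' @param dt sampling interval, s.
#' @export
write_stimulus_csv <- function(trace, path, dt = 0.001) {
  t <- seq(0, trace$duration - dt / 2, by = dt)
  write.csv(data.frame(time_s = t, current_pA = sample_stimulus(trace, t)),
            path, row.names = FALSE)
  invisible(path)
}
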