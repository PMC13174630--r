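# Two-parameter firing-diagram sweeps over (g_CaL, P_up).

#' Build a (g_CaL, P_up) sweep grid
#'
#' Inclusive arithmetic grids with exact integer point counts
#' (floor((stop-start)/step)+1, tolerant of float increments). The
#' full-resolution defaults are g_CaL from 0.28 to 0.52 nS/pF in 0.0025
#' steps (97 values) and P_up from 0 to 12 mM/s in 0.2 steps (61 values),
#' i.e. 5,917 models per condition; the desk-scale default for interactive
#' work is the reduced 13 x 9 grid from [reduced_grid()].
#'
#' @param gcal_range `c(start, stop, step)` for g_CaL, nS/pF.
#' @param pup_range `c(start, stop, step)` for P_up, mM/s.
#' @param condition `"basal"` or `"carbachol"`.
#' @param noise_amp injected white-noise amplitude, pA (0 = none).
#' @param cch carbachol dose, nM, applied when `condition = "carbachol"`.
#' @return a `sweep_grid` object with `g_CaL` and `P_up` value vectors.
#' @export
build_grid <- function(gcal_range = c(0.28, 0.52, 0.0025),
                       pup_range = c(0, 12, 0.2),
                       condition = c("basal", "carbachol"),
                       noise_amp = 0, cch = 300) {
  condition <- match.arg(condition)
  gv <- grid_axis(gcal_range)
  pv <- grid_axis(pup_range)
  if (noise_amp < 0) stop("noise_amp must be >= 0")
  structure(list(g_CaL = gv, P_up = pv, condition = condition,
                 noise_amp = noise_amp, cch = if (condition == "carbachol") cch else 0),
            class = "sweep_grid")
}

grid_axis <- function(range) {
  if (length(range) != 3) stop("range must be c(start, stop, step)")
  start <- range[1]; stop_ <- range[2]; step <- range[3]
  if (step <= 0) stop("step must be > 0")
  if (stop_ < start) stop("stop must be >= start")
  # half-step tolerance so float increments still give exact counts
  n <- floor((stop_ - start + step / 2) / step) + 1
  start + step * (seq_len(n) - 1)
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid> %d x %d = %d points (%s%s)\n",
              length(x$g_CaL), length(x$P_up),
              length(x$g_CaL) * length(x$P_up), x$condition,
              if (x$noise_amp > 0) sprintf(", noise %g pA", x$noise_amp) else ""))
  invisible(x)
}

#' Desk-scale reduced grid
#'
#' A 13 x 9 grid spanning the same parameter ranges as the full-resolution
#' diagram, used for interactive work and tests.
#' @inheritParams build_grid
#' @export
reduced_grid <- function(condition = "basal", noise_amp = 0, cch = 300) {
  build_grid(c(0.28, 0.52, 0.02), c(0, 12, 1.5), condition, noise_amp, cch)
}

#' Run a firing-diagram sweep
#'
#' Simulates one cell model per grid point (20 s by default, first 5 s
#' discarded) and computes firing metrics. Each point's noise realization
#' uses an independent, reproducible sub-seed derived from the master seed,
#' so any single point can be re-run in isolation with
#' [sweep_point_seed()]. Per-point simulation failures are recorded in the
#' `failed` column rather than aborting the sweep.
#'
#' @param grid a `sweep_grid`.
#' @param duration simulated time per point, s.
#' @param discard transient discarded before metrics, s.
#' @param dt integration step, ms.
#' @param seed master seed.
#' @param progress print a dot per completed column.
#' @return a `sweep_diagram`: data.frame with one row per grid point
#'   (`g_CaL`, `P_up`, `rate`, `cv`, `class`, `n_aps`, `failed`) plus
#'   summary attributes.
#' @export
run_sweep <- function(grid, duration = 20, discard = 5, dt = 0.01, seed = 1L,
                      progress = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (duration <= discard) stop("duration must exceed the discarded transient")
  base <- cell_params()
  if (grid$condition == "carbachol") base <- apply_carbachol(base, grid$cch)
  rows <- vector("list", length(grid$g_CaL) * length(grid$P_up))
  k <- 0
  for (i in seq_along(grid$g_CaL)) {
    for (j in seq_along(grid$P_up)) {
      k <- k + 1
      p <- cell_params(g_CaL = grid$g_CaL[i], P_up = grid$P_up[j],
                       base = unclass(base))
      stim <- if (grid$noise_amp > 0)
        stimulus_trace(noise_segment(grid$noise_amp, duration))
      else NULL
      sub_seed <- sweep_point_seed(seed, i, j, grid$condition)
      res <- tryCatch({
        sim <- simulate_cell(p, stim, duration = duration, dt = dt,
                             seed = sub_seed)
        m <- firing_metrics(detect_aps(sim$V_m, sim$time),
                            c(discard, duration))
        data.frame(g_CaL = grid$g_CaL[i], P_up = grid$P_up[j],
                   rate = m$rate, cv = m$cv, class = m$class,
                   n_aps = m$n_aps, failed = FALSE)
      }, error = function(e) {
        data.frame(g_CaL = grid$g_CaL[i], P_up = grid$P_up[j],
                   rate = NA_real_, cv = NA_real_, class = NA_character_,
                   n_aps = NA_integer_, failed = TRUE)
      })
      rows[[k]] <- res
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "summary") <- list(
    n_points = nrow(out),
    n_firing = sum(!out$failed & out$class != "dormant"),
    n_nonfiring = sum(!out$failed & out$class == "dormant"),
    n_failed = sum(out$failed))
  class(out) <- c("sweep_diagram", "data.frame")
  out
}

#' Deterministic per-point sub-seed
#'
#' Hash of (master seed, grid indices, condition) into a positive 31-bit
#' integer, so any sweep point can be reproduced in isolation.
#' @param seed master seed.
#' @param i,j grid indices (g_CaL, P_up).
#' @param condition condition label (contributes its characters).
#' @export
sweep_point_seed <- function(seed, i, j, condition = "basal") {
  h <- as.double(seed) %% 2147483647
  for (v in c(i, j, utf8ToInt(as.character(condition)))) {
    h <- (h * 48271 + v) %% 2147483647
  }
  as.integer(h + 1)
}

#' Summarize a sweep diagram
#' @param object a `sweep_diagram`.
#' @param ... unused.
#' @export
summary.sweep_diagram <- function(object, ...) attr(object, "summary")

#' Expansion summary between two sweep diagrams
#'
#' Compares two diagrams on identical grids and counts points converting
#' non-firing to firing (e.g. awakened by noise) and vice versa, plus the
#' mean rate change among points firing in both.
#'
#' @param d0,d1 `sweep_diagram` objects on the same grid.
#' @return list with `n_awakened`, `n_silenced`, `mean_rate_change`,
#'   `nonfiring0`, `nonfiring1`.
#' @export
diagram_delta <- function(d0, d1) {
  stopifnot(inherits(d0, "sweep_diagram"), inherits(d1, "sweep_diagram"))
  if (nrow(d0) != nrow(d1) ||
      any(abs(d0$g_CaL - d1$g_CaL) > 1e-12) ||
      any(abs(d0$P_up - d1$P_up) > 1e-12))
    stop("diagrams are not on identical grids")
  ok <- !d0$failed & !d1$failed
  f0 <- d0$class != "dormant" & ok
  f1 <- d1$class != "dormant" & ok
  both <- f0 & f1
  list(n_awakened = sum(!f0 & f1),
       n_silenced = sum(f0 & !f1),
       mean_rate_change = if (any(both)) mean(d1$rate[both] - d0$rate[both]) else NA_real_,
       nonfiring0 = sum(ok & !f0), nonfiring1 = sum(ok & !f1))
}

#' Write a sweep diagram as long-format CSV
#' @param diagram a `sweep_diagram`.
#' @param path output file.
#' @export
write_sweep_csv <- function(diagram, path) {
  write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep summary as JSON
#' @param diagram a `sweep_diagram`.
#' @param path output file.
#' @export
write_sweep_json <- function(diagram, path) {
  jsonlite::write_json(summary(diagram), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
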