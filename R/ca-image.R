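# Ca-imaging analysis: normalization, global-transient subtraction, local
# Ca-release (LCR) detection, and subthreshold Vm-Ca cross-correlation.

#' Ca movie container
#'
#' @param stack numeric T x H x W array of intensities (finite; raw movies
#'   must be nonnegative).
#' @param frame_interval frame interval, ms.
#' @param pixel_size pixel size, um.
#' @param mask optional logical H x W matrix of valid tissue pixels.
#' @param signed allow negative values (for derived movies such as dF/F0
#'   residuals).
#' @return a `ca_movie` object.
#' @export
ca_movie <- function(stack, frame_interval = 10, pixel_size = 1,
                     mask = NULL, signed = FALSE) {
  d <- dim(stack)
  if (length(d) != 3 || d[1] < 2) stop("stack must be a T x H x W array with T >= 2")
  if (any(!is.finite(stack)))
    stop("intensities must be finite and nonnegative")
  if (!signed && any(stack < 0))
    stop("intensities must be finite and nonnegative")
  if (!is.null(mask) && !identical(dim(mask), d[2:3]))
    stop("mask must be H x W")
  structure(list(stack = stack, frame_interval = frame_interval,
                 pixel_size = pixel_size, mask = mask),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<ca_movie> %d frames of %d x %d px (%g ms/frame, %g um/px)\n",
              d[1], d[2], d[3], x$frame_interval, x$pixel_size))
  invisible(x)
}

#' Read / write multi-page TIFF movies
#'
#' @param path TIFF file.
#' @param frame_interval,pixel_size,mask passed to [ca_movie()].
#' @export
read_ca_tiff <- function(path, frame_interval = 10, pixel_size = 1,
                         mask = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- aperm(simplify2array(pages), c(3, 1, 2))
  ca_movie(stack, frame_interval, pixel_size, mask)
}

#' @rdname read_ca_tiff
#' @param movie a `ca_movie` (intensities are rescaled to [0, 1] on write).
#' @export
write_ca_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  mx <- max(movie$stack)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(movie$stack)[1]),
                  function(t) movie$stack[t, , ] / mx)
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Normalize a movie to dF/F0
#'
#' Per-pixel baseline F0 is a low percentile of the pixel's time course
#' (default 10th); output is (F - F0)/F0. Pixels with F0 = 0 (and pixels
#' outside the mask) are excluded from the valid mask of the result.
#'
#' @param movie a `ca_movie`.
#' @param probs baseline percentile in `[0, 1)`.
#' @return a `ca_movie` of dF/F0 values, with updated `mask` and the F0 map
#'   as attribute `F0`.
#' @export
normalize_movie <- function(movie, probs = 0.1) {
  stopifnot(inherits(movie, "ca_movie"))
  if (all(movie$stack == 0)) stop("all-zero movie: F0 is not estimable")
  d <- dim(movie$stack)
  flat <- matrix(movie$stack, nrow = d[1]) # T x (H*W)
  f0 <- apply(flat, 2, quantile, probs = probs, names = FALSE)
  valid <- f0 > 0
  if (!is.null(movie$mask)) valid <- valid & as.vector(movie$mask)
  norm <- flat
  norm[, valid] <- sweep(sweep(flat[, valid, drop = FALSE], 2, f0[valid]),
                         2, f0[valid], "/")
  norm[, !valid] <- 0
  out <- movie
  out$stack <- array(norm, d)
  out$mask <- matrix(valid, d[2], d[3])
  attr(out, "F0") <- matrix(f0, d[2], d[3])
  out$normalized <- TRUE
  out
}

#' Subtract the global (principal-component) transient
#'
#' Computes the leading principal component(s) of the pixel x time matrix
#' (valid pixels only), reconstructs the rank-`k` global AP-induced Ca
#' transient signal (one spatial gain map x one time course for `k = 1`) and
#' returns the residual movie together with the global component. The
#' residual retains local Ca releases and other background signals.
#'
#' @param movie a normalized `ca_movie` (see [normalize_movie()]).
#' @param k number of components to subtract (default 1, the principal
#'   component).
#' @return list with `residual` (a `ca_movie`), `global` (reconstructed
#'   rank-k movie), `time_course` (T x k), `spatial_map` (H x W x k, gain
#'   maps) and `var_share` (fraction of variance captured per component).
#' @export
subtract_global_component <- function(movie, k = 1) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$stack)
  flat <- matrix(movie$stack, nrow = d[1]) # T x P
  valid <- if (is.null(movie$mask)) rep(TRUE, ncol(flat)) else as.vector(movie$mask)
  x <- flat[, valid, drop = FALSE]
  if (ncol(x) == 0) stop("no valid pixels")
  if (all(abs(x) < 1e-300)) stop("degenerate (rank-0) movie")
  sv <- svd(x, nu = k, nv = k)
  if (sv$d[1] <= 0) stop("degenerate (rank-0) movie")
  recon <- sv$u %*% (t(sv$v) * sv$d[seq_len(k)])
  res <- flat
  res[, valid] <- x - recon
  glob <- matrix(0, nrow(flat), ncol(flat))
  glob[, valid] <- recon
  sm <- array(0, c(d[2], d[3], k))
  smv <- matrix(0, ncol(flat), k)
  smv[valid, ] <- sv$v %*% diag(sv$d[seq_len(k)], k)
  residual <- movie
  residual$stack <- array(res, d)
  global <- movie
  global$stack <- array(glob, d)
  list(residual = residual, global = global,
       time_course = sv$u,
       spatial_map = array(smv, c(d[2], d[3], k)),
       var_share = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Detect local Ca releases in a residual movie
#'
#' Thresholds the residual at `k_mad` times each pixel's robust noise scale
#' (median absolute deviation of its time course), labels 26-connected
#' (x, y, t) components of supra-threshold voxels, and filters them by
#' minimum spatial footprint and duration. The size of each event is its
#' path area: the area of the 2-D spatial projection of the component, i.e.
#' the full territory swept by the release as it propagates.
#'
#' @param residual a `ca_movie` (residual after
#'   [subtract_global_component()]).
#' @param k_mad threshold multiplier.
#' @param min_area minimum path area, px^2.
#' @param min_duration minimum duration, frames.
#' @return data.frame of class `lcr_events`: one row per event with
#'   `start_frame`, `end_frame` (1-based), `path_area_px`, `path_area_um2`,
#'   `peak_dff`, `centroid_x`, `centroid_y` (0-based pixel coordinates).
#' @export
detect_lcrs <- function(residual, k_mad = 3, min_area = 4, min_duration = 2) {
  stopifnot(inherits(residual, "ca_movie"))
  d <- dim(residual$stack)
  flat <- matrix(residual$stack, nrow = d[1])
  ctr <- apply(flat, 2, median)
  flat <- sweep(flat, 2, ctr) # per-pixel robust centering
  sigma <- apply(flat, 2, mad)
  sigma[sigma <= 0] <- Inf
  thresh <- sweep(flat, 2, k_mad * sigma, ">")
  if (!is.null(residual$mask))
    thresh[, !as.vector(residual$mask)] <- FALSE
  vox <- which(thresh) # linear indices into T x (H*W)
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      path_area_px = numeric(0), path_area_um2 = numeric(0),
                      peak_dff = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  class(empty) <- c("lcr_events", "data.frame")
  if (!length(vox)) return(empty)
  tt <- (vox - 1) %% d[1] + 1
  pix <- (vox - 1) %/% d[1] + 1
  yy <- (pix - 1) %% d[2] + 1
  xx <- (pix - 1) %/% d[2] + 1
  lab <- label_components_3d(tt, yy, xx, dims = c(d[1], d[2], d[3]))
  rows <- lapply(split(seq_along(vox), lab), function(idx) {
    fr <- tt[idx]
    foot <- unique(pix[idx])
    area <- length(foot)
    dur <- max(fr) - min(fr) + 1
    if (area < min_area || dur < min_duration) return(NULL)
    vals <- flat[vox[idx]]
    data.frame(start_frame = min(fr), end_frame = max(fr),
               path_area_px = area,
               path_area_um2 = area * residual$pixel_size^2,
               peak_dff = max(vals),
               centroid_x = mean(xx[idx]) - 1,
               centroid_y = mean(yy[idx]) - 1)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lcr_events", "data.frame")
  out
}

# 26-connected component labelling of sparse voxels (t, y, x).  Union-find
# over a hash of occupied voxels; linear in voxels x 26 neighbours.
label_components_3d <- function(tt, yy, xx, dims) {
  n <- length(tt)
  key <- (tt - 1) + dims[1] * ((yy - 1) + dims[2] * (xx - 1))
  idx_of <- new.env(hash = TRUE, parent = emptyenv(), size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx_of)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off <- as.matrix(expand.grid(dt = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(off))) {
      t2 <- tt[i] + off[r, 1]; y2 <- yy[i] + off[r, 2]; x2 <- xx[i] + off[r, 3]
      if (t2 < 1 || t2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          x2 < 1 || x2 > dims[3]) next
      k2 <- as.character((t2 - 1) + dims[1] * ((y2 - 1) + dims[2] * (x2 - 1)))
      j <- idx_of[[k2]]
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Subthreshold Vm-Ca cross-correlation
#'
#' Linearly detrends both traces over the window and computes the normalized
#' cross-correlation over lags up to `max_lag` ms. With
#' `subthreshold = TRUE` the window must end before the first AP in
#' `ap_times` -- after the first AP the correlation is dominated by the
#' AP/Ca-transient pairing and is strong regardless of coupling, so it no
#' longer reflects subthreshold coupling.
#'
#' @param vm,ca co-sampled traces.
#' @param time sample times, s (uniform grid).
#' @param window `c(t0, t1)` analysis window, s.
#' @param max_lag maximum lag, ms.
#' @param subthreshold enforce the pre-first-AP guard.
#' @param ap_times AP times, s (required when `subthreshold = TRUE` and
#'   checked against the window).
#' @return list with `lag_ms` (positive lag = Ca follows Vm), `ccf` (values
#'   in `[-1, 1]`), `peak`, `peak_lag_ms`.
#' @export
vm_ca_crosscorr <- function(vm, ca, time, window = range(time),
                            max_lag = 500, subthreshold = FALSE,
                            ap_times = NULL) {
  if (length(vm) != length(time) || length(ca) != length(time))
    stop("vm, ca and time must be co-sampled")
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 8) stop("window too short")
  if (subthreshold) {
    if (is.null(ap_times)) stop("ap_times required when subthreshold = TRUE")
    first_ap <- if (length(ap_times)) min(ap_times) else Inf
    if (window[2] > first_ap)
      stop("subthreshold window must end before the first AP (at ",
           signif(first_ap, 4), " s)")
  }
  t_w <- time[keep]
  dt_s <- median(diff(t_w))
  x <- residuals(lm(vm[keep] ~ t_w))
  y <- residuals(lm(ca[keep] ~ t_w))
  nl <- min(floor(max_lag / 1000 / dt_s), length(x) - 2)
  cc <- ccf(x, y, lag.max = nl, plot = FALSE, demean = TRUE)
  vals <- as.numeric(cc$acf)
  # ccf(x, y) at lag k correlates x[t+k] with y[t]; flip the axis so that a
  # positive lag means the Ca trace follows the Vm trace
  lags <- -as.numeric(cc$lag) * dt_s * 1000
  i <- which.max(abs(vals))
  list(lag_ms = lags, ccf = vals, peak = vals[i], peak_lag_ms = lags[i])
}

#' Write LCR events as CSV
#' @param events an `lcr_events` data.frame.
#' @param path output file.
#' @export
write_lcr_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
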