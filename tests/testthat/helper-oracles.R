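# Shared helpers: independent oracles and fixtures built in code.

# dormant-zone fixture used throughout: mid-dormant at g_CaL = 0.37
dormant_params <- function(P_up = 5) cell_params(g_CaL = 0.37, P_up = P_up)

# count APs over a window (s) of a sim_result
sim_ap_count <- function(sim, window) {
  tr <- detect_aps(sim$V_m, sim$time)
  sum(tr$times >= window[1] & tr$times <= window[2])
}

# brute-force firing metrics from an interval list (independent of
# firing_metrics internals)
brute_metrics <- function(times) {
  iv <- diff(times)
  f <- 1 / iv
  list(rate = mean(f), cv = sd(f) / mean(f))
}

# match detected LCR events against a generator truth table: an event matches
# a truth entry if it overlaps in time (+/- 1 frame) and its centroid falls in
# the truth footprint's bounding box (+/- `slack` px)
lcr_match <- function(events, truth, footprints, H, slack = 3) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(j) {
    px <- footprints[[j]]
    xs <- (px - 1) %/% H
    ys <- (px - 1) %% H
    any(events$start_frame <= truth$end_frame[j] + 1 &
        events$end_frame >= truth$start_frame[j] - 1 &
        events$centroid_x >= min(xs) - slack &
        events$centroid_x <= max(xs) + slack &
        events$centroid_y >= min(ys) - slack &
        events$centroid_y <= max(ys) + slack)
  }, logical(1))
  hit_event <- vapply(seq_len(nrow(events)), function(i) {
    any(vapply(seq_len(nrow(truth)), function(j) {
      px <- footprints[[j]]
      xs <- (px - 1) %/% H
      ys <- (px - 1) %% H
      events$start_frame[i] <= truth$end_frame[j] + 1 &&
        events$end_frame[i] >= truth$start_frame[j] - 1 &&
        events$centroid_x[i] >= min(xs) - slack &&
        events$centroid_x[i] <= max(xs) + slack &&
        events$centroid_y[i] >= min(ys) - slack &&
        events$centroid_y[i] <= max(ys) + slack
    }, logical(1)))
  }, logical(1))
  list(recall = mean(hit_truth), precision = mean(hit_event))
}

# build a synthetic Vm trace (mV) with rectangular AP-like spikes of given
# upstroke times (s), plateau level and duration (ms), on a dt_s grid
spike_trace <- function(duration, ap_times, dt_s = 0.001, base = -60,
                        peak = 20, width_ms = 60) {
  t <- seq(0, duration, by = dt_s)
  vm <- rep(base, length(t))
  for (t0 in ap_times) {
    vm[t >= t0 & t < t0 + width_ms / 1000] <- peak
  }
  list(time = t, vm = vm)
}
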