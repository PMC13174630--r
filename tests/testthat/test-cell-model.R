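test_that("fully decoupled system has zero derivatives", {
  zero <- c("g_CaL", "g_CaT", "g_Kr", "g_Ks", "g_to", "g_sus", "g_if",
            "g_st", "g_bNa", "i_NaK_max", "k_NCX", "g_KACh", "P_up", "k_s",
            "k_oCa", "k_iCa", "k_im", "k_om",
            "kf_TC", "kb_TC", "kf_TMC", "kb_TMC", "kf_TMM", "kb_TMM",
            "kf_CM", "kb_CM", "kf_CQ", "kb_CQ")
  ov <- as.list(setNames(rep(0, length(zero)), zero))
  ov$tau_dif_Ca <- Inf; ov$tau_tr <- Inf # zero transfer/diffusion rates
  p <- do.call(cell_params, ov)
  st <- initial_state()
  # gating variables relax toward their steady states; put each at its
  # steady state by evaluating the derivative and checking only the
  # non-gating variables, which must be exactly 0
  d <- derivatives(st, p)$dstate
  conc <- c("V_m", "Ca_i", "Ca_sub", "Ca_nSR", "Ca_jSR",
            "R_ryr", "O_ryr", "I_ryr",
            "f_CMi", "f_CMs", "f_TC", "f_TMC", "f_TMM", "f_CQ")
  expect_true(all(abs(d[conc]) == 0))
})

test_that("dV/dt is linear in the injected current with the depolarizing sign", {
  p <- cell_params()
  st <- initial_state()
  d0 <- derivatives(st, p, i_inject = 0)$dstate[["V_m"]]
  d10 <- derivatives(st, p, i_inject = 10)$dstate[["V_m"]]
  expect_equal(d10 - d0, 10 / p[["C_m"]], tolerance = 1e-12)
})

test_that("total current equals the sum of one-current-at-a-time contributions", {
  # brute-force oracle: enable one conductance at a time over a silent
  # membrane; contributions must sum to the full model's I_tot
  p <- cell_params()
  st <- initial_state()
  conds <- c("g_CaL", "g_CaT", "g_Kr", "g_Ks", "g_to", "g_sus", "g_if",
             "g_st", "g_bNa", "i_NaK_max", "k_NCX")
  p_off <- do.call(cell_params,
                   c(as.list(setNames(rep(0, length(conds)), conds)),
                     list(g_KACh = 0.002)))
  base_tot <- derivatives(st, p_off)$currents[["I_tot"]] # I_KACh only
  contrib <- vapply(conds, function(g) {
    off <- setdiff(conds, g)
    ov <- as.list(setNames(rep(0, length(off)), off))
    ov$g_KACh <- 0.002
    ov[[g]] <- p[[g]]
    one <- do.call(cell_params, ov)
    derivatives(st, one)$currents[["I_tot"]] - base_tot
  }, numeric(1))
  full <- cell_params(g_KACh = 0.002)
  tot <- derivatives(st, full)$currents[["I_tot"]]
  expect_equal(tot, sum(contrib) + base_tot, tolerance = 1e-12)
})

test_that("derivatives rejects invalid input", {
  st <- initial_state()
  st[["V_m"]] <- NaN
  expect_error(derivatives(st, cell_params()), "non-finite")
})

test_that("identical seeds give bit-identical simulations", {
  p <- dormant_params()
  st <- protocol_noise_run(62.5, tail = 0.001)
  s1 <- simulate_cell(p, st, duration = 12, seed = 9)
  s2 <- simulate_cell(p, st, duration = 12, seed = 9)
  expect_identical(s1$V_m, s2$V_m)
  expect_identical(s1$Ca_sub, s2$Ca_sub)
  s3 <- simulate_cell(p, st, duration = 12, seed = 10)
  expect_false(identical(s1$V_m, s3$V_m))
  # without stochastic components the seed is irrelevant
  d1 <- simulate_cell(p, duration = 3, seed = 1)
  d2 <- simulate_cell(p, duration = 3, seed = 2)
  expect_identical(d1$V_m, d2$V_m)
})

test_that("basal model fires rhythmically and dormant-zone model is silent", {
  sim <- simulate_cell(cell_params(), duration = 20)
  m <- firing_metrics(detect_aps(sim$V_m, sim$time), c(5, 20))
  expect_gt(m$rate, 2)
  expect_lt(m$rate, 4)
  expect_lt(m$cv, 0.05)
  # the published dormant-zone point: g_CaL = 0.37, P_up = 1, no stimulus
  # (after the standard 5 s settling discard; the shipped initial state is a
  # firing-cell state, so the very first cycle can still produce one AP)
  d <- simulate_cell(cell_params(g_CaL = 0.37, P_up = 1), duration = 20)
  expect_equal(sim_ap_count(d, c(5, 20)), 0)
  # it oscillates subthreshold rather than resting flat
  late <- d$V_m[d$time > 10]
  expect_gt(diff(range(late)), 2)
  expect_lt(max(late), 0)
})

test_that("gates stay in [0,1] and concentrations nonnegative across protocols", {
  p <- dormant_params()
  protos <- list(NULL, protocol_noise_run(125, tail = 0.001),
                 stimulus_trace(sine_segment(50, 2, 12)))
  for (st in protos) {
    sim <- simulate_cell(p, st, duration = 12, seed = 3,
                         record_states = TRUE)
    states <- sim$states
    colnames(states) <- names(initial_state())
    conc <- states[, c("Ca_i", "Ca_sub", "Ca_nSR", "Ca_jSR")]
    expect_true(all(is.finite(states)))
    expect_true(all(conc >= 0))
    gates <- states[, c("d_L", "f_L", "f_Ca", "d_T", "f_T", "pa_F", "pa_S",
                        "pi_y", "n", "q", "r", "y", "q_a", "q_i",
                        "f_CMi", "f_CMs", "f_TC", "f_TMC", "f_TMM", "f_CQ")]
    expect_true(all(gates >= 0 & gates <= 1))
  }
})

test_that("stochastic LCR forcing produces subthreshold Ca-coupled fluctuations", {
  p <- dormant_params(P_up = 1)
  s0 <- simulate_cell(p, duration = 12, seed = 4)
  s1 <- simulate_cell(p, duration = 12, seed = 4, stochastic_lcr = TRUE)
  # forcing raises submembrane Ca variability without triggering APs
  late <- function(x, tm) x[tm > 6]
  expect_gt(sd(late(s1$Ca_sub, s1$time)), sd(late(s0$Ca_sub, s0$time)))
  expect_equal(sim_ap_count(s1, c(5, 12)), sim_ap_count(s0, c(5, 12)))
  # and the induced Vm and Ca fluctuations are correlated
  xc <- vm_ca_crosscorr(s1$V_m, s1$Ca_sub, s1$time, window = c(6, 12),
                        max_lag = 200)
  expect_gt(abs(xc$peak), 0.2)
})

test_that("an explicit-solver blow-up is reported with the offending time", {
  expect_error(simulate_cell(cell_params(), duration = 2, dt = 0.5),
               "blow-up at t")
})

test_that("compiled integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- cell_params()
  st <- initial_state()
  rhs <- function(t, y, parms) {
    list(unname(sansr:::cm_derivs(y, unclass(p), 0)$dstate) * 1000) # per s
  }
  out <- deSolve::lsoda(unname(st), seq(0, 0.5, by = 0.001), rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  sim <- simulate_cell(p, duration = 0.5, dt = 0.002, record_dt = 1)
  vm_ref <- out[, 2]
  # trajectories track each other closely over half a second
  expect_lt(max(abs(vm_ref - sim$V_m)), 1.5)
  expect_equal(cor(vm_ref, sim$V_m), 1, tolerance = 1e-4)
})
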