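flat_params <- function(p_fusion = 0.22, kappa = 0, y_inc = 0) {
  list(
    priming = priming_parameters(p_fusion = p_fusion, N_total = 2622,
                                 k1_rest = 0.370, b1 = 0.221, sigma1 = 0,
                                 k2_rest = 0.199, b2 = 0.253, sigma2 = 0,
                                 tau_TSL = 0.09, kappa_TSL = kappa,
                                 b4 = 2.6, ca_rest = 5e-8),
    transient = ctrl_tp,
    influx = influx_dynamics_parameters(y_inc = y_inc, z_dec = 0,
                                        y_max = 1.31, z_min = 0.87,
                                        tau_y = 0.017, tau_z = 3,
                                        p_cooperativity = 0)
  )
}

test_that("first response equals p_fusion times the resting tight pool", {
  res <- simulate_train(ctrl, ctrl_tp, ctrl_idp, stimulus_protocol(100),
                        keep_trajectory = FALSE)
  ts_eq <- unname(equilibrium_occupancy(ctrl)["TS"])
  expect_equal(res$m[1], ctrl$p_fusion * ts_eq, tolerance = 1e-12)
  expect_equal(res$m[1], 190, tolerance = 0.005)
  expect_equal(res$p_fusion_j[1], ctrl$p_fusion)
})

test_that("zero fusion probability releases nothing", {
  fp <- flat_params(p_fusion = 0)
  res <- simulate_train(fp$priming, fp$transient, fp$influx,
                        stimulus_protocol(100, n_stim = 10),
                        keep_trajectory = FALSE)
  expect_equal(res$m, rep(0, 10))
  # with no fusion, no transfer and no transient drive, the state rests
  tp0 <- ca_transient_parameters(mode = "control_biexp", amp_global = 0,
                                 tau_fast = 0.06, tau_slow = 0.23,
                                 f_slow = 0.15)
  res0 <- simulate_train(fp$priming, tp0, fp$influx,
                         stimulus_protocol(100, n_stim = 10))
  eq <- unclass(equilibrium_occupancy(fp$priming))
  final <- res0$final$state
  expect_equal(unname(final), unname(eq), tolerance = 1e-8)
})

test_that("site conservation holds along whole trajectories", {
  for (cond in c("control", "pdbu")) {
    ps <- preset_parameters(cond, "all")
    for (f in c(10, 200)) {
      res <- simulate_train(ps$priming, ps$transient, ps$influx,
                            stimulus_protocol(f), keep_trajectory = TRUE)
      tot <- rowSums(res$state_trajectory[, c("ES", "LS", "TS", "TSL",
                                              "ERS")])
      expect_lt(max(abs(tot - ps$priming$N_total)) / ps$priming$N_total,
                1e-6)
      expect_true(all(res$state_trajectory[, -1] > -1e-6))
      expect_true(all(res$m >= 0))
    }
  }
})

test_that("pure depression: quantal contents decrease monotonically", {
  # without calcium sensitivity, labile transfer and influx facilitation,
  # and with fused sites removed from the cycle, depletion is strict
  fp <- flat_params()
  fields <- unclass(fp$priming); fields$b4 <- 0
  sink <- do.call(priming_parameters, fields)
  for (f in c(10, 100)) {
    res <- simulate_train(sink, fp$transient, fp$influx,
                          stimulus_protocol(f), keep_trajectory = FALSE)
    expect_true(all(diff(res$m) < 0))
  }
  # with site recycling the approach to steady state carries a weakly
  # damped mode; any rebound stays far below the depression itself
  for (f in c(10, 100)) {
    res <- simulate_train(fp$priming, fp$transient, fp$influx,
                          stimulus_protocol(f), keep_trajectory = FALSE)
    expect_lt(max(diff(res$m)) / res$m[1], 0.005)
    expect_lt(res$m[40], 0.5 * res$m[1])
  }
})

test_that("control parameters give net paired-pulse facilitation at 200 Hz", {
  res <- simulate_train(ctrl, ctrl_tp, ctrl_idp, stimulus_protocol(200),
                        keep_trajectory = FALSE)
  expect_gt(res$m[2] / res$m[1], 1)
})

test_that("influx scale update and relaxation follow the stated recursion", {
  idp <- ctrl_idp
  # single action potential from rest, no relaxation
  up <- update_influx_scales(idp, 1, 1, isi = 0)
  expect_equal(up$y, 1 + 0.39 * (1.31 - 1))   # 1.1209
  expect_equal(up$z, 1 - 0.4 * (1 - 0.87))
  # full relaxation at infinite interval
  expect_equal(update_influx_scales(idp, 1.2, 0.9, isi = Inf),
               list(y = 1, z = 1))
  # inert dynamics stay at unity
  idp0 <- influx_dynamics_parameters(0, 0, 1.31, 0.87, 0.017, 3)
  expect_equal(update_influx_scales(idp0, 1, 1, isi = 0.01),
               list(y = 1, z = 1))
})

test_that("solutions are independent of the integrator step size", {
  a <- simulate_train(ctrl, ctrl_tp, ctrl_idp, stimulus_protocol(200),
                      keep_trajectory = FALSE, rtol = 1e-10)
  b <- simulate_train(ctrl, ctrl_tp, ctrl_idp, stimulus_protocol(200),
                      keep_trajectory = FALSE, rtol = 5e-11)
  expect_lt(max(abs(a$m / b$m - 1)), 1e-4)
})

test_that("long unstimulated integration converges to the closed form", {
  for (cond in preset_conditions()) {
    pp <- preset_parameters(cond)
    start <- c(ES = pp$N_total * 0.5, LS = 0, TS = pp$N_total * 0.3,
               TSL = pp$N_total * 0.1, ERS = pp$N_total * 0.1)
    settled <- settle_state(pp, start, duration = 300)
    eq <- unclass(equilibrium_occupancy(pp))
    expect_lt(max(abs(settled[1:3] - eq[1:3]) / eq[1:3]), 1e-6)
  }
})

test_that("release is robust to the assumed resting empty-site fraction", {
  # rescale k1 (and sites) so that k1 * ES(rest) is unchanged while the
  # empty fraction spans 15-30%
  base <- simulate_train(ctrl, ctrl_tp, ctrl_idp, stimulus_protocol(100),
                         keep_trajectory = FALSE)
  r2 <- ctrl$k2_rest / ctrl$b2
  flux <- ctrl$k1_rest * unname(equilibrium_occupancy(ctrl)["ES"])
  for (es_frac in c(0.15, 0.30)) {
    r1 <- (1 / es_frac - 1) / (1 + r2)
    k1 <- r1 * ctrl$b1
    es_count <- flux / k1
    fields <- unclass(ctrl)
    fields$k1_rest <- k1
    fields$N_total <- es_count / es_frac
    pp <- do.call(priming_parameters, fields)
    res <- simulate_train(pp, ctrl_tp, ctrl_idp, stimulus_protocol(100),
                          keep_trajectory = FALSE)
    expect_lt(max(abs(res$m[1:10] / base$m[1:10] - 1)), 0.10)
  }
})

test_that("steady-state release follows its two conventions", {
  expect_equal(steady_state_release(rep(7, 40), "last"), 7)
  expect_equal(steady_state_release(rep(7, 40), "mean_last5"), 7)
  expect_equal(steady_state_release(40:1, "last"), 1)
  expect_equal(steady_state_release(40:1, "mean_last5"), mean(5:1))
  m <- runif(40, 10, 20)
  ml5 <- steady_state_release(m, "mean_last5")
  expect_true(ml5 >= min(m[36:40]) && ml5 <= max(m[36:40]))
  expect_error(steady_state_release(1:20, "mean_last5"), "40")
})

test_that("recovery after conditioning rises monotonically to completion", {
  rec <- simulate_recovery(ctrl, ctrl_tp, ctrl_idp,
                           stimulus_protocol(200),
                           test_intervals = c(0.25, 1, 4, 16))
  expect_true(all(diff(rec$recovered_fraction) > 0))
  expect_gt(rec$recovered_fraction[4], 0.95)
  expect_lt(rec$recovered_fraction[4], 1.05)
})

test_that("fast recovery component appears only after high-frequency trains", {
  r200 <- simulate_recovery(ctrl, ctrl_tp, ctrl_idp,
                            stimulus_protocol(200),
                            test_intervals = c(0.25, 0.5))
  r20 <- simulate_recovery(ctrl, ctrl_tp, ctrl_idp,
                           stimulus_protocol(20),
                           test_intervals = c(0.25, 0.5))
  expect_gt(r200$recovered_fraction[1], r20$recovered_fraction[1])
})

test_that("protocols validate their fields", {
  expect_error(stimulus_protocol(0), "f_stim")
  expect_error(stimulus_protocol(10, n_stim = 0), "n_stim")
  expect_error(stimulus_protocol(10, recovery_tests = c(1, 0.5)),
               "increasing")
  expect_error(simulate_train(ctrl, ctrl_tp, ctrl_idp,
                              stimulus_protocol(10, n_stim = 2),
                              initial_state = c(ES = -1, LS = 0, TS = 0,
                                                TSL = 0, ERS = 0)),
               "initial state")
  expect_error(simulate_recovery(ctrl, ctrl_tp, ctrl_idp,
                                 stimulus_protocol(200, n_stim = 3),
                                 test_intervals = 1), "at least 5")
})

test_that("preconditioned protocols carry their burst before the train", {
  proto <- stimulus_protocol(200, precondition = list(n_pre = 4))
  res <- simulate_train(ctrl, ctrl_tp, ctrl_idp, proto,
                        keep_trajectory = FALSE)
  expect_length(res$m, 40)
  expect_length(res$m_all, 44)
  expect_equal(res$main_index, 5:44)
  expect_equal(res$stimulus_times[1:4], c(0, 0.1, 0.2, 0.3))
})
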