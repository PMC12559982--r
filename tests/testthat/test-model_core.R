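test_that("priming rates are linear in calcium and clamped at zero", {
  k <- priming_rates(ctrl, ctrl$ca_rest)
  expect_equal(k$k1, 0.370)
  expect_equal(k$k2, 0.199)

  # direct substitution at 438 nM
  k438 <- priming_rates(ctrl, 438e-9)
  expect_equal(k438$k1, 0.370 + 2.245e6 * 388e-9, tolerance = 1e-10)
  expect_equal(k438$k2, 0.199 + 1.014e6 * 388e-9, tolerance = 1e-10)
  expect_equal(round(k438$k1, 4), 1.2411)
  expect_equal(round(k438$k2, 4), 0.5924)

  # slope-free parameters are calcium independent
  flat <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1,
                             b1 = 0.5, sigma1 = 0, k2_rest = 2, b2 = 0.5,
                             sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                             b4 = 1, ca_rest = 5e-8)
  expect_equal(priming_rates(flat, 1e-6), list(k1 = 1, k2 = 2))

  # rates stay physical below resting calcium
  low <- priming_rates(ctrl, 0)
  expect_true(low$k1 >= 0 && low$k2 >= 0)
  expect_equal(low$k1, max(0, 0.370 - 2.245e6 * 5e-8))

  expect_error(priming_rates(ctrl, -1e-9), "ca")
})

test_that("equilibrium occupancy matches the closed-form state ratios", {
  eq <- equilibrium_occupancy(ctrl, 50e-9)
  frac <- unclass(eq) / ctrl$N_total
  # 1 : k1/b1 : (k1/b1)(k2/b2), normalised
  r1 <- 0.370 / 0.221; r2 <- 0.199 / 0.253
  expect_equal(unname(frac["ES"]), 1 / (1 + r1 + r1 * r2), tolerance = 1e-10)
  expect_equal(round(unname(frac[c("ES", "LS", "TS")]), 4),
               c(0.2506, 0.4195, 0.3300))
  expect_equal(unname(frac["TSL"]), 0)
  expect_equal(unname(frac["ERS"]), 0)
  expect_equal(sum(eq), ctrl$N_total)

  # ~25% empty sites at rest
  expect_equal(unname(frac["ES"]), 0.25, tolerance = 0.01)

  # no tight docking without a forward rate
  p0 <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1,
                           b1 = 1, sigma1 = 0, k2_rest = 0, b2 = 0.5,
                           sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                           b4 = 1, ca_rest = 5e-8)
  expect_equal(unname(equilibrium_occupancy(p0)["TS"]), 0)

  # degenerate backward rates resolve as limits, not crashes
  pb1 <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1,
                            b1 = 0, sigma1 = 0, k2_rest = 1, b2 = 0.5,
                            sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                            b4 = 1, ca_rest = 5e-8)
  eb1 <- equilibrium_occupancy(pb1)
  expect_equal(unname(eb1[["ES"]]), 0)
  expect_equal(sum(eb1), 100)
  pb2 <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1,
                            b1 = 0.5, sigma1 = 0, k2_rest = 1, b2 = 0,
                            sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                            b4 = 1, ca_rest = 5e-8)
  expect_equal(unname(equilibrium_occupancy(pb2)[["TS"]]), 100)
})

test_that("occupancies increase monotonically with calcium", {
  cas <- seq(50e-9, 500e-9, length.out = 25)
  ts <- vapply(cas, function(ca)
    unname(equilibrium_occupancy(ctrl, ca)["TS"]), numeric(1))
  frp <- vapply(cas, function(ca) frp_fraction(ctrl, ca), numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_true(all(diff(frp) > 0))
})

test_that("half-maximum TS occupancy is reached near 438 nM", {
  hm <- half_max_ca(ctrl)
  expect_equal(hm * 1e9, 438, tolerance = 0.005)
  # the root satisfies its defining equation
  ts0 <- unname(equilibrium_occupancy(ctrl, 5e-8)["TS"])
  target <- ts0 + 0.5 * (ctrl$N_total - ts0)
  expect_equal(unname(equilibrium_occupancy(ctrl, hm)["TS"]), target,
               tolerance = 1e-5)

  # saturated parameters return the reference concentration
  sat <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1,
                            b1 = 0, sigma1 = 0, k2_rest = 1, b2 = 0,
                            sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                            b4 = 1, ca_rest = 5e-8)
  expect_equal(half_max_ca(sat), 5e-8)

  # a flat TS curve cannot bracket the target
  flat <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1,
                             b1 = 0.5, sigma1 = 0, k2_rest = 1, b2 = 0.5,
                             sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                             b4 = 1, ca_rest = 5e-8)
  expect_error(half_max_ca(flat), "bracket")
})

test_that("fast-releasing pool fraction and its calcium dependence", {
  expect_equal(round(frp_fraction(ctrl, 50e-9), 4), 0.7494)
  # ~22% smaller pool at rest than at 500 nM
  red <- 1 - frp_fraction(ctrl, 50e-9) / frp_fraction(ctrl, 500e-9)
  expect_equal(red, 0.22, tolerance = 0.015)
  # overwhelming docking rate fills every site
  fast <- priming_parameters(p_fusion = 0.2, N_total = 100, k1_rest = 1e9,
                             b1 = 0.5, sigma1 = 0, k2_rest = 1, b2 = 0.5,
                             sigma2 = 0, tau_TSL = 0.1, kappa_TSL = 0,
                             b4 = 1, ca_rest = 5e-8)
  expect_equal(frp_fraction(fast), 1, tolerance = 1e-8)
})

test_that("Michaelis-Menten influx ratio", {
  expect_equal(influx_ratio_mm(1.5, 2.0, 2.6), 1.19, tolerance = 0.005)
  expect_equal(influx_ratio_mm(1.7, 1.7, 2.6), 1.0)
  expect_equal(influx_ratio_mm(1.5, 2.0, 0), 1.0)
  expect_error(influx_ratio_mm(0, 2), "> 0")
})

test_that("effective calcium transient evaluates and integrates correctly", {
  tp <- ctrl_tp
  rest <- ctrl$ca_rest
  # no stimuli: resting calcium everywhere
  expect_equal(effective_ca(tp, rest, numeric(0), t = c(0, 1)),
               rep(rest, 2))
  # before the first stimulus: exactly resting
  expect_equal(effective_ca(tp, rest, ap_times = 1, t = 0.5), rest)
  # long after a stimulus: decayed back to rest
  expect_equal(effective_ca(tp, rest, ap_times = 0, t = 60), rest,
               tolerance = 1e-6)
  # transient never dips below rest
  tt <- seq(0, 0.5, by = 1e-3)
  ca <- effective_ca(tp, rest, ap_times = c(0, 0.1), t = tt)
  expect_true(all(ca >= rest))

  # additive mode superposes, reset mode keeps only the latest transient
  tp_reset <- ca_transient_parameters(
    mode = "local_plus_global", amp_global = tp$amp_global,
    tau_fast = tp$tau_fast, tau_slow = tp$tau_slow, f_slow = tp$f_slow,
    amp_local = tp$amp_local, tau_local = tp$tau_local,
    summation = "reset")
  t_probe <- 0.101
  add <- effective_ca(tp, rest, c(0, 0.1), t = t_probe)
  rst <- effective_ca(tp_reset, rest, c(0, 0.1), t = t_probe)
  one <- effective_ca(tp, rest, 0.1, t = t_probe)
  expect_equal(rst, one)
  expect_gt(add, rst)

  # closed-form time integrals: local = amp*tau, global = amp*(f*tau terms)
  int <- ca_transient_integral(tp)
  expect_equal(int$local, 3e-5 * 2.5e-4, tolerance = 1e-9)
  expect_equal(int$global, 4.54e-7 * (0.85 * 0.06 + 0.15 * 0.23),
               tolerance = 1e-9)
  # the local transient carries ~16% of the total calcium time integral
  expect_equal(int$local_share, 0.16, tolerance = 0.02)
})

test_that("parameter configs load with unit tags and validate", {
  cfg <- list(control = list(
    priming = list(p_fusion = 0.22, N_total = 2622, k1_rest = 0.370,
                   b1 = 0.221, sigma1 = 2.245e6, k2_rest = 0.199,
                   b2 = 0.253, sigma2 = 1.014e6, tau_TSL = 0.09,
                   kappa_TSL = 0.1, b4 = 2.6,
                   ca_rest = list(value = 50, unit = "nM")),
    transient = list(mode = "local_plus_global",
                     amp_global = list(value = 454, unit = "nM"),
                     tau_fast = 0.06, tau_slow = 0.23, f_slow = 0.15,
                     amp_local = list(value = 30, unit = "uM"),
                     tau_local = 2.5e-4),
    influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.31, z_min = 0.87,
                  tau_y = 0.017, tau_z = 3)))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  loaded <- load_model_config(path)
  expect_equal(loaded$control$priming$ca_rest, 5e-8)
  expect_equal(loaded$control$transient$amp_local, 3e-5)
  expect_equal(unclass(loaded$control$priming), unclass(ctrl))

  # the shipped example config reproduces the packaged control preset
  shipped <- system.file("extdata", "control_parameters.yaml",
                         package = "calyxstp")
  sc <- load_model_config(shipped)$control
  expect_equal(unclass(sc$priming), unclass(ctrl))
  expect_equal(unclass(sc$transient), unclass(ctrl_tp))
  expect_equal(unclass(sc$influx), unclass(ctrl_idp))

  cfg$control$priming$ca_rest <- list(value = 50, unit = "furlong")
  yaml::write_yaml(cfg, path)
  expect_error(load_model_config(path), "unit")
  expect_error(load_model_config("no/such/file.yaml"), "not found")
})

test_that("parameter constructors reject unphysical values", {
  expect_error(priming_parameters(p_fusion = 1.2, N_total = 100,
                                  k1_rest = 1, b1 = 1, sigma1 = 0,
                                  k2_rest = 1, b2 = 1, sigma2 = 0,
                                  tau_TSL = 0.1, kappa_TSL = 0, b4 = 1,
                                  ca_rest = 5e-8), "p_fusion")
  expect_error(influx_dynamics_parameters(0.4, 0.4, 0.9, 0.9, 0.02, 3),
               "y_max")
  expect_error(ca_transient_parameters(amp_global = 1e-7, tau_fast = -1,
                                       tau_slow = 0.2, f_slow = 0.1),
               "time constants")
})
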