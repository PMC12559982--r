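#' Stimulation protocol for train simulations
#'
#' Regular trains of `n_stim` stimuli at `f_stim`, optionally preceded by a
#' short low-frequency preconditioning burst (the paradigm used to probe
#' facilitation at 100 and 200 Hz), and optionally followed by single test
#' stimuli at increasing intervals to map recovery from depression.
#'
#' @param f_stim Train frequency (Hz), > 0.
#' @param n_stim Number of stimuli in the main train (default 40).
#' @param precondition `NULL` or a list with `n_pre` (number of
#'   preconditioning stimuli), `f_pre` (their frequency in Hz, default 10)
#'   and `gap` (interval between the last preconditioning stimulus and the
#'   first stimulus of the main train, in s; default continues the
#'   preconditioning rhythm, `1/f_pre`).
#' @param recovery_tests `NULL` or a strictly increasing numeric vector of
#'   intervals (s) after the last train stimulus at which single test
#'   stimuli are delivered (see [simulate_recovery()]).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(f_stim, n_stim = 40, precondition = NULL,
                              recovery_tests = NULL) {
  if (f_stim <= 0) stop("f_stim must be > 0")
  if (n_stim < 1) stop("n_stim must be >= 1")
  if (!is.null(precondition)) {
    if (is.null(precondition$f_pre)) precondition$f_pre <- 10
    if (is.null(precondition$gap)) precondition$gap <- 1 / precondition$f_pre
    if (is.null(precondition$n_pre) || precondition$n_pre < 1)
      stop("precondition$n_pre must be >= 1")
  }
  if (!is.null(recovery_tests)) {
    if (any(recovery_tests <= 0) ||
        (length(recovery_tests) > 1 && any(diff(recovery_tests) <= 0)))
      stop("recovery intervals must be positive and strictly increasing")
  }
  structure(list(f_stim = f_stim, n_stim = as.integer(n_stim),
                 precondition = precondition,
                 recovery_tests = recovery_tests),
            class = "stimulus_protocol")
}

# All stimulus onset times of a protocol (s), with the index of the first
# main-train stimulus attached.
.protocol_times <- function(protocol) {
  if (!is.null(protocol$precondition)) {
    pc <- protocol$precondition
    pre <- (seq_len(pc$n_pre) - 1) / pc$f_pre
    start <- pre[length(pre)] + pc$gap
  } else {
    pre <- numeric(0)
    start <- 0
  }
  main <- start + (seq_len(protocol$n_stim) - 1) / protocol$f_stim
  list(times = c(pre, main), main_start = length(pre) + 1L)
}

#' Per-stimulus update and inter-stimulus relaxation of the influx scales
#'
#' Applies the action-potential update `y <- y + y_inc*(y_max - y)`,
#' `z <- z - z_dec*(z - z_min)` and then relaxes both factors exponentially
#' towards 1 over the interval `isi` with time constants `tau_y`, `tau_z`.
#'
#' @param idp An [influx_dynamics_parameters()] object.
#' @param y,z Current facilitation/depression scale factors.
#' @param isi Interval over which to relax after the update (s); may be 0
#'   (no relaxation) or `Inf` (full return to 1).
#' @return A list with elements `y` and `z`.
#' @export
#' @examples
#' update_influx_scales(preset_parameters("control", "influx"), 1, 1, 0)$y
update_influx_scales <- function(idp, y, z, isi = 0) {
  stopifnot(inherits(idp, "influx_dynamics_parameters"), isi >= 0)
  y <- y + idp$y_inc * (idp$y_max - y)
  z <- z - idp$z_dec * (z - idp$z_min)
  .relax_yz(idp, y, z, isi)
}

.relax_yz <- function(idp, y, z, dt) {
  if (is.infinite(dt)) return(list(y = 1, z = 1))
  list(y = 1 + (y - 1) * exp(-dt / idp$tau_y),
       z = 1 - (1 - z) * exp(-dt / idp$tau_z))
}

.pfusion_j <- function(params, idp, y, z) {
  min(1, params$p_fusion * (y * z)^idp$p_cooperativity)
}

# Integrate the coupled ES/LS/TS system over one inter-stimulus segment.
# TSL and ERS decay independently (first-order) and are propagated in closed
# form; the calcium transient within the segment is a fixed sum of three
# exponentials with segment-start amplitudes `camp` = (local, global-fast,
# global-slow) and decay constants from the transient parameterisation.
.integrate_segment <- function(state, camp, params, tp, duration,
                               sample_times = NULL, rtol = 1e-10,
                               atol = NULL, ca_fixed = NULL) {
  if (is.null(atol)) atol <- 1e-8 * max(1, params$N_total)
  ctau <- c(tp$tau_local, tp$tau_fast, tp$tau_slow)
  b3 <- 1 / params$tau_TSL
  p <- params
  tsl0 <- state[["TSL"]]; ers0 <- state[["ERS"]]
  deriv <- function(t, y, parms) {
    ca <- if (is.null(ca_fixed))
      p$ca_rest + sum(camp * exp(-t / ctau)) else ca_fixed
    d <- ca - p$ca_rest
    k1 <- max(0, p$k1_rest + p$sigma1 * d)
    k2 <- max(0, p$k2_rest + p$sigma2 * d)
    dES <- -k1 * y[1] + p$b1 * y[2] + p$b4 * ers0 * exp(-p$b4 * t)
    dLS <- k1 * y[1] - (p$b1 + k2) * y[2] + p$b2 * y[3] +
      b3 * tsl0 * exp(-b3 * t)
    dTS <- k2 * y[2] - p$b2 * y[3]
    list(c(dES, dLS, dTS))
  }
  times <- sort(unique(c(0, sample_times, duration)))
  sol <- deSolve::lsoda(y = c(state[["ES"]], state[["LS"]], state[["TS"]]),
                        times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  tt <- sol[, 1]
  out <- cbind(ES = sol[, 2], LS = sol[, 3], TS = sol[, 4],
               TSL = tsl0 * exp(-b3 * tt), ERS = ers0 * exp(-p$b4 * tt))
  ca_out <- if (is.null(ca_fixed))
    p$ca_rest + drop(exp(-outer(tt, 1 / ctau)) %*% camp)
  else rep(ca_fixed, length(tt))
  neg <- which(out < -1e-6 * params$N_total, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf(
      "state %s negative beyond tolerance at t = %.6f s within segment",
      colnames(out)[neg[1, 2]], tt[neg[1, 1]]))
  list(times = tt, states = out, ca = ca_out,
       final = out[nrow(out), ], camp_final = camp * exp(-duration / ctau))
}

#' Simulate evoked release during a stimulus train
#'
#' Hybrid continuous/discrete simulation of the five-state priming/fusion
#' scheme. Between stimuli the state occupancies follow the coupled ODEs
#' with calcium-dependent forward rates, integrated with an adaptive solver
#' (relative tolerance `rtol`). At each stimulus time, in order: (1) the
#' quantal content `m_j = p_j * (TS + TSL)` is released, with
#' `p_j = min(1, p_fusion * (y*z)^p_cooperativity)` evaluated from the
#' influx scales immediately before the stimulus (so `p_1 = p_fusion` for a
#' train starting from rest); (2) TS and TSL are decremented by their fused
#' fractions and the refractory pool ERS is incremented by `m_j`; (3) a
#' fraction `kappa_TSL` of LS vesicles is transferred to the labile tight
#' state TSL; (4) the influx scales receive their per-stimulus update and
#' the stimulus' calcium transient is added with its amplitude scaled by the
#' updated `y*z`. Site conservation holds throughout. Quantal contents are
#' expected values (real numbers); stochastic sampling lives in the
#' synthetic-data generator.
#'
#' @param params A [priming_parameters()] object.
#' @param tp A [ca_transient_parameters()] object.
#' @param idp An [influx_dynamics_parameters()] object.
#' @param protocol A [stimulus_protocol()] object.
#' @param initial_state Optional named vector `(ES, LS, TS, TSL, ERS)`;
#'   defaults to the resting equilibrium.
#' @param rtol Relative tolerance of the ODE solver (default 1e-10).
#' @param keep_trajectory If `TRUE` (default), state and calcium
#'   trajectories are sampled on a regular grid of spacing `dt_sample`.
#' @param dt_sample Trajectory sampling interval (s), default 1 ms.
#' @return An object of class `simulation_result`: a list with `m` (quantal
#'   content of the main-train stimuli), `m_all` (including preconditioning
#'   stimuli), `p_fusion_j` (per-stimulus fusion probability),
#'   `stimulus_times`, `main_index`, `y_z_history` (influx scales
#'   immediately before each stimulus), `state_trajectory` / `ca_trace`
#'   (matrices, if kept), `at_last_stimulus` (state snapshot immediately
#'   after the last stimulus' discrete events, used to branch recovery
#'   continuations) and `final` (state one ISI after the last stimulus).
#' @export
#' @examples
#' res <- simulate_train(preset_parameters("control"),
#'                       preset_parameters("control", "transient"),
#'                       preset_parameters("control", "influx"),
#'                       stimulus_protocol(200), keep_trajectory = FALSE)
#' res$m[2] / res$m[1]  # paired-pulse ratio at 5 ms ISI
simulate_train <- function(params, tp, idp, protocol, initial_state = NULL,
                           rtol = 1e-10, keep_trajectory = TRUE,
                           dt_sample = 1e-3) {
  stopifnot(inherits(params, "priming_parameters"),
            inherits(tp, "ca_transient_parameters"),
            inherits(idp, "influx_dynamics_parameters"),
            inherits(protocol, "stimulus_protocol"))
  pt <- .protocol_times(protocol)
  ap_times <- pt$times
  n_ap <- length(ap_times)
  state <- if (is.null(initial_state)) {
    unclass(equilibrium_occupancy(params, params$ca_rest))
  } else {
    s <- initial_state[c("ES", "LS", "TS", "TSL", "ERS")]
    if (any(is.na(s)) || any(s < 0)) stop("invalid initial state")
    s
  }
  amp_vec <- c(if (tp$mode == "local_plus_global") tp$amp_local else 0,
               tp$amp_global * (1 - tp$f_slow), tp$amp_global * tp$f_slow)
  camp <- c(0, 0, 0)
  y <- 1; z <- 1
  m <- numeric(n_ap); pj <- numeric(n_ap)
  yz_hist <- matrix(NA_real_, n_ap, 2, dimnames = list(NULL, c("y", "z")))
  traj_t <- vector("list", n_ap); traj_s <- vector("list", n_ap)
  traj_ca <- vector("list", n_ap)
  isis <- c(diff(ap_times), 1 / protocol$f_stim)
  at_last <- NULL
  for (j in seq_len(n_ap)) {
    yz_hist[j, ] <- c(y, z)
    p_j <- .pfusion_j(params, idp, y, z)
    m[j] <- p_j * (state[["TS"]] + state[["TSL"]])
    pj[j] <- p_j
    state[["ERS"]] <- state[["ERS"]] + m[j]
    state[["TS"]] <- state[["TS"]] * (1 - p_j)
    state[["TSL"]] <- state[["TSL"]] * (1 - p_j)
    transfer <- params$kappa_TSL * state[["LS"]]
    state[["TSL"]] <- state[["TSL"]] + transfer
    state[["LS"]] <- state[["LS"]] - transfer
    y <- y + idp$y_inc * (idp$y_max - y)
    z <- z - idp$z_dec * (z - idp$z_min)
    if (tp$summation == "reset") camp[] <- 0
    camp <- camp + (y * z) * amp_vec
    if (j == n_ap)
      at_last <- list(state = state, camp = camp, y = y, z = z,
                      time = ap_times[j])
    isi <- isis[j]
    sample_times <- if (keep_trajectory) seq(0, isi, by = dt_sample) else NULL
    seg <- .integrate_segment(state, camp, params, tp, isi,
                              sample_times = sample_times, rtol = rtol)
    if (keep_trajectory) {
      traj_t[[j]] <- ap_times[j] + seg$times
      traj_s[[j]] <- seg$states
      traj_ca[[j]] <- seg$ca
    }
    state <- seg$final
    camp <- seg$camp_final
    rel <- .relax_yz(idp, y, z, isi)
    y <- rel$y; z <- rel$z
  }
  res <- list(
    m = m[pt$main_start:n_ap],
    m_all = m, p_fusion_j = pj,
    stimulus_times = ap_times,
    main_index = pt$main_start:n_ap,
    y_z_history = yz_hist,
    protocol = protocol,
    at_last_stimulus = at_last,
    final = list(state = state, camp = camp, y = y, z = z,
                 time = ap_times[n_ap] + isis[n_ap])
  )
  if (keep_trajectory) {
    res$state_trajectory <- cbind(time = unlist(traj_t),
                                  do.call(rbind, traj_s))
    res$ca_trace <- cbind(time = unlist(traj_t), ca = unlist(traj_ca))
  }
  class(res) <- "simulation_result"
  res
}

#' Relax the state occupancies at constant calcium
#'
#' Integrates the docking/priming ODEs with no stimulation and a fixed
#' calcium concentration for `duration` seconds; used to verify that the
#' dynamical system converges to the closed-form equilibrium.
#'
#' @param params A [priming_parameters()] object.
#' @param state Named vector `(ES, LS, TS, TSL, ERS)`.
#' @param duration Integration time (s).
#' @param ca Calcium concentration (M), default `ca_rest`.
#' @param rtol Relative solver tolerance.
#' @return Named state vector after `duration` seconds.
#' @export
settle_state <- function(params, state, duration, ca = params$ca_rest,
                         rtol = 1e-10) {
  tp0 <- ca_transient_parameters(mode = "control_biexp", amp_global = 0,
                                 tau_fast = 1, tau_slow = 1, f_slow = 0)
  seg <- .integrate_segment(state[c("ES", "LS", "TS", "TSL", "ERS")],
                            c(0, 0, 0), params, tp0, duration,
                            rtol = rtol, ca_fixed = ca)
  seg$final
}

#' Steady-state release of a simulated or measured train
#'
#' @param result A `simulation_result` or a numeric vector of quantal
#'   contents.
#' @param mode `"last"` (the final stimulus, the convention for
#'   deterministic simulations) or `"mean_last5"` (mean of the last five
#'   stimuli, the convention for measured trains; requires >= 40 stimuli).
#' @return Scalar quantal content.
#' @export
steady_state_release <- function(result, mode = c("last", "mean_last5")) {
  mode <- match.arg(mode)
  m <- if (inherits(result, "simulation_result")) result$m else
    as.numeric(result)
  n <- length(m)
  if (mode == "last") {
    if (n < 1) stop("empty train")
    return(m[n])
  }
  if (n < 40) stop("mean_last5 requires a train of at least 40 stimuli")
  mean(m[(n - 4):n])
}

#' Recovery of release after a pool-depleting conditioning train
#'
#' Simulates the conditioning train, then follows the conditioned terminal
#' without further stimulation and probes it with single test stimuli at the
#' given intervals after the last conditioning stimulus. Test stimuli are
#' non-invasive probes (each evaluated on an independent continuation of the
#' conditioned state). The recovered fraction at each interval is
#' `(m_test - m_ss) / (m_1 - m_ss)` with `m_ss` the mean of the last five
#' conditioning responses and `m_1` the first.
#'
#' @inheritParams simulate_train
#' @param conditioning A [stimulus_protocol()] for the conditioning train
#'   (>= 5 stimuli).
#' @param test_intervals Strictly increasing intervals (s); defaults to
#'   `conditioning$recovery_tests`.
#' @return A data.frame with columns `interval`, `m_test` and
#'   `recovered_fraction` (`NaN` when `m_1 == m_ss`, in which case the
#'   fraction is undefined).
#' @export
simulate_recovery <- function(params, tp, idp, conditioning,
                              test_intervals = NULL, rtol = 1e-10) {
  if (is.null(test_intervals)) test_intervals <- conditioning$recovery_tests
  if (is.null(test_intervals)) stop("no test intervals supplied")
  if (any(test_intervals <= 0) ||
      (length(test_intervals) > 1 && any(diff(test_intervals) <= 0)))
    stop("test intervals must be positive and strictly increasing")
  if (conditioning$n_stim < 5)
    stop("conditioning train must have at least 5 stimuli")
  cond <- simulate_train(params, tp, idp, conditioning,
                         keep_trajectory = FALSE, rtol = rtol)
  m <- cond$m
  m_ss <- mean(m[(length(m) - 4):length(m)])
  m_1 <- m[1]
  snap <- cond$at_last_stimulus
  seg <- .integrate_segment(snap$state, snap$camp, params, tp,
                            max(test_intervals),
                            sample_times = test_intervals, rtol = rtol)
  idx <- match(test_intervals, seg$times)
  m_test <- vapply(seq_along(test_intervals), function(i) {
    rel <- .relax_yz(idp, snap$y, snap$z, test_intervals[i])
    p_t <- .pfusion_j(params, idp, rel$y, rel$z)
    st <- seg$states[idx[i], ]
    p_t * (st[["TS"]] + st[["TSL"]])
  }, numeric(1))
  frac <- if (abs(m_1 - m_ss) < 1e-12 * max(1, abs(m_1))) {
    rep(NaN, length(m_test))
  } else {
    (m_test - m_ss) / (m_1 - m_ss)
  }
  data.frame(interval = test_intervals, m_test = m_test,
             recovered_fraction = frac)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulated train: %d stimuli at %g Hz\n",
              x$protocol$n_stim, x$protocol$f_stim))
  cat(sprintf("  m1 = %.1f, m2/m1 = %.3f, m_last = %.1f quanta\n",
              x$m[1], if (length(x$m) > 1) x$m[2] / x$m[1] else NA_real_,
              x$m[length(x$m)]))
  invisible(x)
}
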