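#' Calcium-dependent priming rates
#'
#' The two forward priming rates increase linearly with the 'effective'
#' intracellular calcium concentration,
#' `k1 = k1_rest + sigma1 * (ca - ca_rest)` and
#' `k2 = k2_rest + sigma2 * (ca - ca_rest)`, clamped at zero for calcium
#' below rest (rates are physical quantities).
#'
#' @param params A [priming_parameters()] object.
#' @param ca Free calcium concentration (M), scalar or vector, must be >= 0.
#' @return A list with numeric elements `k1` and `k2` (1/s), each the same
#'   length as `ca`.
#' @export
#' @examples
#' priming_rates(preset_parameters("control"), 438e-9)
priming_rates <- function(params, ca) {
  stopifnot(inherits(params, "priming_parameters"))
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("ca must be finite and >= 0")
  d <- ca - params$ca_rest
  list(k1 = pmax(0, params$k1_rest + params$sigma1 * d),
       k2 = pmax(0, params$k2_rest + params$sigma2 * d))
}

#' Evaluate the 'effective' calcium transient
#'
#' Computes the free calcium concentration at time `t` given a sequence of
#' action potentials at `ap_times`, each contributing a transient whose
#' amplitudes are scaled by the corresponding entry of `ap_scales` (the
#' product of the influx facilitation and depression factors `y*z` for that
#' stimulus). In `"additive"` summation mode (the default, set on the
#' transient object) contributions of all past action potentials superpose
#' linearly; in `"reset"` mode only the most recent action potential
#' contributes. Before the first action potential the function returns
#' `ca_rest` exactly.
#'
#' @param tp A [ca_transient_parameters()] object.
#' @param ca_rest Resting calcium concentration (M).
#' @param ap_times Onset times of the action potentials (s), sorted
#'   ascending.
#' @param ap_scales Dimensionless amplitude scale per action potential; same
#'   length as `ap_times` (defaults to 1 for each).
#' @param t Evaluation time(s) (s).
#' @return Calcium concentration(s) (M), same length as `t`.
#' @export
effective_ca <- function(tp, ca_rest, ap_times, ap_scales = NULL, t) {
  stopifnot(inherits(tp, "ca_transient_parameters"))
  n <- length(ap_times)
  if (is.null(ap_scales)) ap_scales <- rep(1, n)
  if (length(ap_scales) != n)
    stop("ap_scales must match ap_times in length")
  if (n > 1 && any(diff(ap_times) < 0))
    stop("ap_times must be sorted ascending")
  vapply(t, function(tt) {
    past <- which(ap_times <= tt)
    if (length(past) == 0L) return(ca_rest)
    if (tp$summation == "reset") past <- past[length(past)]
    dt <- tt - ap_times[past]
    s <- ap_scales[past]
    glob <- tp$amp_global *
      ((1 - tp$f_slow) * exp(-dt / tp$tau_fast) +
         tp$f_slow * exp(-dt / tp$tau_slow))
    loc <- if (tp$mode == "local_plus_global")
      tp$amp_local * exp(-dt / tp$tau_local) else 0
    ca_rest + sum(s * (glob + loc))
  }, numeric(1))
}

#' Time integral of one transient above resting calcium
#'
#' Closed-form integral over `[0, Inf)` of the single-stimulus transient,
#' split into its local and global parts. The local share of the total
#' integral is the quantity used to apportion the contributions of local
#' and global calcium signalling to activity-dependent priming.
#'
#' @param tp A [ca_transient_parameters()] object.
#' @return A list with elements `local`, `global` (both M s) and
#'   `local_share` (dimensionless fraction of the total integral).
#' @export
#' @examples
#' ca_transient_integral(preset_parameters("control", "transient"))$local_share
ca_transient_integral <- function(tp) {
  stopifnot(inherits(tp, "ca_transient_parameters"))
  g <- tp$amp_global * ((1 - tp$f_slow) * tp$tau_fast +
                          tp$f_slow * tp$tau_slow)
  l <- if (tp$mode == "local_plus_global") tp$amp_local * tp$tau_local else 0
  list(local = l, global = g,
       local_share = if (l + g > 0) l / (l + g) else NA_real_)
}

#' Equilibrium occupancy of the model states
#'
#' At constant calcium the labile tight state and the refractory state are
#' empty and the remaining three states obey detailed-balance-like ratios
#' `LS/ES = k1/b1` and `TS/LS = k2/b2`, scaled so the occupancies sum to
#' `N_total` (site conservation). Zero backward rates are handled as limits:
#' `b1 = 0` puts all mass beyond ES, `b2 = 0` drains LS into TS.
#'
#' @param params A [priming_parameters()] object.
#' @param ca Calcium concentration (M), scalar; defaults to `ca_rest`.
#' @return A named numeric vector of class `state_occupancy` with elements
#'   `ES`, `LS`, `TS`, `TSL`, `ERS` (site counts summing to `N_total`).
#' @export
#' @examples
#' eq <- equilibrium_occupancy(preset_parameters("control"), 50e-9)
#' eq["ES"] / sum(eq)  # ~25% empty sites at rest
equilibrium_occupancy <- function(params, ca = params$ca_rest) {
  stopifnot(inherits(params, "priming_parameters"), length(ca) == 1L)
  k <- priming_rates(params, ca)
  if (params$b1 == 0 && k$k1 > 0) {
    # all mass leaves ES; distribution between LS and TS set by k2/b2
    if (params$b2 == 0 && k$k2 > 0) {
      frac <- c(ES = 0, LS = 0, TS = 1)
    } else if (k$k2 == 0) {
      frac <- c(ES = 0, LS = 1, TS = 0)
    } else {
      r2 <- k$k2 / params$b2
      frac <- c(ES = 0, LS = 1, TS = r2) / (1 + r2)
    }
  } else if (params$b2 == 0 && k$k2 > 0) {
    frac <- c(ES = 0, LS = 0, TS = 1)
  } else {
    r1 <- if (params$b1 > 0) k$k1 / params$b1 else 0
    r2 <- if (params$b2 > 0) k$k2 / params$b2 else 0
    frac <- c(ES = 1, LS = r1, TS = r1 * r2)
    frac <- frac / sum(frac)
  }
  out <- c(frac * params$N_total, TSL = 0, ERS = 0)
  structure(out[c("ES", "LS", "TS", "TSL", "ERS")], class = "state_occupancy")
}

#' Fraction of sites holding a fast-releasing vesicle at equilibrium
#'
#' The fast-releasing pool (FRP) is the sum of loosely and tightly docked
#' vesicles; this returns `(LS + TS) / N_total` at the equilibrium for the
#' given calcium concentration.
#'
#' @inheritParams equilibrium_occupancy
#' @return Fraction in \[0, 1\].
#' @export
frp_fraction <- function(params, ca = params$ca_rest) {
  occ <- equilibrium_occupancy(params, ca)
  unname((occ["LS"] + occ["TS"]) / params$N_total)
}

#' Calcium concentration for half-maximum increase in TS occupancy
#'
#' Finds the calcium concentration at which the equilibrium occupancy of the
#' tightly docked state reaches half of its maximum possible increase above
#' the reference, i.e. `TS(ca_ref) + 0.5 * (N_total - TS(ca_ref))`. The
#' closed-form TS occupancy is bisected over `[ca_ref, ca_upper]`.
#'
#' @param params A [priming_parameters()] object.
#' @param ca_ref Reference calcium concentration (M), default 50 nM.
#' @param ca_upper Upper search bound (M), default 10 uM.
#' @param tol Absolute tolerance on the returned concentration (M), default
#'   0.01 nM.
#' @return Calcium concentration (M).
#' @export
#' @examples
#' half_max_ca(preset_parameters("control")) * 1e9  # ~438 nM
half_max_ca <- function(params, ca_ref = 5e-8, ca_upper = 1e-5, tol = 1e-11) {
  stopifnot(inherits(params, "priming_parameters"))
  ts_at <- function(ca) unname(equilibrium_occupancy(params, ca)["TS"])
  ts0 <- ts_at(ca_ref)
  target <- ts0 + 0.5 * (params$N_total - ts0)
  if (ts0 >= params$N_total) return(ca_ref)
  f <- function(ca) ts_at(ca) - target
  if (f(ca_upper) < 0)
    stop("TS occupancy does not reach the half-maximum target within ",
         "the search bracket; increase ca_upper")
  lo <- ca_ref; hi <- ca_upper
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' Michaelis-Menten ratio of calcium influx between two external calcium
#' concentrations
#'
#' Presynaptic calcium influx saturates with external calcium following
#' `J = J_max * ca_ext / (ca_ext + EC50)`. This returns the fold change in
#' influx when stepping the external concentration from `ca_ext_a` to
#' `ca_ext_b`.
#'
#' @param ca_ext_a,ca_ext_b External calcium before/after (mM), > 0.
#' @param ec50 Half-saturating external calcium (mM), default 2.6.
#' @return Dimensionless influx ratio (b relative to a).
#' @export
#' @examples
#' influx_ratio_mm(1.5, 2.0)  # ~1.19
influx_ratio_mm <- function(ca_ext_a, ca_ext_b, ec50 = 2.6) {
  if (ca_ext_a <= 0 || ca_ext_b <= 0 || ec50 < 0)
    stop("concentrations must be > 0 and ec50 >= 0")
  (ca_ext_b / (ca_ext_b + ec50)) / (ca_ext_a / (ca_ext_a + ec50))
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat("State occupancy (sites):\n")
  print(round(unclass(x), 2))
  invisible(x)
}
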