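#' Kinetic parameters of the two-step priming and fusion scheme
#'
#' Bundles all constants of the five-state release-site scheme: empty
#' available sites (ES), loosely docked vesicles (LS), tightly docked
#' vesicles (TS), a labile tightly docked state (TSL) populated from LS
#' immediately after each action potential, and empty refractory sites (ERS).
#' Forward priming rates `k1` (ES to LS) and `k2` (LS to TS) increase
#' linearly with the 'effective' intracellular calcium concentration; all
#' backward rates are fixed.
#'
#' @param p_fusion Probability that a fusion-competent (TS or TSL) vesicle
#'   fuses in response to a single action potential, dimensionless in
#'   \[0, 1\].
#' @param N_total Total number of release sites (count, > 0).
#' @param k1_rest ES to LS priming rate at resting calcium (1/s).
#' @param b1 LS to ES un-priming rate (1/s).
#' @param sigma1 Linear calcium sensitivity of `k1` (1/(M s)).
#' @param k2_rest LS to TS priming rate at resting calcium (1/s).
#' @param b2 TS to LS un-priming rate (1/s).
#' @param sigma2 Linear calcium sensitivity of `k2` (1/(M s)).
#' @param tau_TSL Mean lifetime of the labile tight state, `1/b3` (s).
#' @param kappa_TSL Fraction of LS vesicles transferred to TSL immediately
#'   after each action potential, dimensionless in \[0, 1\].
#' @param b4 Recovery rate of refractory sites back to available sites (1/s).
#' @param ca_rest Resting free intracellular calcium concentration (M).
#'
#' @return An object of class `priming_parameters` (a validated named list).
#' @seealso [preset_parameters()] for the published parameter columns,
#'   [equilibrium_occupancy()], [simulate_train()].
#' @export
#' @examples
#' pp <- preset_parameters("control")
#' pp$k1_rest
priming_parameters <- function(p_fusion, N_total, k1_rest, b1, sigma1,
                               k2_rest, b2, sigma2, tau_TSL, kappa_TSL,
                               b4, ca_rest) {
  x <- list(
    p_fusion = as.numeric(p_fusion), N_total = as.numeric(N_total),
    k1_rest = as.numeric(k1_rest), b1 = as.numeric(b1),
    sigma1 = as.numeric(sigma1), k2_rest = as.numeric(k2_rest),
    b2 = as.numeric(b2), sigma2 = as.numeric(sigma2),
    tau_TSL = as.numeric(tau_TSL), kappa_TSL = as.numeric(kappa_TSL),
    b4 = as.numeric(b4), ca_rest = as.numeric(ca_rest)
  )
  rates <- c("k1_rest", "b1", "sigma1", "k2_rest", "b2", "sigma2", "b4")
  if (any(vapply(x, length, 1L) != 1L) || any(!vapply(x, is.finite, TRUE)))
    stop("all priming parameters must be finite scalars")
  if (any(unlist(x[rates]) < 0))
    stop("rates and calcium sensitivities must be >= 0")
  if (x$p_fusion < 0 || x$p_fusion > 1)
    stop("p_fusion must lie in [0, 1]")
  if (x$kappa_TSL < 0 || x$kappa_TSL > 1)
    stop("kappa_TSL must lie in [0, 1]")
  if (x$N_total <= 0) stop("N_total must be > 0")
  if (x$tau_TSL <= 0) stop("tau_TSL must be > 0")
  if (x$ca_rest <= 0) stop("ca_rest must be > 0")
  structure(x, class = "priming_parameters")
}

#' Shape of the action-potential-evoked 'effective' calcium transient
#'
#' Two parameterisations are supported. In `"control_biexp"` mode a single
#' transient of amplitude `amp_global` decays bi-exponentially (fractions
#' `1 - f_slow` with `tau_fast` and `f_slow` with `tau_slow`). In
#' `"local_plus_global"` mode a large, very fast local component
#' (`amp_local`, `tau_local`) is superimposed on the bi-exponential global
#' component; this is the parameterisation that reconciles a low calcium
#' sensitivity of priming with pronounced activity-dependent acceleration.
#'
#' @param mode `"control_biexp"` or `"local_plus_global"`.
#' @param amp_global Amplitude of the global transient above rest (M).
#' @param tau_fast Fast decay time constant of the global transient (s).
#' @param tau_slow Slow decay time constant of the global transient (s).
#' @param f_slow Fraction of the global amplitude decaying with `tau_slow`.
#' @param amp_local Amplitude of the local transient (M); used only in
#'   `"local_plus_global"` mode.
#' @param tau_local Decay time constant of the local transient (s).
#' @param summation `"additive"` (transients of successive action potentials
#'   superpose linearly; default) or `"reset"` (only the most recent action
#'   potential contributes).
#'
#' @return An object of class `ca_transient_parameters`.
#' @export
ca_transient_parameters <- function(mode = c("local_plus_global", "control_biexp"),
                                    amp_global, tau_fast, tau_slow, f_slow,
                                    amp_local = 0, tau_local = 2.5e-4,
                                    summation = c("additive", "reset")) {
  mode <- match.arg(mode)
  summation <- match.arg(summation)
  x <- list(mode = mode, amp_global = as.numeric(amp_global),
            tau_fast = as.numeric(tau_fast), tau_slow = as.numeric(tau_slow),
            f_slow = as.numeric(f_slow), amp_local = as.numeric(amp_local),
            tau_local = as.numeric(tau_local), summation = summation)
  num <- x[c("amp_global", "tau_fast", "tau_slow", "f_slow", "amp_local",
             "tau_local")]
  if (any(!vapply(num, is.finite, TRUE)))
    stop("transient parameters must be finite scalars")
  if (x$f_slow < 0 || x$f_slow > 1) stop("f_slow must lie in [0, 1]")
  if (x$tau_fast <= 0 || x$tau_slow <= 0 || x$tau_local <= 0)
    stop("decay time constants must be > 0")
  if (x$amp_global < 0 || x$amp_local < 0) stop("amplitudes must be >= 0")
  if (mode == "control_biexp") x$amp_local <- 0
  structure(x, class = "ca_transient_parameters")
}

#' Per-stimulus facilitation/depression of presynaptic calcium influx
#'
#' Scalar dynamics for the two influx scale factors: a facilitation factor
#' `y` that is incremented towards its ceiling `y_max` at each action
#' potential and relaxes back to 1 with time constant `tau_y`, and a
#' depression factor `z` that is decremented towards its floor `z_min` and
#' relaxes back to 1 with `tau_z`. The product `y*z` scales the amplitude of
#' the 'effective' calcium transient of each stimulus, and the per-stimulus
#' fusion probability follows `p_fusion * (y*z)^p_cooperativity` (see
#' [simulate_train()]).
#'
#' @param y_inc Per-stimulus fractional increment of `y` towards `y_max`.
#' @param z_dec Per-stimulus fractional decrement of `z` towards `z_min`.
#' @param y_max Facilitation ceiling (>= 1).
#' @param z_min Depression floor (0 < `z_min` <= 1).
#' @param tau_y Relaxation time constant of `y` towards 1 (s).
#' @param tau_z Relaxation time constant of `z` towards 1 (s).
#' @param p_cooperativity Exponent coupling the relative influx scale `y*z`
#'   to the per-stimulus fusion probability (default 4, the classical
#'   intracellular calcium cooperativity of vesicle fusion; 0 keeps
#'   `p_fusion` constant within a train).
#'
#' @return An object of class `influx_dynamics_parameters`.
#' @export
influx_dynamics_parameters <- function(y_inc, z_dec, y_max, z_min,
                                       tau_y, tau_z, p_cooperativity = 4) {
  x <- list(y_inc = as.numeric(y_inc), z_dec = as.numeric(z_dec),
            y_max = as.numeric(y_max), z_min = as.numeric(z_min),
            tau_y = as.numeric(tau_y), tau_z = as.numeric(tau_z),
            p_cooperativity = as.numeric(p_cooperativity))
  if (any(!vapply(x, is.finite, TRUE)))
    stop("influx dynamics parameters must be finite scalars")
  if (x$y_max < 1) stop("y_max must be >= 1")
  if (x$z_min <= 0 || x$z_min > 1) stop("z_min must lie in (0, 1]")
  if (x$y_inc < 0 || x$y_inc > 1 || x$z_dec < 0 || x$z_dec > 1)
    stop("y_inc and z_dec must lie in [0, 1]")
  if (x$tau_y <= 0 || x$tau_z <= 0) stop("tau_y and tau_z must be > 0")
  if (x$p_cooperativity < 0) stop("p_cooperativity must be >= 0")
  structure(x, class = "influx_dynamics_parameters")
}

# Published model parameter columns (STP modelling at the calyx of Held,
# P14-16 rat, room temperature). Conditions: "control" / "ionomycin" are the
# pair recorded at 1.5 mM external Ca with and without 2.5 uM ionomycin;
# "ca15" / "ca20" the pair at 1.5 vs 2.0 mM external Ca; "pdbu_control" /
# "pdbu" the pair with and without 1 uM PDBu at 1.5 mM external Ca.
.preset_table <- function() {
  list(
    control = list(
      priming = list(p_fusion = 0.22, N_total = 2622, k1_rest = 0.370,
                     b1 = 0.221, sigma1 = 2.245e6, k2_rest = 0.199,
                     b2 = 0.253, sigma2 = 1.014e6, tau_TSL = 0.09,
                     kappa_TSL = 0.1, b4 = 2.6, ca_rest = 5e-8),
      transient = list(amp_global = 4.54e-7, tau_fast = 0.06, tau_slow = 0.23,
                       f_slow = 0.15, amp_local = 3e-5, tau_local = 2.5e-4),
      influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.31, z_min = 0.87,
                    tau_y = 0.017, tau_z = 3)
    ),
    ionomycin = list(
      priming = list(p_fusion = 0.30, N_total = 2622, k1_rest = 0.370,
                     b1 = 0.221, sigma1 = 2.245e6, k2_rest = 0.199,
                     b2 = 0.253, sigma2 = 1.014e6, tau_TSL = 0.09,
                     kappa_TSL = 0.15, b4 = 4.2, ca_rest = 1.3e-7),
      transient = list(amp_global = 4.54e-7, tau_fast = 0.06, tau_slow = 0.23,
                       f_slow = 0.15, amp_local = 3e-5, tau_local = 2.5e-4),
      influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.16, z_min = 1,
                    tau_y = 0.017, tau_z = 3)
    ),
    ca15 = list(
      priming = list(p_fusion = 0.22, N_total = 2910, k1_rest = 0.374015,
                     b1 = 0.215, sigma1 = 2.181e6, k2_rest = 0.191,
                     b2 = 0.264, sigma2 = 1.042e6, tau_TSL = 0.09,
                     kappa_TSL = 0.1, b4 = 2.5, ca_rest = 5e-8),
      transient = list(amp_global = 4.54e-7, tau_fast = 0.06, tau_slow = 0.23,
                       f_slow = 0.15, amp_local = 3e-5, tau_local = 2.5e-4),
      influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.28, z_min = 0.84,
                    tau_y = 0.017, tau_z = 3)
    ),
    ca20 = list(
      priming = list(p_fusion = 0.42, N_total = 2910, k1_rest = 0.374015,
                     b1 = 0.215, sigma1 = 2.181e6, k2_rest = 0.191,
                     b2 = 0.264, sigma2 = 1.042e6, tau_TSL = 0.09,
                     kappa_TSL = 0.1, b4 = 2.9, ca_rest = 9e-8),
      transient = list(amp_global = 5.45e-7, tau_fast = 0.06, tau_slow = 0.23,
                       f_slow = 0.15, amp_local = 3.6e-5, tau_local = 2.5e-4),
      influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.28, z_min = 0.84,
                    tau_y = 0.017, tau_z = 3)
    ),
    pdbu_control = list(
      priming = list(p_fusion = 0.22, N_total = 2590, k1_rest = 0.373,
                     b1 = 0.210, sigma1 = 2.051e6, k2_rest = 0.187,
                     b2 = 0.271, sigma2 = 1.019e6, tau_TSL = 0.09,
                     kappa_TSL = 0.11, b4 = 2.8, ca_rest = 5e-8),
      transient = list(amp_global = 4.54e-7, tau_fast = 0.06, tau_slow = 0.23,
                       f_slow = 0.15, amp_local = 3e-5, tau_local = 2.5e-4),
      influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.27, z_min = 0.87,
                    tau_y = 0.017, tau_z = 3)
    ),
    pdbu = list(
      priming = list(p_fusion = 0.29, N_total = 3297, k1_rest = 0.373,
                     b1 = 0.210, sigma1 = 2.051e6, k2_rest = 0.378,
                     b2 = 0.271, sigma2 = 2.436e6, tau_TSL = 0.09,
                     kappa_TSL = 0.11, b4 = 2.8, ca_rest = 5e-8),
      transient = list(amp_global = 4.54e-7, tau_fast = 0.06, tau_slow = 0.23,
                       f_slow = 0.15, amp_local = 3e-5, tau_local = 2.5e-4),
      influx = list(y_inc = 0.39, z_dec = 0.4, y_max = 1.27, z_min = 0.87,
                    tau_y = 0.017, tau_z = 3)
    )
  )
}

#' Published parameter sets for the priming/fusion model
#'
#' Returns the model constants fitted to calyx of Held train data for one
#' experimental condition. `"control"` and `"ionomycin"` are the pair
#' recorded at 1.5 mM external calcium with/without ionomycin; `"ca15"` and
#' `"ca20"` the pair at 1.5 vs 2.0 mM external calcium; `"pdbu_control"`
#' and `"pdbu"` the pair with/without the diacylglycerol mimetic PDBu.
#'
#' @param condition One of `"control"`, `"ionomycin"`, `"ca15"`, `"ca20"`,
#'   `"pdbu_control"`, `"pdbu"`.
#' @param what `"priming"`, `"transient"`, `"influx"` or `"all"` (a list of
#'   the three).
#' @return A [priming_parameters()], [ca_transient_parameters()] or
#'   [influx_dynamics_parameters()] object, or a named list of all three.
#' @export
#' @examples
#' preset_parameters("pdbu")$k2_rest / preset_parameters("pdbu_control")$k2_rest
preset_parameters <- function(condition = c("control", "ionomycin", "ca15",
                                            "ca20", "pdbu_control", "pdbu"),
                              what = c("priming", "transient", "influx", "all")) {
  condition <- match.arg(condition)
  what <- match.arg(what)
  raw <- .preset_table()[[condition]]
  build <- list(
    priming = function() do.call(priming_parameters, raw$priming),
    transient = function() do.call(ca_transient_parameters,
                                   c(list(mode = "local_plus_global"),
                                     raw$transient)),
    influx = function() do.call(influx_dynamics_parameters, raw$influx)
  )
  if (what == "all") {
    list(priming = build$priming(), transient = build$transient(),
         influx = build$influx())
  } else {
    build[[what]]()
  }
}

#' List the available preset condition names
#' @return Character vector of condition identifiers.
#' @export
preset_conditions <- function() names(.preset_table())

# Convert a config value with an explicit unit tag into molar.
.to_molar <- function(x, field) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x) && !is.null(x$value) && !is.null(x$unit)) {
    fac <- switch(tolower(x$unit),
                  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6,
                  "nm" = 1e-9, "pm" = 1e-12,
                  stop("unknown concentration unit '", x$unit,
                       "' for field ", field))
    return(as.numeric(x$value) * fac)
  }
  stop("field ", field, " must be numeric (molar) or a {value, unit} pair")
}

#' Load a model parameter configuration from YAML or JSON
#'
#' The file holds one or more named condition blocks, each with `priming`,
#' `transient` and `influx` sub-blocks whose keys match the constructor
#' arguments of [priming_parameters()], [ca_transient_parameters()] and
#' [influx_dynamics_parameters()]. Concentration-valued fields (`ca_rest`,
#' `amp_global`, `amp_local`) may be given either as numbers in molar or as
#' `{value: 50, unit: nM}` pairs; all values are validated on load.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of condition blocks, each a list with elements
#'   `priming`, `transient`, `influx`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a named list of condition blocks")
  lapply(cfg, function(block) {
    if (!all(c("priming", "transient", "influx") %in% names(block)))
      stop("each condition block needs priming, transient and influx parts")
    pr <- block$priming
    pr$ca_rest <- .to_molar(pr$ca_rest, "ca_rest")
    tr <- block$transient
    tr$amp_global <- .to_molar(tr$amp_global, "amp_global")
    if (!is.null(tr$amp_local)) tr$amp_local <- .to_molar(tr$amp_local, "amp_local")
    list(priming = do.call(priming_parameters, pr),
         transient = do.call(ca_transient_parameters, tr),
         influx = do.call(influx_dynamics_parameters, block$influx))
  })
}

#' @export
print.priming_parameters <- function(x, ...) {
  cat("Two-step priming/fusion parameters\n")
  cat(sprintf("  p_fusion %.3g, N_total %d, ca_rest %.3g M\n",
              x$p_fusion, round(x$N_total), x$ca_rest))
  cat(sprintf("  k1_rest %.3g, b1 %.3g, sigma1 %.3g /M/s\n",
              x$k1_rest, x$b1, x$sigma1))
  cat(sprintf("  k2_rest %.3g, b2 %.3g, sigma2 %.3g /M/s\n",
              x$k2_rest, x$b2, x$sigma2))
  cat(sprintf("  tau_TSL %.3g s, kappa_TSL %.3g, b4 %.3g /s\n",
              x$tau_TSL, x$kappa_TSL, x$b4))
  invisible(x)
}
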