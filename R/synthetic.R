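#' Specification of a synthetic synapse population
#'
#' Describes the in-silico experimental design used to validate the
#' analysis pipeline without recordings: a cohort of model synapses sharing
#' all kinetic constants except for per-synapse heterogeneity in the number
#' of release sites (`N_total`, log-normal, CV `cv_ntotal`) and in the
#' resting LS-to-TS priming rate (`k2_rest`, log-normal, CV `cv_k2`). The
#' two dispersions reproduce the experimentally observed cohort structure
#' (roughly ten-fold spread of initial quantal content; mature docked
#' fraction spanning about 0.28-0.59) while the fusion probability is
#' uniform across synapses, so that recovering it from the decomposition is
#' a meaningful test. Measurement noise is multiplicative log-normal per
#' response (CV `noise_cv`), optionally preceded by binomial sampling of
#' fusion counts, and `n_repetitions` trials are averaged as in the
#' recording protocol.
#'
#' @param n_synapses Number of synapses (>= 2, default 50).
#' @param condition Preset condition name for the shared parameters
#'   (default `"control"`); alternatively supply `params` directly.
#' @param params Optional list with elements `priming`, `transient`,
#'   `influx` overriding `condition`.
#' @param cv_ntotal Coefficient of variation of per-synapse `N_total`
#'   (default 0.35).
#' @param cv_k2 Coefficient of variation of per-synapse `k2_rest` (default
#'   0.4).
#' @param noise_cv Per-response multiplicative noise CV (default 0.1).
#' @param n_repetitions Trials averaged per train (default 3).
#' @param binomial If `TRUE`, fusion counts are binomially sampled before
#'   measurement noise is applied (default `FALSE`).
#' @param seed RNG seed (Mersenne-Twister), recorded in the output.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_synapses = 50, condition = "control",
                            params = NULL, cv_ntotal = 0.35, cv_k2 = 0.4,
                            noise_cv = 0.1, n_repetitions = 3,
                            binomial = FALSE, seed = 1L) {
  if (n_synapses < 2) stop("n_synapses must be >= 2")
  if (cv_ntotal < 0 || cv_k2 < 0 || noise_cv < 0)
    stop("coefficients of variation must be >= 0")
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  if (is.null(params)) params <- preset_parameters(condition, "all")
  stopifnot(inherits(params$priming, "priming_parameters"),
            inherits(params$transient, "ca_transient_parameters"),
            inherits(params$influx, "influx_dynamics_parameters"))
  structure(list(n_synapses = as.integer(n_synapses), params = params,
                 cv_ntotal = cv_ntotal, cv_k2 = cv_k2, noise_cv = noise_cv,
                 n_repetitions = as.integer(n_repetitions),
                 binomial = isTRUE(binomial), seed = as.integer(seed)),
            class = "population_spec")
}

#' The ten stimulation layers of the standard train design
#'
#' Unconditioned 40-stimulus trains at 5, 10, 20, 50, 100 and 200 Hz, plus
#' 100 and 200 Hz trains preconditioned by two or four stimuli at 10 Hz.
#'
#' @param n_stim Stimuli per main train (default 40).
#' @return Named list of [stimulus_protocol()] objects.
#' @export
standard_layers <- function(n_stim = 40) {
  freqs <- c(5, 10, 20, 50, 100, 200)
  layers <- lapply(freqs, stimulus_protocol, n_stim = n_stim)
  names(layers) <- paste0("f", freqs)
  for (f in c(100, 200)) {
    for (npre in c(2, 4)) {
      layers[[sprintf("f%d_pre%d", f, npre)]] <-
        stimulus_protocol(f, n_stim = n_stim,
                          precondition = list(n_pre = npre, f_pre = 10))
    }
  }
  layers
}

#' Binomially sampled fusion counts
#'
#' Stochastic stand-in for quantal release: draws the number of fused
#' vesicles from a binomial with `n = n_available` trials and success
#' probability `expected_m / n_available`, so the mean equals the
#' deterministic expectation.
#'
#' @param expected_m Expected quantal content(s), `0 <= expected_m <=
#'   n_available`.
#' @param n_available Number of fusion-competent vesicles (rounded to
#'   integer counts).
#' @return Integer quantal content(s).
#' @export
binomial_fusion_noise <- function(expected_m, n_available) {
  n <- round(n_available)
  if (any(expected_m < 0) || any(expected_m > n_available))
    stop("expected_m must lie in [0, n_available]")
  p <- ifelse(n > 0, pmin(1, expected_m / n), 0)
  stats::rbinom(length(expected_m), n, p)
}

#' Generate a synthetic synapse population with ground truth
#'
#' Simulates every synapse of the population through all stimulation layers
#' deterministically, then applies per-repetition stochastic noise and
#' averages repetitions, assembling the noisy release tensor exactly as the
#' recording protocol would. The exported ground truth holds each synapse's
#' true parameters and resting-state composition, enabling parameter-
#' recovery tests of the decomposition and pool estimators.
#'
#' @param spec A [population_spec()].
#' @param layers Named list of [stimulus_protocol()]s (default
#'   [standard_layers()]).
#' @param rtol ODE solver tolerance passed to [simulate_train()] (default
#'   1e-8).
#' @return A list of class `synthetic_population` with elements `tensor`
#'   (noisy, averaged `release_tensor`), `noiseless` (same shape, no
#'   noise), `truth` (data.frame: `synapse_id`, `N_total`, `k2_rest`, `ES`,
#'   `LS`, `TS`, `f_TS`, `p_fusion`, `m1`), and `spec` (with the seed as
#'   resolved).
#' @export
generate_population <- function(spec, layers = standard_layers(),
                                rtol = 1e-8) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  base <- spec$params$priming
  tp <- spec$params$transient
  idp <- spec$params$influx
  lnorm_factor <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  n <- spec$n_synapses
  ntot <- base$N_total * lnorm_factor(n, spec$cv_ntotal)
  k2 <- base$k2_rest * lnorm_factor(n, spec$cv_k2)
  n_stim <- layers[[1]]$n_stim
  dims <- c(n_stim, n, length(layers))
  noiseless <- array(NA_real_, dim = dims,
                     dimnames = list(stimulus = seq_len(n_stim),
                                     synapse = sprintf("syn%02d", seq_len(n)),
                                     layer = names(layers)))
  noisy <- noiseless
  truth <- vector("list", n)
  sdlog_noise <- if (spec$noise_cv > 0) sqrt(log(1 + spec$noise_cv^2)) else 0
  for (s in seq_len(n)) {
    fields <- unclass(base)
    fields$N_total <- ntot[s]
    fields$k2_rest <- k2[s]
    pp <- do.call(priming_parameters, fields)
    eq <- equilibrium_occupancy(pp, pp$ca_rest)
    for (l in seq_along(layers)) {
      sim <- simulate_train(pp, tp, idp, layers[[l]],
                            keep_trajectory = FALSE, rtol = rtol)
      m <- sim$m
      noiseless[, s, l] <- m
      reps <- matrix(NA_real_, n_stim, spec$n_repetitions)
      for (r in seq_len(spec$n_repetitions)) {
        mr <- m
        if (spec$binomial) {
          avail <- m / pmax(sim$p_fusion_j[sim$main_index], 1e-12)
          mr <- binomial_fusion_noise(pmin(mr, avail), avail)
        }
        if (sdlog_noise > 0)
          mr <- mr * exp(stats::rnorm(n_stim, -sdlog_noise^2 / 2,
                                      sdlog_noise))
        reps[, r] <- mr
      }
      noisy[, s, l] <- rowMeans(reps)
    }
    truth[[s]] <- data.frame(
      synapse_id = sprintf("syn%02d", s), N_total = ntot[s],
      k2_rest = k2[s], ES = eq[["ES"]], LS = eq[["LS"]], TS = eq[["TS"]],
      f_TS = eq[["TS"]] / (eq[["LS"]] + eq[["TS"]]),
      p_fusion = pp$p_fusion,
      m1 = pp$p_fusion * eq[["TS"]])
  }
  structure(list(
    tensor = structure(noisy, class = c("release_tensor", "array")),
    noiseless = structure(noiseless, class = c("release_tensor", "array")),
    truth = do.call(rbind, truth),
    spec = spec), class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf(
    "Synthetic population: %d synapses, %d layers, %d stimuli (seed %d)\n",
    d[2], d[3], d[1], x$spec$seed))
  cat(sprintf("  mean m1 = %.1f quanta (range %.0f-%.0f), f_TS %.2f-%.2f\n",
              mean(x$truth$m1), min(x$truth$m1), max(x$truth$m1),
              min(x$truth$f_TS), max(x$truth$f_TS)))
  invisible(x)
}
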