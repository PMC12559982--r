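#' Convert evoked-EPSC peak amplitudes to quantal contents
#'
#' Divides peak amplitudes by the effective quantal size `q_star`. The
#' default, -6.6 pA, is the effective size of a single quantum in the
#' presence of 1 mM kynurenate, chosen slightly smaller than the mean
#' miniature amplitude to absorb the temporal dispersion of quanta during
#' synchronous release. Peaks and `q_star` must share the sign convention
#' (inward currents negative).
#'
#' @param peak_amplitudes Numeric vector of eEPSC peak amplitudes (pA).
#' @param q_star Effective quantal size (pA), non-zero; default -6.6.
#' @param allow_abs If `TRUE`, a sign mismatch between peaks and `q_star`
#'   produces a warning and absolute values are used; if `FALSE` (default)
#'   it is an error.
#' @return Quantal contents (vesicles), same length as the input.
#' @export
#' @examples
#' quantal_content(-1273.8)  # ~193 quanta
quantal_content <- function(peak_amplitudes, q_star = -6.6,
                            allow_abs = FALSE) {
  if (q_star == 0) stop("q_star must be non-zero")
  mismatch <- peak_amplitudes != 0 &
    sign(peak_amplitudes) != sign(q_star)
  if (any(mismatch)) {
    if (!allow_abs)
      stop("peak amplitudes and q_star have opposite signs; set ",
           "allow_abs = TRUE to divide magnitudes")
    warning("sign mismatch between peaks and q_star; using magnitudes")
    return(abs(peak_amplitudes) / abs(q_star))
  }
  peak_amplitudes / q_star
}

#' Apparent fast-releasing pool size from one high-frequency train
#'
#' Back-extrapolation estimate: the cumulative quantal release is plotted
#' against stimulus index, a straight line is fitted to the late
#' steady-state segment (where release is balanced by replenishment, so the
#' slope absorbs the replenishment rate) and its intercept at index 0 is
#' returned as the apparent pool. Because high-frequency trains deplete the
#' pool only partially, this per-frequency estimate underestimates the true
#' pool; see [frp_extrapolate()] for the correction.
#'
#' @param m Numeric vector of quantal contents (typically 40 stimuli).
#' @param f_stim Train frequency (Hz); must be one of the high-frequency
#'   protocols (50, 100 or 200 Hz).
#' @param window Number of trailing cumulative points used for the line fit
#'   (default 10).
#' @return Apparent pool size FRP' (vesicles).
#' @export
frp_apparent <- function(m, f_stim, window = 10) {
  if (inherits(m, "simulation_result")) m <- m$m
  if (!f_stim %in% c(50, 100, 200))
    stop("back-extrapolation is defined for the high-frequency trains ",
         "(50, 100, 200 Hz)")
  n <- length(m)
  if (n < window + 5) stop("train too short for a ", window, "-point fit")
  if (any(m < 0)) stop("quantal contents must be >= 0")
  # require an approximately stationary tail: no steady state, no estimate
  tail_m <- m[(n - window + 1):n]
  head_mean <- mean(m[1:5])
  if (mean(tail_m) > 0.9 * max(head_mean, max(m)))
    stop("train does not reach a depressed steady state; ",
         "back-extrapolation is not applicable")
  cum <- cumsum(m)
  idx <- (n - window + 1):n
  fit <- stats::lm.fit(cbind(1, idx), cum[idx])
  unname(fit$coefficients[1])
}

#' Fast-releasing pool size extrapolated to zero interstimulus interval
#'
#' Corrects the apparent per-frequency pool estimates for incomplete
#' depletion: the reciprocal apparent pool is regressed on the
#' interstimulus interval and the regression line is extrapolated to
#' ISI = 0 (infinite frequency); the reciprocal intercept is the pool
#' estimate.
#'
#' @param frp_apparent_by_isi Named numeric vector or list mapping ISI in
#'   seconds (names or a separate `isi` argument) to apparent pool sizes,
#'   or a numeric vector with `isi` supplied.
#' @param isi Optional numeric vector of interstimulus intervals (s)
#'   matching `frp_apparent_by_isi`.
#' @return Extrapolated pool size (vesicles).
#' @export
#' @examples
#' frp_extrapolate(c("0.005" = 1600, "0.01" = 1450, "0.02" = 1250))
frp_extrapolate <- function(frp_apparent_by_isi, isi = NULL) {
  v <- unlist(frp_apparent_by_isi)
  if (is.null(isi)) isi <- as.numeric(names(v))
  if (length(v) < 2 || length(isi) != length(v) || any(is.na(isi)))
    stop("need >= 2 apparent pool estimates with their ISIs")
  if (any(v <= 0)) stop("apparent pool sizes must be > 0")
  fit <- stats::lm.fit(cbind(1, isi), 1 / v)
  a <- unname(fit$coefficients[1])
  if (a <= 0)
    stop("non-positive intercept of 1/FRP' vs ISI; inputs are inconsistent")
  1 / a
}

#' Initial fusion probability from a regression through the origin
#'
#' Regresses the quantal content of the first train response on the
#' NTF-derived number of pre-existing tightly docked vesicles, forcing the
#' line through the origin; the slope `sum(m1*M_TS) / sum(M_TS^2)` measures
#' the initial fusion probability shared across the cohort.
#'
#' @param m1_by_synapse First-response quantal contents, one per synapse.
#' @param mts_by_synapse Matching `M_TS` estimates (vesicles).
#' @return Slope (dimensionless).
#' @export
#' @examples
#' pfusion_regression(c(10, 20, 30), c(40, 90, 160))
pfusion_regression <- function(m1_by_synapse, mts_by_synapse) {
  x <- as.numeric(mts_by_synapse); y <- as.numeric(m1_by_synapse)
  if (length(x) != length(y) || length(x) < 1)
    stop("inputs must have equal length >= 1")
  if (any(x < 0) || any(y < 0)) stop("inputs must be >= 0")
  if (sum(x^2) == 0) stop("all M_TS are zero; slope undefined")
  sum(y * x) / sum(x^2)
}

#' Compound release probabilities from priming and fusion factors
#'
#' The probability that a fast-releasing-pool vesicle is released by one
#' action potential is the compound probability of being tightly docked at
#' stimulus arrival times fusing given tight docking, `F = f_ts * p_fusion`;
#' the per-release-site probability additionally weights by the resting
#' site occupancy, `p_r = f_ts * p_fusion * occupancy`.
#'
#' @param f_ts Fraction of docked vesicles that are tightly docked,
#'   `TS/(LS+TS)`, in \[0, 1\].
#' @param p_fusion Fusion probability of a tightly docked vesicle, \[0, 1\].
#' @param occupancy Fraction of release sites occupied by a docked vesicle
#'   at rest, \[0, 1\] (default 1, giving `p_r = F`).
#' @return List with elements `F` and `p_r`.
#' @export
#' @examples
#' compound_probabilities(0.59, 0.22, 0.75)$p_r  # ~0.10
compound_probabilities <- function(f_ts, p_fusion, occupancy = 1) {
  v <- c(f_ts, p_fusion, occupancy)
  if (any(v < 0) || any(v > 1))
    stop("all factors must lie in [0, 1]")
  list(F = f_ts * p_fusion, p_r = f_ts * p_fusion * occupancy)
}

#' Short-term plasticity metrics of a quantal-content train
#'
#' Computes the standard train descriptors: the initial quantal content
#' `m1`; the depression ratio `m5/m1`; the facilitation ratio `mmax/m1`
#' with `m_max` the largest response among stimuli 2..n; the paired-pulse
#' ratio `m2/m1`; and the relative steady-state depression `ssd = m_ss/m1`,
#' with `m_ss` either the mean of the last five responses (measured or
#' noisy trains) or the final response (deterministic simulations).
#'
#' @param m Numeric vector of quantal contents (>= 5 stimuli; >= 40 for the
#'   `mean_last5` steady state).
#' @param f_stim Train frequency (Hz), recorded alongside the ratios (the
#'   paired-pulse ISI is `1/f_stim`).
#' @param ssd_mode `"mean_last5"` (default) or `"last"`.
#' @return A list of class `train_metrics` with fields `f_stim`, `m1`,
#'   `m5_over_m1`, `mmax_over_m1`, `ppr`, `ssd`, `isi`. Ratios are `NaN`
#'   when `m1` is zero (undefined).
#' @export
stp_metrics <- function(m, f_stim, ssd_mode = c("mean_last5", "last")) {
  ssd_mode <- match.arg(ssd_mode)
  if (inherits(m, "simulation_result")) {
    f_stim <- m$protocol$f_stim
    m <- m$m
  }
  if (length(m) < 5) stop("need at least 5 stimuli")
  if (any(m < 0)) stop("quantal contents must be >= 0")
  m1 <- m[1]
  m_ss <- steady_state_release(m, mode = ssd_mode)
  ratios <- if (m1 == 0) {
    list(m5 = NaN, mmax = NaN, ppr = NaN, ssd = NaN)
  } else {
    list(m5 = m[5] / m1, mmax = max(m[-1]) / m1, ppr = m[2] / m1,
         ssd = m_ss / m1)
  }
  structure(list(f_stim = f_stim, m1 = m1, m5_over_m1 = ratios$m5,
                 mmax_over_m1 = ratios$mmax, ppr = ratios$ppr,
                 ssd = ratios$ssd, isi = 1 / f_stim),
            class = "train_metrics")
}

#' Convert a membrane-capacitance jump to a vesicle count
#'
#' Divides the presynaptic capacitance increase by the capacitance of a
#' single vesicle (default 80 aF).
#'
#' @param delta_cm Capacitance jump (fF), > 0.
#' @param sv_capacitance Single-vesicle capacitance (aF), > 0, default 80.
#' @return Vesicle count.
#' @export
#' @examples
#' dcm_to_sv(167.92)  # ~2099 vesicles
dcm_to_sv <- function(delta_cm, sv_capacitance = 80) {
  if (any(delta_cm <= 0) || sv_capacitance <= 0)
    stop("inputs must be > 0")
  delta_cm * 1000 / sv_capacitance
}

#' Pool and fusion-probability estimates for a cohort of train recordings
#'
#' Convenience wrapper running the full estimator chain on a release tensor
#' plus its NTF decomposition: apparent pool sizes per high-frequency
#' layer, the ISI -> 0 extrapolated pool, the mature docked fraction
#' `f_ts = mean(M_TS) / (mean(M_TS) + mean(M_LS))`, the fusion-probability
#' regression and the compound probabilities.
#'
#' @param tensor A `release_tensor` whose layer names include the
#'   high-frequency trains given in `hf_layers`.
#' @param fit3 A three-component `ntf_decomposition` of the same tensor.
#' @param hf_layers Named numeric vector mapping layer name to `f_stim` in
#'   Hz for the unconditioned high-frequency layers (default
#'   `c(f50 = 50, f100 = 100, f200 = 200)`).
#' @param occupancy Resting site occupancy used for `p_r` (default the
#'   docked fraction is not known here, 0.75 as for a quarter of sites
#'   empty).
#' @return A list of class `pool_estimates`: `frp_apparent` (per layer),
#'   `frp`, `f_ts`, `p_fusion_hat`, `F`, `p_r`, `mean_mts`, `mean_mls`.
#' @export
pool_estimates <- function(tensor, fit3,
                           hf_layers = c(f50 = 50, f100 = 100, f200 = 200),
                           occupancy = 0.75) {
  stopifnot(inherits(fit3, "ntf_decomposition"),
            fit3$n_components == 3L)
  X <- unclass(tensor)
  lay <- dimnames(tensor)$layer
  if (!all(names(hf_layers) %in% lay))
    stop("tensor lacks the high-frequency layers ",
         paste(setdiff(names(hf_layers), lay), collapse = ", "))
  frp_app <- vapply(names(hf_layers), function(nm) {
    mbar <- rowMeans(X[, , match(nm, lay)])
    frp_apparent(mbar, hf_layers[[nm]])
  }, numeric(1))
  frp <- frp_extrapolate(frp_app, isi = 1 / unname(hf_layers))
  A <- fit3$amplitudes
  mean_mts <- mean(A[, "M_TS"]); mean_mls <- mean(A[, "M_LS"])
  f_ts <- mean_mts / (mean_mts + mean_mls)
  # initial quantal content averaged across the unconditioned frequencies
  uncond <- .unconditioned_layers(tensor)
  m1 <- apply(X[1, , uncond, drop = FALSE], 2, mean)
  p_hat <- pfusion_regression(m1, A[, "M_TS"])
  cp <- compound_probabilities(f_ts, min(1, p_hat), occupancy)
  structure(list(frp_apparent = frp_app, frp = frp, f_ts = f_ts,
                 p_fusion_hat = p_hat, F = cp$F, p_r = cp$p_r,
                 mean_mts = mean_mts, mean_mls = mean_mls),
            class = "pool_estimates")
}

#' @export
print.train_metrics <- function(x, ...) {
  cat(sprintf(
    "Train metrics (%g Hz): m1 = %.1f, m5/m1 = %.2f, mmax/m1 = %.2f, ppr = %.2f, ssd = %.2f\n",
    x$f_stim, x$m1, x$m5_over_m1, x$mmax_over_m1, x$ppr, x$ssd))
  invisible(x)
}

#' @export
print.pool_estimates <- function(x, ...) {
  cat(sprintf("Pool estimates: FRP = %.0f SVs (apparent: %s)\n", x$frp,
              paste(sprintf("%.0f", x$frp_apparent), collapse = ", ")))
  cat(sprintf("  f_TS = %.2f, p_fusion = %.3f, F = %.3f, p_r = %.3f\n",
              x$f_ts, x$p_fusion_hat, x$F, x$p_r))
  invisible(x)
}
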