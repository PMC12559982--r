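#' Assemble a release tensor from a tidy train table
#'
#' Builds the 3-way array (stimulus x synapse x layer) of quantal contents
#' that the NTF decomposition operates on. Every (synapse, layer) trace must
#' be complete, and all values non-negative.
#'
#' @param df Data frame with columns `synapse_id`, `layer`,
#'   `stimulus_index` (1-based) and `m`.
#' @return An object of class `release_tensor`: a numeric array with
#'   dimnames `stimulus`, `synapse`, `layer`.
#' @export
assemble_release_tensor <- function(df) {
  need <- c("synapse_id", "layer", "stimulus_index", "m")
  if (!all(need %in% names(df)))
    stop("table needs columns ", paste(need, collapse = ", "))
  syn <- unique(as.character(df$synapse_id))
  lay <- unique(as.character(df$layer))
  stim <- sort(unique(df$stimulus_index))
  if (!identical(as.integer(stim), seq_along(stim)))
    stop("stimulus_index must be 1..n_stim with no gaps")
  arr <- array(NA_real_, dim = c(length(stim), length(syn), length(lay)),
               dimnames = list(stimulus = stim, synapse = syn, layer = lay))
  arr[cbind(df$stimulus_index,
            match(as.character(df$synapse_id), syn),
            match(as.character(df$layer), lay))] <- df$m
  if (anyNA(arr)) stop("incomplete traces: every (synapse, layer) pair ",
                       "must contain every stimulus")
  if (any(arr < 0)) stop("quantal contents must be >= 0")
  structure(arr, class = c("release_tensor", "array"))
}

#' Flatten a release tensor back into a tidy train table
#' @param tensor A `release_tensor`.
#' @return Data frame with columns `synapse_id`, `layer`, `stimulus_index`,
#'   `m`.
#' @export
release_table <- function(tensor) {
  dn <- dimnames(tensor)
  d <- dim(tensor)
  data.frame(
    synapse_id = rep(dn$synapse, each = d[1], times = d[3]),
    layer = rep(dn$layer, each = d[1] * d[2]),
    stimulus_index = rep(seq_len(d[1]), times = d[2] * d[3]),
    m = as.vector(tensor),
    stringsAsFactors = FALSE
  )
}

# --- internals ----------------------------------------------------------

# reconstruction: X_hat[j, s, l] = sum_c A[s, c] * B[j, c, l]
.ntf_reconstruct <- function(A, B) {
  d <- c(dim(B)[1], nrow(A), dim(B)[3])
  out <- array(0, dim = d)
  for (l in seq_len(d[3]))
    out[, , l] <- B[, , l] %*% t(A)
  out
}

.ntf_sse <- function(X, A, B) sum((X - .ntf_reconstruct(A, B))^2)

# one multiplicative least-squares update of the shared amplitudes
.update_amplitudes <- function(X, A, B, eps = 1e-12) {
  num <- matrix(0, nrow(A), ncol(A))
  den <- matrix(0, nrow(A), ncol(A))
  Xh <- .ntf_reconstruct(A, B)
  for (l in seq_len(dim(B)[3])) {
    num <- num + crossprod(X[, , l], B[, , l])
    den <- den + crossprod(Xh[, , l], B[, , l])
  }
  A * num / (den + eps)
}

# one multiplicative update of the base functions; columns in `fixed` are
# left untouched (frozen components)
.update_basefuns <- function(X, A, B, fixed = integer(0), eps = 1e-12) {
  Xh <- .ntf_reconstruct(A, B)
  free <- setdiff(seq_len(ncol(A)), fixed)
  for (l in seq_len(dim(B)[3])) {
    num <- X[, , l] %*% A[, free, drop = FALSE]
    den <- Xh[, , l] %*% A[, free, drop = FALSE]
    B[, free, l] <- B[, free, l] * num / (den + eps)
  }
  B
}

# constraint projection: tie the first entry of the TS base function across
# the unconditioned-frequency layers (averaged; preconditioned layers start
# from a partially depleted tight-state pool and are left free), renormalise
# every free base function to unit cumulative sum and rescale the amplitudes
# compensatorily (by the mean norm factor across layers, the exact
# compensation when the factors agree).
.project_basefuns <- function(A, B, ts_col = 1L, fixed = integer(0),
                              tie_layers = seq_len(dim(B)[3])) {
  n_lay <- dim(B)[3]
  if (length(tie_layers) > 1 && !(ts_col %in% fixed)) {
    first <- mean(B[1, ts_col, tie_layers])
    B[1, ts_col, tie_layers] <- first
  }
  free <- setdiff(seq_len(ncol(A)), fixed)
  for (cc in free) {
    norms <- vapply(seq_len(n_lay), function(l) sum(B[, cc, l]), numeric(1))
    norms[norms <= 0] <- 1
    for (l in seq_len(n_lay)) B[, cc, l] <- B[, cc, l] / norms[l]
    A[, cc] <- A[, cc] * mean(norms)
  }
  list(A = A, B = B)
}

# geometric-decay initialisation of the TS base function from the mean trace
.init_bf_ts <- function(X) {
  n_stim <- dim(X)[1]
  tr <- apply(X, 1, mean)
  tr <- pmax(tr, max(tr) * 1e-6)
  k <- min(10L, n_stim)
  fit <- stats::lm.fit(cbind(1, seq_len(k) - 1), log(tr[seq_len(k)]))
  r <- exp(min(0, fit$coefficients[2]))
  bf <- r^(seq_len(n_stim) - 1)
  bf / sum(bf)
}

# near-zero-start base function: tiny first entry, flat elsewhere
.init_bf_small <- function(n_stim, first = 1e-6) {
  bf <- c(first, rep(1, n_stim - 1))
  bf / sum(bf)
}

# archetypal initial shapes for the three-component stage: pre-existing
# loosely docked vesicles fuse after a single maturation step (early hump),
# newly recruited vesicles require site refilling plus two maturation steps
# (late saturating ramp); both are silent at the first stimulus
.init_bf_hump <- function(n_stim, tau = 6) {
  j <- seq_len(n_stim) - 1
  bf <- c(0, j[-1] * exp(-j[-1] / tau))
  bf[1] <- 1e-6
  bf / sum(bf)
}

.init_bf_ramp <- function(n_stim, tau = 10) {
  j <- seq_len(n_stim) - 1
  bf <- c(0, 1 - exp(-j[-1] / tau))
  bf[1] <- 1e-6
  bf / sum(bf)
}

# non-negative least-squares amplitude initialisation against fixed BFs
.init_amplitudes <- function(X, B) {
  d <- dim(X)
  n_comp <- dim(B)[2]
  M <- matrix(aperm(B, c(1, 3, 2)), nrow = d[1] * d[3], ncol = n_comp)
  A <- matrix(0, d[2], n_comp)
  for (s in seq_len(d[2])) {
    x <- as.vector(X[, s, ])
    A[s, ] <- pracma::lsqnonneg(M, x)$x
  }
  A[A <= 0] <- 1e-6 * max(A)
  A
}

# Anchor constraints that make the component split identifiable. The
# two-component model is otherwise invariant under remixing (moving a
# multiple of one base function into the other while adjusting per-synapse
# amplitudes), so the data alone cannot set the component scales. Two
# model-derived facts close this degree of freedom:
#   (1) vesicles not tightly docked at rest contribute nothing to the first
#       response, so every non-TS base function has a (near-)zero first
#       entry;
#   (2) the cohort of initially tightly docked vesicles is fully consumed
#       well before the end of a >= 100 Hz train (over 99.5% by stimulus
#       25), so the TS base function of high-frequency layers has a
#       (near-)zero tail.
# Pinning both after every update keeps the iteration at the corner of the
# non-negativity cone that corresponds to the physical decomposition.
.pin_anchors <- function(B, ts_col, tail_layers, tail_start,
                         eps = 1e-9) {
  non_ts <- setdiff(seq_len(dim(B)[2]), ts_col)
  B[1, non_ts, ] <- eps
  n_stim <- dim(B)[1]
  if (length(tail_layers) > 0 && tail_start <= n_stim)
    B[tail_start:n_stim, ts_col, tail_layers] <- eps
  B
}

# layers stimulated at >= 100 Hz (by the "f<freq>..." naming convention);
# empty when layers are unnamed
.high_freq_layers <- function(layer_names) {
  if (is.null(layer_names)) return(integer(0))
  f <- suppressWarnings(as.numeric(sub("^f(\\d+).*$", "\\1", layer_names)))
  which(!is.na(f) & f >= 100)
}

.ntf_core <- function(X, A, B, n_iter, fixed = integer(0), ts_col = 1L,
                      tie_layers = seq_len(dim(B)[3]),
                      tail_layers = integer(0), tail_start = 26L,
                      adjust = NULL) {
  tss <- sum(X^2)
  history <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    A <- .update_amplitudes(X, A, B)
    B <- .update_basefuns(X, A, B, fixed = fixed)
    B <- .pin_anchors(B, ts_col, tail_layers, tail_start)
    pr <- .project_basefuns(A, B, ts_col = ts_col, fixed = fixed,
                            tie_layers = tie_layers)
    A <- pr$A; B <- pr$B
    if (!is.null(adjust)) A <- adjust(A)
    history[it] <- .ntf_sse(X, A, B) / tss
  }
  list(A = A, B = B, history = history)
}

# layers carrying unconditioned trains (the first-entry tie applies to
# these); preconditioned layers are marked by "_pre" in their name
.unconditioned_layers <- function(tensor) {
  lay <- dimnames(tensor)$layer
  if (is.null(lay)) return(seq_len(dim(tensor)[3]))
  idx <- grep("_pre", lay, invert = TRUE)
  if (length(idx) == 0) seq_len(dim(tensor)[3]) else idx
}

# --- exported operations ------------------------------------------------

#' Two-component NTF decomposition of a release tensor
#'
#' First stage of the decomposition: splits quantal release during trains
#' into the contribution of vesicles that were tightly docked (TS) prior to
#' stimulation and everything else (pre-existing loosely docked plus newly
#' recruited vesicles, LS+RS). Per-synapse component amplitudes are shared
#' across layers while the normalized release time courses ("base
#' functions") are shared across synapses within a layer. The TS base
#' function is initialised as a geometric decay fitted to the mean trace,
#' the LS+RS base function with a near-zero first entry; multiplicative
#' non-negative least-squares updates are iterated with, after every
#' iteration, the TS base function's first entry tied across layers
#' (projection by averaging) and all base functions renormalised to unit
#' cumulative sum with compensatory amplitude rescaling. The first entry of
#' the TS base function estimates the initial fusion probability, and the
#' TS amplitudes `M_TS` estimate the number of tightly docked vesicles per
#' synapse at rest.
#'
#' @param tensor A `release_tensor` (see [assemble_release_tensor()]).
#' @param n_iter Number of multiplicative update iterations (default 200).
#' @param tie_layers Indices of the layers across which the TS base
#'   function's first entry is tied; defaults to the unconditioned layers
#'   (layer names without `"_pre"`). Preconditioned trains start from a
#'   partially depleted tight-state pool, so their initial release fraction
#'   is legitimately lower and is left free.
#' @param tail_layers Indices of the layers in which the TS base function's
#'   tail (stimuli `tail_start..n`) is pinned at zero because the
#'   initially-tightly-docked cohort is fully consumed by then; defaults to
#'   all layers stimulated at >= 100 Hz. Together with the near-zero first
#'   entries of the non-TS base functions this anchors the otherwise
#'   scale-ambiguous component split.
#' @param tail_start First stimulus index of the pinned tail (default 26).
#' @return An object of class `ntf_decomposition` with elements
#'   `amplitudes` (matrix synapse x component, columns `M_TS`, `M_LSRS`),
#'   `base_functions` (array stimulus x component x layer, each column
#'   summing to one), `fit_history` (relative summed squared error per
#'   iteration), `initial_pfusion` (tied first entry of the TS base
#'   function) and `n_components`.
#' @export
ntf_two_component <- function(tensor, n_iter = 200, tie_layers = NULL,
                              tail_layers = NULL, tail_start = 26L) {
  X <- unclass(tensor)
  if (sum(X) <= 0) stop("all-zero tensor cannot be decomposed")
  if (any(X < 0)) stop("tensor must be non-negative")
  if (is.null(tie_layers)) tie_layers <- .unconditioned_layers(tensor)
  if (is.null(tail_layers))
    tail_layers <- .high_freq_layers(dimnames(tensor)$layer)
  d <- dim(X)
  n_lay <- d[3]
  bf_ts <- .init_bf_ts(X)
  bf_rest <- .init_bf_small(d[1])
  B <- array(0, dim = c(d[1], 2, n_lay))
  for (l in seq_len(n_lay)) {
    B[, 1, l] <- bf_ts
    B[, 2, l] <- bf_rest
  }
  B <- .pin_anchors(B, 1L, tail_layers, tail_start)
  A <- .init_amplitudes(X, B)
  fit <- .ntf_core(X, A, B, n_iter = n_iter, tie_layers = tie_layers,
                   tail_layers = tail_layers, tail_start = tail_start)
  colnames(fit$A) <- c("M_TS", "M_LSRS")
  structure(list(amplitudes = fit$A, base_functions = fit$B,
                 fit_history = fit$history,
                 initial_pfusion = mean(fit$B[1, 1, tie_layers]),
                 n_components = 2L,
                 layers = dimnames(tensor)$layer,
                 synapses = dimnames(tensor)$synapse),
            class = "ntf_decomposition")
}

#' Target value for the mean number of pre-existing loosely docked vesicles
#'
#' The three-component decomposition does not by itself separate the
#' pre-existing-LS component from newly recruited vesicles; the mean `M_LS`
#' is therefore steered towards an independently determined target, the
#' fast-releasing pool size minus the mean `M_TS`.
#'
#' @param frp Fast-releasing pool size (vesicles), from
#'   [frp_extrapolate()] or capacitance measurements.
#' @param mean_mts Mean TS amplitude across synapses (vesicles).
#' @return Target mean `M_LS` (vesicles), `frp - mean_mts`.
#' @export
#' @examples
#' mls_target_value(1967, 868)
mls_target_value <- function(frp, mean_mts) {
  if (!is.finite(frp) || !is.finite(mean_mts))
    stop("inputs must be finite")
  if (frp <= mean_mts)
    stop("frp must exceed mean_mts; upstream pool and amplitude estimates ",
         "are inconsistent")
  frp - mean_mts
}

#' Three-component NTF decomposition with a frozen TS base function
#'
#' Second stage: splits the non-TS release into contributions of
#' pre-existing loosely docked vesicles (`M_LS`) and newly recruited
#' vesicles (`M_RS`). The TS base functions are constrained to the result of
#' the two-component stage and are not updated. Because the LS/RS split is
#' not unique, after every iteration the mean `M_LS` across synapses is
#' shifted by `shift_fraction` towards `mls_target` by proportional
#' rescaling of the `M_LS` column, with a compensatory adjustment of `M_RS`
#' (preserving each synapse's total as closely as non-negativity allows).
#'
#' @param tensor A `release_tensor`.
#' @param frozen_bf_ts TS base functions to hold fixed: either a
#'   two-component `ntf_decomposition` (its TS base functions are taken) or
#'   an array/matrix of per-layer TS base functions.
#' @param mls_target Target mean `M_LS` (vesicles), from
#'   [mls_target_value()]; must be > 0.
#' @param n_iter Number of iterations (default 100).
#' @param shift_fraction Fraction of the remaining distance to the target
#'   applied per iteration (default 0.3, within the 0.25-0.35 working
#'   range; 0 disables the adjustment).
#' @param tie_layers Layers across which the (frozen) TS first entry is
#'   reported; defaults to the unconditioned layers.
#' @return An `ntf_decomposition` with amplitude columns `M_TS`, `M_LS`,
#'   `M_RS`.
#' @export
ntf_three_component <- function(tensor, frozen_bf_ts, mls_target,
                                n_iter = 100, shift_fraction = 0.3,
                                tie_layers = NULL) {
  X <- unclass(tensor)
  if (is.null(tie_layers)) tie_layers <- .unconditioned_layers(tensor)
  if (sum(X) <= 0) stop("all-zero tensor cannot be decomposed")
  if (!is.finite(mls_target) || mls_target <= 0)
    stop("mls_target must be > 0")
  if (shift_fraction < 0 || shift_fraction > 1)
    stop("shift_fraction must lie in [0, 1]")
  d <- dim(X)
  n_lay <- d[3]
  bf_ts <- if (inherits(frozen_bf_ts, "ntf_decomposition")) {
    frozen_bf_ts$base_functions[, 1, , drop = FALSE]
  } else if (is.matrix(frozen_bf_ts)) {
    array(frozen_bf_ts, dim = c(nrow(frozen_bf_ts), 1, ncol(frozen_bf_ts)))
  } else {
    array(frozen_bf_ts, dim = c(d[1], 1, n_lay))
  }
  if (dim(bf_ts)[1] != d[1] || dim(bf_ts)[3] != n_lay)
    stop("frozen TS base functions do not match the tensor dimensions")
  B <- array(0, dim = c(d[1], 3, n_lay))
  for (l in seq_len(n_lay)) {
    B[, 1, l] <- bf_ts[, 1, l]
    B[, 2, l] <- .init_bf_hump(d[1])   # LS: early hump, silent at stim 1
    B[, 3, l] <- .init_bf_ramp(d[1])   # RS: late ramp, silent at stim 1
  }
  A <- .init_amplitudes(X, B)
  adjust <- if (shift_fraction > 0) {
    function(A) {
      mean_mls <- mean(A[, 2])
      if (mean_mls <= 0) return(A)
      new_mean <- mean_mls + shift_fraction * (mls_target - mean_mls)
      fac <- new_mean / mean_mls
      delta <- A[, 2] * (fac - 1)
      A[, 2] <- A[, 2] * fac
      A[, 3] <- pmax(A[, 3] - delta, 0)
      A
    }
  } else NULL
  # the frozen TS base functions already carry the anchor structure from
  # the two-component stage; only the first-entry pins apply here
  fit <- .ntf_core(X, A, B, n_iter = n_iter, fixed = 1L,
                   tie_layers = tie_layers, tail_layers = integer(0),
                   adjust = adjust)
  colnames(fit$A) <- c("M_TS", "M_LS", "M_RS")
  structure(list(amplitudes = fit$A, base_functions = fit$B,
                 fit_history = fit$history,
                 initial_pfusion = mean(fit$B[1, 1, tie_layers]),
                 n_components = 3L,
                 layers = dimnames(tensor)$layer,
                 synapses = dimnames(tensor)$synapse),
            class = "ntf_decomposition")
}

#' Reconstruct the fitted tensor of an NTF decomposition
#' @param fit An `ntf_decomposition`.
#' @return Numeric array (stimulus x synapse x layer).
#' @export
ntf_fitted <- function(fit) {
  stopifnot(inherits(fit, "ntf_decomposition"))
  .ntf_reconstruct(fit$amplitudes, fit$base_functions)
}

#' @export
print.ntf_decomposition <- function(x, ...) {
  cat(sprintf("NTF decomposition: %d components, %d synapses, %d layers\n",
              x$n_components, nrow(x$amplitudes), dim(x$base_functions)[3]))
  cat(sprintf("  initial p_fusion (BF_TS first entry): %.3f\n",
              x$initial_pfusion))
  cat(sprintf("  relative SSE after %d iterations: %.3g\n",
              length(x$fit_history), x$fit_history[length(x$fit_history)]))
  invisible(x)
}
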