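# Significance testing of coupling/causality measures with random time-shift
# surrogates: one series is circularly rotated by a random shift (minimum
# tau_min lags away from either end of the series), destroying the coupling
# while preserving each series' own distribution and autocorrelation.

#' Random time-shift surrogate of a pair
#'
#' Circularly shifts y1 by a shift s drawn uniformly from
#' \{tau_min, ..., L - tau_min\} (wrapping the displaced values around the
#' beginning), leaving y2 untouched; the multiset of y1 values is preserved
#' exactly.
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param tau_min minimum shift in lags (also enforced as minimum distance
#'   from L, symmetrically).
#' @param shift optional fixed shift; when \code{NULL} (default) the shift is
#'   drawn from the current RNG stream.
#' @return A \code{ts_pair}; attribute \code{"shift"} records the applied
#'   shift.
#' @export
timeshift_surrogate <- function(pair, tau_min = 20L, shift = NULL) {
  stopifnot(inherits(pair, "ts_pair"))
  L <- pair$L
  if (2 * tau_min >= L)
    stop("tau_min too large: need 2 * tau_min < L")
  if (is.null(shift))
    shift <- sample(seq.int(tau_min, L - tau_min), 1L)
  idx <- ((seq_len(L) - 1L + shift) %% L) + 1L
  out <- ts_pair(pair$y1[idx], pair$y2, fs = pair$fs, labels = pair$labels,
                 min_length = min(L, 50L))
  attr(out, "shift") <- shift
  out
}

#' Surrogate-based significance test of a coupling/causality measure
#'
#' Computes \code{measure_fn} on the original pair and on \code{n_s}
#' time-shift surrogate pairs; the measure is deemed significant when the
#' observed value exceeds the 100(1-alpha)-th percentile of the surrogate
#' distribution. The percentile uses the nearest-rank rule
#' \code{sorted\[n_s - floor(alpha n_s) + 1\]} (for n_s = 100, alpha = 0.05:
#' the 5th largest surrogate value); the observed value is not pooled into
#' the surrogate distribution.
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param measure_fn function taking a \code{ts_pair} and returning one
#'   numeric value (a scalar information measure or a band-integrated
#'   spectral measure). Must be deterministic given its input.
#' @param n_s number of surrogates; values below 20 give unstable percentiles
#'   (warning).
#' @param alpha significance level.
#' @param tau_min minimum surrogate shift in lags.
#' @param seed master seed; each surrogate uses a derived sub-stream so runs
#'   are exactly reproducible.
#' @return An object of class \code{surrogate_test}: list with
#'   \code{observed}, \code{threshold}, \code{surrogate_values},
#'   \code{significant}, \code{alpha}, \code{n_s}, \code{tau_min},
#'   \code{seed}.
#' @export
significance_test <- function(pair, measure_fn, n_s = 100L, alpha = 0.05,
                              tau_min = 20L, seed = 1L) {
  stopifnot(is.function(measure_fn))
  if (n_s < 20L) warning("n_s < 20: percentile threshold is unstable")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  observed <- measure_fn(pair)
  stopifnot(is.numeric(observed), length(observed) == 1L)
  set.seed(seed)
  shifts <- sample(seq.int(tau_min, pair$L - tau_min), n_s, replace = TRUE)
  surrogate_values <- vapply(shifts, function(s)
    measure_fn(timeshift_surrogate(pair, tau_min, shift = s)), numeric(1))
  rank_idx <- n_s - floor(alpha * n_s) + 1L
  threshold <- sort(surrogate_values)[min(rank_idx, n_s)]
  structure(list(observed = observed, threshold = threshold,
                 surrogate_values = surrogate_values,
                 significant = observed > threshold,
                 alpha = alpha, n_s = as.integer(n_s),
                 tau_min = as.integer(tau_min), seed = seed),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, digits = 4, ...) {
  cat(sprintf("surrogate test: observed = %.*f, threshold = %.*f (alpha = %g, n_s = %d) -> %s\n",
              digits, x$observed, digits, x$threshold, x$alpha, x$n_s,
              if (x$significant) "SIGNIFICANT" else "not significant"))
  invisible(x)
}
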