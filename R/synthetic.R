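# Seeded generator of bivariate ARX realizations with analytically known
# population measures: the fixture factory that makes every estimator in the
# package verifiable against closed forms.

#' Simulation specification
#'
#' @param model a stable \code{\link{arx_model}} used as ground truth.
#' @param L number of retained samples.
#' @param n_transient burn-in samples discarded before recording (default
#'   1000).
#' @param seed RNG seed.
#' @param innovations \code{"gaussian"} (default; the regime where linear and
#'   information measures coincide) or \code{"uniform"} (variance-matched, to
#'   probe estimator robustness).
#' @param description free-text tag.
#' @return A list of class \code{sim_spec}.
#' @export
sim_spec <- function(model, L, n_transient = 1000L, seed = 1L,
                     innovations = c("gaussian", "uniform"),
                     description = "") {
  check_stable(model)
  innovations <- match.arg(innovations)
  structure(list(model = model, L = as.integer(L),
                 n_transient = as.integer(n_transient), seed = seed,
                 innovations = innovations, description = description),
            class = "sim_spec")
}

#' Simulate a bivariate ARX realization
#'
#' Generates innovations with the model covariance (via its Cholesky square
#' root), iterates the ARX recursion from zero initial conditions, discards
#' the burn-in and returns the remaining samples as a pair. Fixed seed gives
#' bit-identical output.
#'
#' @param spec a \code{\link{sim_spec}} (or an \code{\link{arx_model}}, in
#'   which case \code{L} and \code{seed} must be supplied).
#' @param L,seed convenience overrides when \code{spec} is a model.
#' @param fs sampling frequency attached to the output pair.
#' @return A \code{\link{ts_pair}} of length \code{L}.
#' @export
simulate_arx <- function(spec, L = NULL, seed = NULL, fs = 1) {
  if (inherits(spec, "arx_model"))
    spec <- sim_spec(spec, L = L, seed = if (is.null(seed)) 1L else seed)
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(L)) spec$L <- as.integer(L)
  if (!is.null(seed)) spec$seed <- seed
  model <- spec$model
  check_stable(model)
  p <- model$p
  n_tot <- spec$L + spec$n_transient + p
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  E <- switch(spec$innovations,
              gaussian = matrix(rnorm(2 * n_tot), n_tot, 2),
              uniform = matrix(runif(2 * n_tot, -sqrt(3), sqrt(3)),
                               n_tot, 2))
  U <- E %*% chol(model$Sigma_U)          # rows have covariance Sigma_U
  Y <- matrix(0, n_tot, 2)
  A <- model$A
  for (n in (p + 1):n_tot) {
    acc <- U[n, ]
    for (k in seq_len(p)) acc <- acc + A[[k]] %*% Y[n - k, ]
    Y[n, ] <- acc
  }
  keep <- (n_tot - spec$L + 1):n_tot
  ts_pair(Y[keep, 1], Y[keep, 2], fs = fs,
          min_length = min(spec$L, 50L))
}

#' Benchmark generator with oscillatory self-dynamics and lag-1 coupling
#'
#' Each process has AR(2) self-dynamics with a complex pole pair of modulus
#' \code{rho} at normalized frequency \code{f} (self coefficients
#' \code{2 rho cos(2 pi f)} at lag 1 and \code{-rho^2} at lag 2), mimicking
#' the band-limited rhythms of physiological variability; cross-coupling acts
#' at lag 1 with gains \code{c12} (1 -> 2) and \code{c21} (2 -> 1). Unit
#' innovation variances, no instantaneous effects.
#'
#' @param c12 coupling gain from process 1 to process 2.
#' @param c21 coupling gain from process 2 to process 1.
#' @param rho1,f1 pole modulus (0 <= rho < 1) and normalized frequency
#'   (0 < f < 0.5) of process 1; defaults 0.8 and 0.1 (a low-frequency
#'   rhythm).
#' @param rho2,f2 same for process 2; defaults 0.9 and 0.25 (a
#'   high-frequency rhythm).
#' @param Sigma_U innovation covariance; default identity.
#' @param L,seed,n_transient passed to \code{\link{sim_spec}}.
#' @return A \code{\link{sim_spec}} (its \code{$model} is the ground truth).
#' @export
benchmark_physio <- function(c12 = 0.5, c21 = 0, rho1 = 0.8, f1 = 0.1,
                             rho2 = 0.9, f2 = 0.25, Sigma_U = diag(2),
                             L = 2000L, seed = 1L, n_transient = 1000L) {
  if (rho1 < 0 || rho1 >= 1 || rho2 < 0 || rho2 >= 1)
    stop("pole moduli must satisfy 0 <= rho < 1")
  if (f1 <= 0 || f1 >= 0.5 || f2 <= 0 || f2 >= 0.5)
    stop("pole frequencies must lie strictly inside (0, 0.5)")
  A1 <- matrix(c(2 * rho1 * cos(2 * pi * f1), c12,
                 c21, 2 * rho2 * cos(2 * pi * f2)),
               2, 2, byrow = FALSE)
  # column-major fill above puts c12 in position [2,1]: driver 1 -> target 2
  A2 <- diag(c(-rho1^2, -rho2^2))
  model <- arx_model(list(A1, A2), Sigma_U)
  check_stable(model)
  sim_spec(model, L = L, n_transient = n_transient, seed = seed,
           description = sprintf("oscillatory benchmark c12=%g c21=%g", c12,
                                 c21))
}

#' The closed-form unidirectional benchmark
#'
#' Y1 white with unit variance, \code{Y2_n = c * Y1_\{n-1\} + U2_n} with unit
#' innovation variance and no instantaneous effects. For c = 1 the population
#' values are known exactly: \code{F_gc(1->2) = log 2}, \code{TE(1->2) =
#' log(2)/2}, \code{coh2 = 0.5} and \code{DC2(1->2) = 0.5} flat over
#' frequency, all other measures zero.
#'
#' @param gain coupling gain at lag 1 (default 1).
#' @return An \code{\link{arx_model}}.
#' @export
benchmark_unidirectional <- function(gain = 1) {
  arx_model(list(matrix(c(0, gain, 0, 0), 2, 2)), diag(2))
}

#' Population measures of an ARX model
#'
#' Ground-truth time-domain, spectral and band-integrated measures computed
#' analytically from the model parameters (no data): restricted variances via
#' the state-space/Riccati route, spectra via spectral factorization, band
#' values via the spectral integration property. Used as the oracle for all
#' estimator tests.
#'
#' @param model a stable \code{\link{arx_model}}.
#' @param n_freq spectral grid size.
#' @param fs sampling frequency for the band table.
#' @param bands named list of bands in the units of \code{fs} (default whole
#'   band + LF/HF, see \code{\link{band_measures}}).
#' @return A list with \code{time} (a \code{td_measures}), \code{spectral}
#'   (a \code{spectral_decomp}), \code{bands} (a data frame).
#' @export
population_measures <- function(model, n_freq = 1001L, fs = 1, bands = NULL) {
  check_stable(model)
  r1 <- restrict_ss(model, 1L)
  r2 <- restrict_ss(model, 2L)
  td <- time_domain_measures(model, r1, r2, clip_negative = FALSE)
  spec <- spectral_measures(model, n_freq = n_freq, fs = fs,
                            warn_nondiagonal = FALSE)
  list(time = td, spectral = spec, bands = band_measures(spec, bands))
}

#' Random stable ARX models
#'
#' Draws coefficient matrices with independent normal entries and rescales
#' them until the companion spectral radius is below \code{rho_max}; the
#' innovation covariance is either the identity-plus-noise SPD matrix or
#' diagonal (strictly causal) as requested. Intended for property-style tests
#' across many models.
#'
#' @param p model order.
#' @param rho_max upper bound for the companion spectral radius.
#' @param strictly_causal if \code{TRUE}, diagonal innovation covariance.
#' @param coef_scale standard deviation of the raw coefficient entries.
#' @return An \code{\link{arx_model}}.
#' @export
random_stable_model <- function(p = 2L, rho_max = 0.9,
                                strictly_causal = TRUE, coef_scale = 0.4) {
  repeat {
    A <- lapply(seq_len(p), function(k)
      matrix(rnorm(4, sd = coef_scale / k), 2, 2))
    S <- if (strictly_causal) diag(exp(runif(2, -0.5, 0.5))) else {
      M <- matrix(rnorm(4, sd = 0.4), 2, 2)
      diag(2) + crossprod(M)
    }
    m <- arx_model(A, S)
    rho <- spectral_radius(companion_matrix(m))
    if (rho < rho_max && m$stable) return(m)
    # shrink towards stability rather than rejecting outright
    A <- lapply(seq_along(A), function(k)
      A[[k]] * (0.95 * rho_max / max(rho, 1e-12))^k)
    m <- arx_model(A, S)
    if (m$stable && spectral_radius(companion_matrix(m)) < rho_max)
      return(m)
  }
}
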