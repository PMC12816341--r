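# Frequency-domain representation: parametric PSD by spectral factorization,
# coherence, directed coherence, Geweke spectral profiles, band integration,
# and the non-parametric weighted-covariance PSD with a Parzen lag window.
#
# The transfer matrix is H(f) = [I - sum_k A_k e^{-j 2 pi f k}]^{-1} and the
# PSD matrix factorizes as P(f) = H Sigma_U H*.  All profiles live on a
# uniform normalized-frequency grid on [0, 0.5] (inclusive endpoints).

#' Transfer matrix and parametric PSD of an ARX model
#'
#' @param model a stable \code{\link{arx_model}}.
#' @param n_freq number of grid points on \[0, 0.5\] (inclusive endpoints).
#' @param fs sampling frequency used to report the physical frequency axis.
#' @return An object of class \code{spectral_decomp}: list with
#'   \code{f_norm} (normalized frequencies), \code{f_hz} (= f_norm * fs),
#'   \code{fs}, \code{P} (complex array 2 x 2 x n_freq, Hermitian),
#'   \code{H} (complex array 2 x 2 x n_freq), \code{Sigma_U}, \code{det_P}
#'   (real vector).
#' @export
transfer_and_psd <- function(model, n_freq = 1001L, fs = 1) {
  check_stable(model)
  if (n_freq < 64L) stop("n_freq must be at least 64")
  fgrid <- seq(0, 0.5, length.out = n_freq)
  p <- model$p
  S <- model$Sigma_U
  # A-bar(f) = I - sum_k A_k e^{-j 2 pi f k}, element-wise over the grid
  Zk <- exp(outer(-2i * pi * fgrid, seq_len(p)))    # n_freq x p
  coef <- function(i, j) vapply(model$A, function(a) a[i, j], numeric(1))
  a11 <- 1 - as.vector(Zk %*% coef(1, 1))
  a12 <- -as.vector(Zk %*% coef(1, 2))
  a21 <- -as.vector(Zk %*% coef(2, 1))
  a22 <- 1 - as.vector(Zk %*% coef(2, 2))
  dA <- a11 * a22 - a12 * a21
  if (any(Mod(dA) < 1e-12)) stop("marginally stable: pole on the unit circle")
  H11 <- a22 / dA
  H12 <- -a12 / dA
  H21 <- -a21 / dA
  H22 <- a11 / dA
  s11 <- S[1, 1]; s22 <- S[2, 2]; s12 <- S[1, 2]
  P11 <- s11 * Mod(H11)^2 + s22 * Mod(H12)^2 + 2 * s12 * Re(H11 * Conj(H12))
  P22 <- s11 * Mod(H21)^2 + s22 * Mod(H22)^2 + 2 * s12 * Re(H21 * Conj(H22))
  P12 <- s11 * H11 * Conj(H21) + s22 * H12 * Conj(H22) +
    s12 * (H11 * Conj(H22) + H12 * Conj(H21))
  H <- array(NA_complex_, c(2, 2, n_freq))
  P <- array(NA_complex_, c(2, 2, n_freq))
  H[1, 1, ] <- H11; H[1, 2, ] <- H12; H[2, 1, ] <- H21; H[2, 2, ] <- H22
  P[1, 1, ] <- P11; P[1, 2, ] <- P12; P[2, 1, ] <- Conj(P12); P[2, 2, ] <- P22
  detP <- Mod(dA)^(-2) * det(S)  # |det H|^2 det Sigma_U, real > 0
  structure(list(f_norm = fgrid, f_hz = fgrid * fs, fs = fs,
                 P = P, H = H, Sigma_U = S, det_P = detP,
                 n_freq = n_freq),
            class = "spectral_decomp")
}

#' @export
print.spectral_decomp <- function(x, ...) {
  cat(sprintf("spectral_decomp: %d frequencies on [0, 0.5] (fs = %g)\n",
              x$n_freq, x$fs))
  cat("  fields:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Magnitude-squared coherence profile
#'
#' \code{coh2 = |P_12|^2 / (P_11 P_22)} in \[0, 1\]; also stores the
#' non-normalized spectral total dependence \code{f_td = -log(1 - coh2)}.
#'
#' @param spec a \code{spectral_decomp} with the PSD filled.
#' @return \code{spec} with fields \code{coh2} and \code{f_td} added.
#' @export
coherence <- function(spec) {
  stopifnot(inherits(spec, "spectral_decomp"))
  P11 <- Re(spec$P[1, 1, ])
  P22 <- Re(spec$P[2, 2, ])
  if (any(P11 <= 0) || any(P22 <= 0)) stop("zero diagonal PSD")
  coh2 <- Mod(spec$P[1, 2, ])^2 / (P11 * P22)
  spec$coh2 <- pmin(coh2, 1)
  # f_td = log(P11 P22 / det P) = -log(1 - coh2), computed from det P for
  # numerical symmetry with the Geweke decomposition
  spec$f_td <- log(P11 * P22 / spec$det_P)
  spec
}

#' Squared directed coherence profiles
#'
#' Under strict causality (diagonal innovation covariance) the squared DC from
#' driver j to target i is
#' \code{sigma_j^2 |H_ij|^2 / (sigma_1^2 |H_i1|^2 + sigma_2^2 |H_i2|^2)}, the
#' normalized share of the target spectrum causally due to the driver. When
#' the innovation covariance is not diagonal a warning is issued and the
#' diagonal terms are used; the power-decomposition interpretation is then
#' lost.
#'
#' @param spec a \code{spectral_decomp}.
#' @return \code{spec} with \code{dc2_12} (1 -> 2) and \code{dc2_21} (2 -> 1)
#'   added.
#' @export
directed_coherence <- function(spec) {
  stopifnot(inherits(spec, "spectral_decomp"))
  S <- spec$Sigma_U
  if (abs(S[1, 2]) > 1e-8 * sqrt(S[1, 1] * S[2, 2]))
    warning("innovation covariance is not diagonal: directed coherence ",
            "computed from diagonal terms only (no strict causality)")
  s1 <- S[1, 1]
  s2 <- S[2, 2]
  H <- spec$H
  d1 <- s1 * Mod(H[1, 1, ])^2 + s2 * Mod(H[1, 2, ])^2  # target 1 row
  d2 <- s1 * Mod(H[2, 1, ])^2 + s2 * Mod(H[2, 2, ])^2  # target 2 row
  spec$dc2_12 <- s1 * Mod(H[2, 1, ])^2 / d2  # influence of 1 onto 2
  spec$dc2_21 <- s2 * Mod(H[1, 2, ])^2 / d1  # influence of 2 onto 1
  spec
}

#' Geweke spectral measures of total dependence, causality and instantaneous
#' causality
#'
#' \code{f_gc_12 = log(P_22 / (sigma_2^2 |H_22|^2))} (and symmetrically for
#' 2 -> 1); \code{f_ic} is defined so that the frequency-wise decomposition
#' \code{f_td = f_gc_12 + f_gc_21 + f_ic} holds exactly at every grid point.
#' The causal profiles can be negative at some frequencies when the process is
#' not strictly causal; this is expected, not an error.
#'
#' @param spec a \code{spectral_decomp}.
#' @return \code{spec} with \code{f_td}, \code{f_gc_12}, \code{f_gc_21},
#'   \code{f_ic} added.
#' @export
geweke_spectral <- function(spec) {
  stopifnot(inherits(spec, "spectral_decomp"))
  S <- spec$Sigma_U
  P11 <- Re(spec$P[1, 1, ])
  P22 <- Re(spec$P[2, 2, ])
  iso1 <- S[1, 1] * Mod(spec$H[1, 1, ])^2  # part of P11 due to Y1 itself
  iso2 <- S[2, 2] * Mod(spec$H[2, 2, ])^2
  spec$f_gc_12 <- log(P22 / iso2)
  spec$f_gc_21 <- log(P11 / iso1)
  spec$f_ic <- log(iso1 * iso2 / spec$det_P)
  spec$f_td <- log(P11 * P22 / spec$det_P)
  spec
}

#' Full spectral pipeline for an ARX model
#'
#' Runs \code{\link{transfer_and_psd}}, \code{\link{coherence}},
#' \code{\link{directed_coherence}} and \code{\link{geweke_spectral}}.
#'
#' @inheritParams transfer_and_psd
#' @param warn_nondiagonal forward warning from
#'   \code{\link{directed_coherence}}; set \code{FALSE} to silence when
#'   instantaneous effects are known to be present.
#' @return A fully populated \code{spectral_decomp}.
#' @export
spectral_measures <- function(model, n_freq = 1001L, fs = 1,
                              warn_nondiagonal = TRUE) {
  spec <- transfer_and_psd(model, n_freq = n_freq, fs = fs)
  spec <- coherence(spec)
  spec <- if (warn_nondiagonal) directed_coherence(spec) else
    suppressWarnings(directed_coherence(spec))
  geweke_spectral(spec)
}

#' Validity of the spectral integration property for the directional measures
#'
#' The total-dependence profile always satisfies
#' \code{F_td = 2 integral of f_td over [0, 1/2]} for a stable model. For the
#' directional Geweke profiles the identity
#' \code{F_gc = 2 integral of f_gc} additionally requires the driver's own-lag
#' polynomial \code{1 - sum_k a_\{ii,k\} w^k} to be minimum phase; otherwise
#' (by Jensen's formula applied to the transfer-matrix entry) the integral
#' falls short of F by the excess \code{sum log |mu|^2} over the reciprocal
#' roots \code{mu} outside the unit disk, and the IC profile integral picks up
#' the combined excess. This function computes those excesses so users can
#' tell when band-integrated GC values are exact.
#'
#' @param model a stable \code{\link{arx_model}}.
#' @param tol excesses below this are reported as exactly integrable.
#' @return A list with \code{excess_12}, \code{excess_21} (nats x 2, the
#'   shortfall of \code{2 integral f_gc} relative to \code{F_gc} for each
#'   direction) and logical flags \code{integrable_12}, \code{integrable_21}.
#' @export
spectral_gc_integrability <- function(model, tol = 1e-10) {
  check_stable(model)
  jensen_excess <- function(coefs) {
    if (all(coefs == 0)) return(0)
    w <- polyroot(c(1, -coefs))       # roots of 1 - sum c_k w^k
    inside <- Mod(w) < 1
    if (!any(inside)) 0 else -2 * sum(log(Mod(w)[inside]))
  }
  a11 <- vapply(model$A, function(a) a[1, 1], numeric(1))
  a22 <- vapply(model$A, function(a) a[2, 2], numeric(1))
  ex12 <- jensen_excess(a11)  # affects F_gc(1->2): H_22 carries Abar_11
  ex21 <- jensen_excess(a22)  # affects F_gc(2->1): H_11 carries Abar_22
  list(excess_12 = ex12, excess_21 = ex21,
       integrable_12 = ex12 < tol, integrable_21 = ex21 < tol)
}

#' Integrate a spectral profile over a frequency band
#'
#' Trapezoidal integration over normalized frequency, with linear
#' interpolation of the profile at band edges that fall between grid points,
#' so that integrals over a partition of \[0, fs/2\] add up exactly to the
#' whole-band integral. The whole-band integral of a Geweke profile equals
#' the information measure in nats; twice the integral equals the F measure.
#'
#' @param spec a \code{spectral_decomp} holding the profile.
#' @param profile name of the profile field (e.g. \code{"f_gc_12"}) or a
#'   numeric vector on the grid of \code{spec}.
#' @param band numeric \code{c(f_lo, f_hi)} in the same units as \code{fs};
#'   default the whole band \code{c(0, fs/2)}.
#' @return The integral over normalized frequency (nats for Geweke profiles).
#' @export
band_integrate <- function(spec, profile, band = NULL) {
  stopifnot(inherits(spec, "spectral_decomp"))
  y <- if (is.character(profile)) {
    if (is.null(spec[[profile]])) stop("profile not computed: ", profile)
    spec[[profile]]
  } else as.numeric(profile)
  f <- spec$f_norm
  if (is.null(band)) band <- c(0, spec$fs / 2)
  b <- sort(band) / spec$fs          # to normalized frequency
  b[1] <- max(b[1], 0)
  b[2] <- min(b[2], 0.5)
  if (b[2] <= b[1]) stop("empty band on the frequency grid")
  yl <- stats::approx(f, y, xout = b[1])$y
  yu <- stats::approx(f, y, xout = b[2])$y
  inner <- which(f > b[1] & f < b[2])
  xs <- c(b[1], f[inner], b[2])
  ys <- c(yl, y[inner], yu)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Band-integrated measures from a spectral decomposition
#'
#' @param spec a fully populated \code{spectral_decomp} (see
#'   \code{\link{spectral_measures}}).
#' @param bands named list of \code{c(f_lo, f_hi)} bands in the units of
#'   \code{fs}; default whole band plus the cardiovascular LF/HF convention
#'   scaled by \code{fs}.
#' @return A data frame with one row per band and columns for the integrated
#'   information measures \code{I_mir}, \code{T_12}, \code{T_21}, \code{I_it}
#'   (nats) and their doubled F counterparts.
#' @export
band_measures <- function(spec, bands = NULL) {
  stopifnot(inherits(spec, "spectral_decomp"))
  if (is.null(bands))
    bands <- list(total = c(0, spec$fs / 2),
                  LF = c(0.04, 0.15) * spec$fs,
                  HF = c(0.15, 0.40) * spec$fs)
  rows <- lapply(names(bands), function(nm) {
    bd <- bands[[nm]]
    data.frame(band = nm, f_lo = bd[1], f_hi = bd[2],
               I_mir = band_integrate(spec, "f_td", bd),
               T_12 = band_integrate(spec, "f_gc_12", bd),
               T_21 = band_integrate(spec, "f_gc_21", bd),
               I_it = band_integrate(spec, "f_ic", bd))
  })
  out <- do.call(rbind, rows)
  out$F_td <- 2 * out$I_mir
  out$F_gc_12 <- 2 * out$T_12
  out$F_gc_21 <- 2 * out$T_21
  out$F_ic <- 2 * out$I_it
  out
}

#' Parzen lag window
#'
#' Piecewise-cubic window: \code{1 - 6u^2 + 6|u|^3} for |u| <= 1/2,
#' \code{2(1-|u|)^3} for 1/2 < |u| <= 1, zero beyond; \code{u = k/tau}.
#'
#' @param k integer lag(s).
#' @param tau truncation lag.
#' @return Window weights in \[0, 1\], \code{w(0) = 1}.
#' @export
parzen_window <- function(k, tau) {
  u <- abs(k) / tau
  ifelse(u <= 0.5, 1 - 6 * u^2 + 6 * u^3,
         ifelse(u <= 1, 2 * (1 - u)^3, 0))
}

lag_window <- function(k, tau, window = c("parzen", "hanning", "hamming")) {
  window <- match.arg(window)
  u <- abs(k) / tau
  switch(window,
         parzen = parzen_window(k, tau),
         hanning = ifelse(u <= 1, 0.5 * (1 + cos(pi * u)), 0),
         hamming = ifelse(u <= 1, 0.54 + 0.46 * cos(pi * u), 0))
}

#' Truncation lag for a requested Parzen spectral bandwidth
#'
#' Inverts the Parzen bandwidth relation \code{Bw = 1.273 fs / tau}:
#' \code{tau = 1.273 fs / Bw}. The raw (possibly non-integer) value is
#' reported together with the usable integer lag (ceiling, at least 1).
#'
#' @param bandwidth requested spectral bandwidth, same units as \code{fs}.
#' @param fs sampling frequency.
#' @return List with \code{tau_raw} and \code{tau} (integer lag).
#' @export
parzen_truncation_lag <- function(bandwidth, fs = 1) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  tau_raw <- 1.273 * fs / bandwidth
  list(tau_raw = tau_raw, tau = max(1L, as.integer(ceiling(tau_raw))))
}

#' Weighted-covariance (lag-window) PSD estimate
#'
#' Non-parametric PSD matrix estimate
#' \code{P(f) = sum_\{k=-tau..tau\} w(k) R(k) e^\{-j 2 pi f k\}} with biased
#' (1/L) correlation estimates and a Parzen window by default, evaluated on
#' the same uniform grid as the parametric route.
#'
#' @param pair a zero-mean \code{\link{ts_pair}}.
#' @param truncation_lag lag tau at which the correlation estimates are
#'   truncated (1 <= tau <= L - 1).
#' @param n_freq grid size on \[0, 0.5\].
#' @param window lag-window family (\code{"parzen"} default).
#' @return A \code{spectral_decomp} with the PSD matrix \code{P} filled
#'   (no transfer matrix: \code{H} is \code{NULL}).
#' @export
wc_psd <- function(pair, truncation_lag, n_freq = 1001L,
                   window = c("parzen", "hanning", "hamming")) {
  window <- match.arg(window)
  stopifnot(inherits(pair, "ts_pair"))
  tau <- as.integer(truncation_lag)
  if (tau < 1 || tau > pair$L - 1)
    stop("truncation_lag must be between 1 and L - 1")
  lags <- (-tau):tau
  w <- lag_window(lags, tau, window)
  R11 <- cross_correlation(pair, tau, "auto1")$R
  R22 <- cross_correlation(pair, tau, "auto2")$R
  R12 <- cross_correlation(pair, tau, "cross")$R
  fgrid <- seq(0, 0.5, length.out = n_freq)
  E <- exp(-2i * pi * outer(fgrid, lags))   # n_freq x (2 tau + 1)
  P11 <- Re(E %*% (w * R11))
  P22 <- Re(E %*% (w * R22))
  P12 <- as.vector(E %*% (w * R12))
  P <- array(NA_complex_, c(2, 2, n_freq))
  P[1, 1, ] <- P11
  P[2, 2, ] <- P22
  P[1, 2, ] <- P12
  P[2, 1, ] <- Conj(P12)
  detP <- P11 * P22 - Mod(P12)^2
  structure(list(f_norm = fgrid, f_hz = fgrid * pair$fs, fs = pair$fs,
                 P = P, H = NULL, Sigma_U = NULL, det_P = detP,
                 n_freq = n_freq, window = window, truncation_lag = tau),
            class = "spectral_decomp")
}

#' Export spectral profiles as a data frame
#'
#' One row per frequency bin with columns \code{f_norm, f_hz, P11, P22,
#' ReP12, ImP12} plus whichever of \code{coh2, dc2_12, dc2_21, f_td, f_gc_12,
#' f_gc_21, f_ic} have been computed; suitable for CSV serialization.
#'
#' @param spec a \code{spectral_decomp}.
#' @return A data frame.
#' @export
spectral_table <- function(spec) {
  stopifnot(inherits(spec, "spectral_decomp"))
  df <- data.frame(f_norm = spec$f_norm, f_hz = spec$f_hz,
                   P11 = Re(spec$P[1, 1, ]), P22 = Re(spec$P[2, 2, ]),
                   ReP12 = Re(spec$P[1, 2, ]), ImP12 = Im(spec$P[1, 2, ]))
  for (fld in c("coh2", "dc2_12", "dc2_21", "f_td", "f_gc_12", "f_gc_21",
                "f_ic"))
    if (!is.null(spec[[fld]])) df[[fld]] <- spec[[fld]]
  df
}
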