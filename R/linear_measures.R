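# Time-domain measures of coupling/causality from full + restricted models,
# and static correlation tools.
#
# With lambda_i^2 the restricted innovation variances and Sigma_U the full
# innovation covariance (diagonal sigma_1^2, sigma_2^2):
#   F_td    = log( lambda_1^2 lambda_2^2 / |Sigma_U| )        total dependence
#   F_gc_12 = log( lambda_2^2 / sigma_2^2 )                   GC  1 -> 2
#   F_gc_21 = log( lambda_1^2 / sigma_1^2 )                   GC  2 -> 1
#   F_ic    = log( sigma_1^2 sigma_2^2 / |Sigma_U| )          instantaneous
# and F_td = F_gc_12 + F_gc_21 + F_ic holds exactly.  For jointly Gaussian
# processes the information-theoretic counterparts (MIR, TE, IT, in nats) are
# exactly half of the F values.

#' Pearson correlation coefficient of a pair
#'
#' @param pair a \code{\link{ts_pair}}.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(pair) {
  stopifnot(inherits(pair, "ts_pair"))
  if (var(pair$y1) == 0 || var(pair$y2) == 0)
    stop("zero variance: correlation undefined")
  cor(pair$y1, pair$y2)
}

#' Biased cross-correlation function
#'
#' Computes \code{R(k) = (1/L) sum_n y1_n y2_\{n-k\}} for k = -max_lag..max_lag
#' (biased 1/L normalization, which guarantees a positive semi-definite
#' sequence for spectral use). For real data \code{R_12(-k) = R_21(k)}.
#'
#' @param pair a \code{\link{ts_pair}} (series should be zero mean).
#' @param max_lag largest lag (must be < L).
#' @param which \code{"cross"} for R_\{y1 y2\}, \code{"auto1"}/\code{"auto2"}
#'   for the autocorrelations.
#' @return A data frame with columns \code{lag} and \code{R}.
#' @export
cross_correlation <- function(pair, max_lag, which = c("cross", "auto1", "auto2")) {
  which <- match.arg(which)
  stopifnot(inherits(pair, "ts_pair"))
  L <- pair$L
  if (max_lag >= L) stop("max_lag must be smaller than the series length")
  a <- switch(which, cross = pair$y1, auto1 = pair$y1, auto2 = pair$y2)
  b <- switch(which, cross = pair$y2, auto1 = pair$y1, auto2 = pair$y2)
  Rk <- function(k) { # R(k) = (1/L) sum a_n b_{n-k}
    if (k >= 0) sum(a[(k + 1):L] * b[1:(L - k)]) / L
    else        sum(a[1:(L + k)] * b[(1 - k):L]) / L
  }
  lags <- (-max_lag):max_lag
  data.frame(lag = lags, R = vapply(lags, Rk, numeric(1)))
}

#' Mutual information of a bivariate Gaussian from its correlation
#'
#' \code{I = -0.5 * log(1 - rho^2)} nats.
#'
#' @param rho correlation coefficient, |rho| < 1.
#' @return Mutual information in nats.
#' @export
mi_gaussian <- function(rho) {
  if (any(abs(rho) >= 1)) stop("degenerate distribution: |rho| must be < 1")
  -0.5 * log(1 - rho^2)
}

#' Time-domain coupling and causality measures from model parameters
#'
#' @param full the full bivariate \code{\link{arx_model}}.
#' @param r1 restricted model of process 1 (see \code{\link{restrict_ss}},
#'   \code{\link{restrict_yw}}).
#' @param r2 restricted model of process 2.
#' @param clip_negative clip small negative finite-sample estimates to zero
#'   for reporting (raw values retained in the \code{raw} field).
#' @return An object of class \code{td_measures}: list with F measures
#'   (\code{F_td}, \code{F_gc_12}, \code{F_gc_21}, \code{F_ic}), their
#'   information-theoretic halves in nats (\code{I_mir}, \code{T_12},
#'   \code{T_21}, \code{I_it}) and \code{raw} (unclipped F values).
#' @export
time_domain_measures <- function(full, r1, r2, clip_negative = TRUE) {
  stopifnot(inherits(full, "arx_model"),
            inherits(r1, "restricted_model"), r1$target == 1L,
            inherits(r2, "restricted_model"), r2$target == 2L)
  S <- full$Sigma_U
  dS <- det(S)
  if (dS <= 0) stop("innovation covariance is not positive definite")
  l1 <- r1$lambda2
  l2 <- r2$lambda2
  F_gc_12 <- log(l2 / S[2, 2])
  F_gc_21 <- log(l1 / S[1, 1])
  F_ic <- log(S[1, 1] * S[2, 2] / dS)
  F_td <- F_gc_12 + F_gc_21 + F_ic  # = log(l1 l2 / |Sigma_U|) identically
  raw <- c(F_td = F_td, F_gc_12 = F_gc_12, F_gc_21 = F_gc_21, F_ic = F_ic)
  out <- raw
  if (clip_negative) {
    # finite-sample GC estimates can dip below zero; population values cannot
    out <- pmax(raw, 0)
    out["F_td"] <- out["F_gc_12"] + out["F_gc_21"] + out["F_ic"]
  }
  structure(list(F_td = unname(out["F_td"]),
                 F_gc_12 = unname(out["F_gc_12"]),
                 F_gc_21 = unname(out["F_gc_21"]),
                 F_ic = unname(out["F_ic"]),
                 I_mir = unname(out["F_td"]) / 2,
                 T_12 = unname(out["F_gc_12"]) / 2,
                 T_21 = unname(out["F_gc_21"]) / 2,
                 I_it = unname(out["F_ic"]) / 2,
                 raw = raw, units = "nats"),
            class = "td_measures")
}

#' @export
print.td_measures <- function(x, digits = 4, ...) {
  cat("Time-domain measures (F, dimensionless; I = F/2, nats):\n")
  cat(sprintf("  F_td = %.*f   F_gc 1->2 = %.*f   F_gc 2->1 = %.*f   F_ic = %.*f\n",
              digits, x$F_td, digits, x$F_gc_12, digits, x$F_gc_21,
              digits, x$F_ic))
  cat(sprintf("  MIR  = %.*f   TE   1->2 = %.*f   TE   2->1 = %.*f   IT   = %.*f\n",
              digits, x$I_mir, digits, x$T_12, digits, x$T_21, digits, x$I_it))
  invisible(x)
}

#' Linear parametric measures directly from data
#'
#' Convenience wrapper: identifies the full ARX model (order given or selected
#' by criterion), derives both restricted models, and returns the time-domain
#' measures.
#'
#' @param pair a zero-mean \code{\link{ts_pair}}.
#' @param p model order; if \code{NULL}, selected by \code{criterion} up to
#'   \code{p_max}.
#' @param p_max maximum scanned order when \code{p} is \code{NULL}.
#' @param criterion order-selection criterion, \code{"aic"} or \code{"bic"}.
#' @param method restricted-model route, \code{"ss"} (exact) or \code{"yw"}.
#' @param q truncation lag for the YW route.
#' @param clip_negative see \code{\link{time_domain_measures}}.
#' @return A \code{td_measures} object with attribute \code{"model"} holding
#'   the identified full model.
#' @export
linear_measures <- function(pair, p = NULL, p_max = 8L,
                            criterion = c("aic", "bic"),
                            method = c("ss", "yw"), q = NULL,
                            clip_negative = TRUE) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  if (is.null(p)) p <- select_order(pair, p_max, criterion)$order
  full <- identify_arx(pair, p)
  if (is.null(q)) q <- max(20L, 2L * p)
  restrict <- function(target) {
    if (method == "ss") restrict_ss(full, target) else
      restrict_yw(full, target, q)
  }
  out <- time_domain_measures(full, restrict(1L), restrict(2L),
                              clip_negative = clip_negative)
  attr(out, "model") <- full
  out
}
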