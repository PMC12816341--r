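# Bivariate ARX identification and restricted (univariate) model derivation.
#
# The full model is
#   Y_n = sum_{k=1..p} A_k Y_{n-k} + U_n,   cov(U_n) = Sigma_U (2x2, SPD),
# and the restricted model of one component regresses its present on its own
# past only.  Restricted parameters are never re-estimated from data: they are
# extracted from the full model either through a state-space submodel whose
# innovation variance solves a discrete algebraic Riccati equation, or through
# the Yule-Walker route via the model autocovariance sequence (discrete
# Lyapunov equation plus recursion).

#' Construct a bivariate ARX model
#'
#' @param A list of p coefficient matrices (2x2), lag 1 first; or a 2 x 2p
#'   matrix \code{[A_1, ..., A_p]}.
#' @param Sigma_U 2x2 symmetric positive definite innovation covariance.
#' @return An object of class \code{arx_model} with fields \code{p}, \code{A}
#'   (list of 2x2 matrices), \code{Sigma_U}, \code{stable} (spectral radius of
#'   the companion matrix below 1 - 1e-8).
#' @export
arx_model <- function(A, Sigma_U) {
  if (is.matrix(A)) {
    stopifnot(nrow(A) == 2L, ncol(A) %% 2L == 0L)
    A <- lapply(seq_len(ncol(A) / 2L), function(k) A[, (2 * k - 1):(2 * k)])
  }
  stopifnot(is.list(A), length(A) >= 1L)
  A <- lapply(A, function(a) {
    a <- as.matrix(a)
    stopifnot(all(dim(a) == c(2L, 2L)))
    a
  })
  Sigma_U <- as.matrix(Sigma_U)
  stopifnot(all(dim(Sigma_U) == c(2L, 2L)))
  if (max(abs(Sigma_U - t(Sigma_U))) > 1e-10)
    stop("Sigma_U must be symmetric")
  ev <- eigen(Sigma_U, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma_U must be positive definite")
  m <- structure(list(p = length(A), A = A, Sigma_U = Sigma_U),
                 class = "arx_model")
  m$stable <- spectral_radius(companion_matrix(m)) < 1 - 1e-8
  m
}

#' @export
print.arx_model <- function(x, ...) {
  cat(sprintf("arx_model: p = %d, %s\n", x$p,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Companion-form state matrix of an ARX model
#'
#' @param model an \code{\link{arx_model}}.
#' @return The 2p x 2p companion matrix \code{[A_1 ... A_p; I 0]}.
#' @export
companion_matrix <- function(model) {
  p <- model$p
  Atop <- do.call(cbind, model$A)
  if (p == 1L) return(Atop)
  rbind(Atop, cbind(diag(2 * (p - 1)), matrix(0, 2 * (p - 1), 2)))
}

spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

check_stable <- function(model) {
  if (!model$stable)
    stop("non-stationary: spectral radius >= 1")
  invisible(TRUE)
}

#' Identify a bivariate ARX model by ordinary least squares
#'
#' Regresses the present 2-vector on the stacked past of both series at lags
#' 1..p, solving the least-squares normal equations (via QR, with a
#' pseudo-inverse fallback for condition numbers above 1e10). The innovation
#' covariance is the residual covariance with denominator L - p.
#'
#' @param pair a zero-mean \code{\link{ts_pair}} (see \code{\link{preprocess}}).
#' @param p model order (lags).
#' @param n_obs number of regression rows to use, counted from the end of the
#'   series; defaults to \code{L - p} (all available). Used by
#'   \code{\link{select_order}} to hold the sample fixed across orders.
#' @return An \code{\link{arx_model}} with extra fields: \code{residuals}
#'   (matrix, one column per process), \code{se} (2 x 2p matrix of coefficient
#'   standard errors, same layout as \code{[A_1,...,A_p]}), \code{n_obs}.
#' @export
identify_arx <- function(pair, p, n_obs = NULL) {
  stopifnot(inherits(pair, "ts_pair"), p >= 1)
  L <- pair$L
  if (is.null(n_obs)) n_obs <- L - p
  if (n_obs > L - p) stop("n_obs larger than available rows")
  if (L - p <= 4 * p + 3)
    stop("series too short for order ", p, ": need L - p > 4p + 3")
  Y <- cbind(pair$y1, pair$y2)
  rows <- (L - n_obs + 1):L
  # regressor columns ordered [y1_{n-1}, y2_{n-1}, ..., y1_{n-p}, y2_{n-p}]
  X <- matrix(0, n_obs, 2 * p)
  for (k in seq_len(p)) {
    X[, 2 * k - 1] <- Y[rows - k, 1]
    X[, 2 * k]     <- Y[rows - k, 2]
  }
  Yp <- Y[rows, , drop = FALSE]
  XtX <- crossprod(X)
  kappa_x <- tryCatch(kappa(XtX, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa_x) || kappa_x > 1e10) {
    # pseudo-inverse fallback; a truly deficient design is rejected
    sv <- svd(X)
    tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
    r <- sum(sv$d > tol)
    if (r < ncol(X)) stop("singular design: collinear or constant regressors")
    Ahat <- t(sv$v %*% diag(1 / sv$d, r) %*% crossprod(sv$u, Yp))
  } else {
    Ahat <- t(qr.solve(X, Yp, tol = 1e-12))  # 2 x 2p
  }
  resid <- Yp - X %*% t(Ahat)
  Sigma_U <- crossprod(resid) / n_obs
  if (det(Sigma_U) <= 0) stop("singular design: degenerate residual covariance")
  model <- arx_model(Ahat, (Sigma_U + t(Sigma_U)) / 2)
  # SE of coefficients: cov(vec A) = Sigma_U (x) (X'X)^{-1}
  XtXinv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (!is.null(XtXinv)) {
    se_base <- sqrt(pmax(diag(XtXinv), 0))
    model$se <- rbind(se_base * sqrt(Sigma_U[1, 1]),
                      se_base * sqrt(Sigma_U[2, 2]))
  }
  model$residuals <- resid
  model$n_obs <- as.integer(n_obs)
  model
}

#' Select the ARX model order by information criterion
#'
#' Minimizes \code{N * log det(Sigma_U(p)) + penalty * 4p} over p = 1..p_max,
#' with penalty 2 (AIC) or log N (BIC). The regression sample is held fixed at
#' the last \code{N = L - p_max} rows for every candidate so that the
#' criteria are comparable across orders.
#'
#' @param pair a zero-mean \code{\link{ts_pair}}.
#' @param p_max maximum order scanned.
#' @param criterion \code{"aic"} or \code{"bic"}.
#' @return A list with \code{order} (selected p), \code{criterion},
#'   \code{curve} (criterion value for each candidate order).
#' @export
select_order <- function(pair, p_max, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  stopifnot(p_max >= 1)
  N <- pair$L - p_max
  vals <- vapply(seq_len(p_max), function(p) {
    m <- identify_arx(pair, p, n_obs = N)
    pen <- if (criterion == "aic") 2 else log(N)
    N * log(det(m$Sigma_U)) + pen * (4 * p)
  }, numeric(1))
  list(order = which.min(vals), criterion = criterion, curve = vals)
}

#' Autocovariance sequence of a stable ARX model
#'
#' Solves the discrete Lyapunov equation \code{Psi = A Psi A' + Xi} for the
#' covariance of the stacked state (yielding Gamma_0..Gamma_\{p-1\}), then
#' extends by the Yule-Walker recursion
#' \code{Gamma_k = sum_l A_l Gamma_\{k-l\}} for k >= p.
#'
#' @param model a stable \code{\link{arx_model}}.
#' @param q_max largest lag computed.
#' @return An object of class \code{acov_seq}: list with \code{q_max} and
#'   \code{Gamma}, a list of 2x2 matrices for lags 0..q_max, where
#'   \code{Gamma_k = E[Y_n Y_\{n-k\}']}.
#' @export
autocovariance_from_arx <- function(model, q_max) {
  check_stable(model)
  p <- model$p
  d <- 2 * p
  A_comp <- companion_matrix(model)
  Xi <- matrix(0, d, d)
  Xi[1:2, 1:2] <- model$Sigma_U
  # vec(Psi) = (I - A (x) A)^{-1} vec(Xi)
  Psi <- matrix(solve(diag(d * d) - kronecker(A_comp, A_comp), as.vector(Xi)),
                d, d)
  Psi <- (Psi + t(Psi)) / 2
  Gamma <- vector("list", q_max + 1L)
  for (k in 0:min(q_max, p - 1)) {
    # block row 1, block column k+1 of Psi holds Gamma_k
    Gamma[[k + 1L]] <- Psi[1:2, (2 * k + 1):(2 * k + 2)]
  }
  if (q_max >= p) {
    for (k in p:q_max) {
      G <- matrix(0, 2, 2)
      for (l in seq_len(p)) G <- G + model$A[[l]] %*% Gamma[[k - l + 1L]]
      Gamma[[k + 1L]] <- G
    }
  }
  structure(list(q_max = q_max, Gamma = Gamma), class = "acov_seq")
}

#' Restricted AR model via the Yule-Walker / Lyapunov route
#'
#' Builds the autocovariance sequence of the full model up to lag q, assembles
#' the q x q Toeplitz autocovariance of the target and its lag-1..q
#' cross-covariance with the present, and solves for the truncated restricted
#' coefficients and the residual variance
#' \code{lambda2 = sigma_Y^2 - c' C^\{-1\} c}.
#'
#' @param model a stable \code{\link{arx_model}}.
#' @param target which process (1 or 2) the restricted model describes.
#' @param q truncation lag of the (in general infinite-order) restricted
#'   model; default \code{max(20, 2p)}.
#' @return An object of class \code{restricted_model}: list with
#'   \code{target}, \code{q}, \code{b} (coefficients), \code{lambda2},
#'   \code{method = "yw"}.
#' @export
restrict_yw <- function(model, target = 2L, q = max(20L, 2L * model$p)) {
  check_stable(model)
  stopifnot(target %in% c(1L, 2L), q >= 1)
  acov <- autocovariance_from_arx(model, q)
  r <- vapply(0:q, function(k) acov$Gamma[[k + 1L]][target, target],
              numeric(1))
  C <- toeplitz(r[1:q])          # q x q autocovariance of the past
  cc <- r[2:(q + 1L)]            # cross-covariance present vs past
  kap <- kappa(C, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stop("ill-conditioned past covariance (condition number ",
         format(kap, digits = 3), ")")
  b <- solve(C, cc)
  lambda2 <- r[1] - sum(cc * b)
  if (lambda2 <= 0) stop("non-positive restricted variance (numerical)")
  structure(list(target = as.integer(target), q = as.integer(q), b = b,
                 lambda2 = lambda2, method = "yw"),
            class = "restricted_model")
}

# Fixed-point solution of the DARE associated with the innovations form of a
# restricted state-space model: iterate the Kalman-filter Riccati recursion
#   P <- A P A' + Q - (A P C' + S)(C P C' + R)^{-1}(A P C' + S)'
# until convergence (guaranteed for stable A with SPD noise).
solve_dare_filter <- function(A, C, Q, R, S, tol = 1e-13, max_iter = 20000L) {
  P <- Q
  for (i in seq_len(max_iter)) {
    APC <- A %*% P %*% t(C) + S
    Vt <- as.numeric(C %*% P %*% t(C)) + R
    Pn <- A %*% P %*% t(A) + Q - tcrossprod(APC) / Vt
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * max(1, max(abs(Pn)))) {
      K <- (A %*% Pn %*% t(C) + S) /
        (as.numeric(C %*% Pn %*% t(C)) + R)
      return(list(P = Pn, V = as.numeric(C %*% Pn %*% t(C)) + R, K = K,
                  iterations = i))
    }
    P <- Pn
  }
  stop("DARE iteration did not converge")
}

#' Restricted AR model via the state-space / Riccati route
#'
#' Casts the full ARX model in innovations state-space form (state = stacked
#' past, gain loading the current innovation), forms the submodel observing
#' only the target row, and solves the resulting discrete algebraic Riccati
#' equation for the restricted innovation variance. This route is exact: the
#' restricted process is a finite-order state-space process even though its AR
#' representation has infinite order.
#'
#' @inheritParams restrict_yw
#' @return A \code{restricted_model} with \code{lambda2}, \code{K} (restricted
#'   Kalman gain), \code{method = "ss"}. The \code{b} field is \code{NULL}:
#'   the SS route yields the innovation variance directly.
#' @export
restrict_ss <- function(model, target = 2L) {
  check_stable(model)
  stopifnot(target %in% c(1L, 2L))
  p <- model$p
  d <- 2 * p
  A_ss <- companion_matrix(model)
  K <- rbind(diag(2), matrix(0, d - 2, 2))   # d x 2
  V <- model$Sigma_U
  Cfull <- do.call(cbind, model$A)           # 2 x d
  Ct <- Cfull[target, , drop = FALSE]        # 1 x d
  Q <- K %*% V %*% t(K)
  R <- V[target, target]
  S <- K %*% V[, target, drop = FALSE]       # d x 1
  sol <- tryCatch(solve_dare_filter(A_ss, Ct, Q, R, S),
                  error = function(e)
                    stop("DARE failure for target ", target, ": ",
                         conditionMessage(e)))
  structure(list(target = as.integer(target), q = NA_integer_, b = NULL,
                 lambda2 = sol$V, K = sol$K, method = "ss"),
            class = "restricted_model")
}

#' @export
print.restricted_model <- function(x, ...) {
  cat(sprintf("restricted_model: target = %d, method = %s, lambda2 = %.6g\n",
              x$target, x$method, x$lambda2))
  invisible(x)
}
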