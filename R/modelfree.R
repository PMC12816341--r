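# Model-free estimation of transfer entropy (TE), instantaneous transfer (IT)
# and mutual information rate (MIR) via nearest-neighbour, binning and
# permutation entropy estimators, with uniform and non-uniform embedding.
#
# All estimators share the same vector configurations: present states y1_n,
# y2_n and past vectors Y1q, Y2q built from lags tau, 2 tau, ..., q tau.
# The decomposition MIR = TE(1->2) + TE(2->1) + IT holds exactly by
# construction for every estimator.

#' Uniform embedding of a time-series pair
#'
#' Builds aligned present-state columns and past-state matrices using q
#' equally spaced lags \code{tau, 2 tau, ..., q tau} for each process.
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param q memory length (number of past samples per process).
#' @param tau embedding delay in samples.
#' @return A list with \code{y1n}, \code{y2n} (length-N present vectors),
#'   \code{Y1q}, \code{Y2q} (N x q past matrices, lag tau first), \code{N}
#'   (= L - q tau usable samples), \code{q}, \code{tau}, \code{lags}.
#' @export
build_embedding_uniform <- function(pair, q, tau = 1L) {
  stopifnot(inherits(pair, "ts_pair"), q >= 1, tau >= 1)
  L <- pair$L
  span <- q * tau
  if (L <= span + 1)
    stop("series too short for embedding: need L > q * tau + 1 = ", span + 1)
  n_idx <- (span + 1):L
  N <- length(n_idx)
  past <- function(y) {
    out <- matrix(0, N, q)
    for (j in seq_len(q)) out[, j] <- y[n_idx - j * tau]
    out
  }
  list(y1n = pair$y1[n_idx], y2n = pair$y2[n_idx],
       Y1q = past(pair$y1), Y2q = past(pair$y2),
       N = N, q = as.integer(q), tau = as.integer(tau),
       lags = as.integer(seq_len(q) * tau))
}

mf_result <- function(T_12, T_21, I_it, estimator, hyperparams) {
  structure(list(T_12 = T_12, T_21 = T_21, I_it = I_it,
                 I_mir = T_12 + T_21 + I_it,
                 estimator = estimator, hyperparams = hyperparams,
                 units = "nats"),
            class = "mf_measures")
}

#' @export
print.mf_measures <- function(x, digits = 4, ...) {
  cat(sprintf("%s estimator (nats): MIR = %.*f, TE 1->2 = %.*f, TE 2->1 = %.*f, IT = %.*f\n",
              x$estimator, digits, x$I_mir, digits, x$T_12, digits, x$T_21,
              digits, x$I_it))
  invisible(x)
}

#' Nearest-neighbour entropy of a sample
#'
#' Kozachenko-Leonenko estimator under the maximum norm:
#' \code{H = psi(N) - psi(k) + d <log eps_n>}, where \code{eps_n} is twice
#' the distance from sample n to its k-th nearest neighbour.
#'
#' @param x numeric vector or matrix (one row per observation).
#' @param k number of neighbours.
#' @return Entropy in nats.
#' @export
knn_entropy <- function(x, k = 10L) {
  X <- as.matrix(x)
  N <- nrow(X)
  if (k >= N) stop("k must be smaller than the number of samples")
  eps <- 2 * .knn_kth_dist(X, as.integer(k))
  if (any(eps <= 0))
    stop("duplicate points: nearest-neighbour distance is zero ",
         "(consider jittering)")
  digamma(N) - digamma(k) + ncol(X) * mean(log(eps))
}

#' Nearest-neighbour (conditional) mutual information
#'
#' Shared-radius estimator of \code{I(X; Y | Z)} (Z optional): the k-th
#' neighbour distance is found in the full joint space and neighbour counts in
#' the projected subspaces are converted to digamma averages.
#'
#' @param x,y numeric vectors or matrices (rows = observations).
#' @param z optional conditioning vector/matrix.
#' @param k number of neighbours.
#' @return (Conditional) mutual information in nats.
#' @export
knn_cmi <- function(x, y, z = NULL, k = 10L) {
  X <- as.matrix(x)
  Y <- as.matrix(y)
  joint <- if (is.null(z)) cbind(X, Y) else cbind(X, Y, as.matrix(z))
  N <- nrow(joint)
  if (k >= N) stop("k must be smaller than the number of samples")
  r <- .knn_kth_dist(joint, as.integer(k))
  if (is.null(z)) {
    nx <- .knn_range_count(X, r)
    ny <- .knn_range_count(Y, r)
    digamma(k) + digamma(N) - mean(digamma(nx + 1) + digamma(ny + 1))
  } else {
    Z <- as.matrix(z)
    nz <- .knn_range_count(Z, r)
    nxz <- .knn_range_count(cbind(X, Z), r)
    nyz <- .knn_range_count(cbind(Y, Z), r)
    digamma(k) + mean(digamma(nz + 1) - digamma(nxz + 1) - digamma(nyz + 1))
  }
}

#' Nearest-neighbour estimates of TE, IT and MIR
#'
#' Shared-radius k-nearest-neighbour estimator: the k-th neighbour distance is
#' determined once in the full joint space \code{[y1_n, y2_n, Y1q, Y2q]} and
#' reused as the range-search radius in every projected subspace (strict
#' inequality, maximum norm), so the dimension-dependent bias terms cancel in
#' the entropy combinations.
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param q memory length; default 3.
#' @param tau embedding delay; default 1.
#' @param k number of neighbours; default 10.
#' @param jitter add a seeded uniform jitter of amplitude \code{1e-10 * sd} to
#'   each series before the search, to break massive ties in discrete-valued
#'   data. Off by default (continuous data).
#' @param jitter_seed seed for the jitter stream.
#' @return An \code{mf_measures} object (fields \code{T_12}, \code{T_21},
#'   \code{I_it}, \code{I_mir}, nats).
#' @export
knn_measures <- function(pair, q = 3L, tau = 1L, k = 10L,
                         jitter = FALSE, jitter_seed = 1L) {
  if (jitter) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(jitter_seed)
    pair$y1 <- pair$y1 + runif(pair$L, -1, 1) * 1e-10 * sd(pair$y1)
    pair$y2 <- pair$y2 + runif(pair$L, -1, 1) * 1e-10 * sd(pair$y2)
  }
  emb <- build_embedding_uniform(pair, q, tau)
  N <- emb$N
  if (k >= N) stop("k must be smaller than the number of embedded samples")
  joint <- cbind(emb$y1n, emb$y2n, emb$Y1q, emb$Y2q)
  r <- .knn_kth_dist(joint, as.integer(k))
  cnt <- function(M) .knn_range_count(M, r)
  n_1q2q   <- cnt(cbind(emb$Y1q, emb$Y2q))
  n_2n1q2q <- cnt(cbind(emb$y2n, emb$Y1q, emb$Y2q))
  n_1n1q2q <- cnt(cbind(emb$y1n, emb$Y1q, emb$Y2q))
  n_2n2q   <- cnt(cbind(emb$y2n, emb$Y2q))
  n_1n1q   <- cnt(cbind(emb$y1n, emb$Y1q))
  n_1q     <- cnt(emb$Y1q)
  n_2q     <- cnt(emb$Y2q)
  T_12 <- mean(digamma(n_2n1q2q + 1) - digamma(n_1q2q + 1) -
                 digamma(n_2n2q + 1) + digamma(n_2q + 1))
  T_21 <- mean(digamma(n_1n1q2q + 1) - digamma(n_1q2q + 1) -
                 digamma(n_1n1q + 1) + digamma(n_1q + 1))
  I_it <- digamma(k) + mean(digamma(n_1q2q + 1) - digamma(n_1n1q2q + 1) -
                              digamma(n_2n1q2q + 1))
  out <- mf_result(T_12, T_21, I_it, "knn",
                   list(k = k, q = q, tau = tau, jitter = jitter))
  if (!all(is.finite(unlist(out[c("T_12", "T_21", "I_it")]))))
    stop("non-finite nearest-neighbour estimate: check for duplicate points")
  out
}

# save/restore the RNG state so seeded internals do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Uniform quantization of a series
#'
#' Maps value v to bin i iff \code{w_min + (i-1) r <= v < w_min + i r} with
#' \code{r = (w_max - w_min)/b}; the maximum value is assigned to bin b.
#'
#' @param series numeric vector, non-constant.
#' @param b number of bins (>= 2).
#' @return Integer symbol sequence with alphabet \{1..b\}.
#' @export
quantize <- function(series, b) {
  stopifnot(b >= 2)
  lo <- min(series)
  hi <- max(series)
  if (hi == lo) stop("constant series: cannot quantize")
  r <- (hi - lo) / b
  sym <- pmin(floor((series - lo) / r) + 1L, b)
  as.integer(sym)
}

# Plug-in entropy (nats) of a discrete vector variable given as a matrix of
# symbol rows; 0 log 0 taken as 0.
discrete_entropy <- function(M) {
  M <- as.matrix(M)
  key <- do.call(paste, c(as.data.frame(M), sep = "\r"))
  p <- tabulate(match(key, unique(key))) / nrow(M)
  -sum(p * log(p))
}

#' Binning estimates of TE, IT and MIR
#'
#' Each series is uniformly quantized with b bins; entropies of the embedded
#' symbol vectors are estimated by plug-in frequencies and combined into
#' \code{TE(1->2) = H(y2n, Y2q) - H(Y2q) - H(y2n, Y1q, Y2q) + H(Y1q, Y2q)}
#' (and symmetrically), \code{IT} from the joint-past terms, and
#' \code{MIR = TE(1->2) + TE(2->1) + IT}.
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param q memory length; default 2.
#' @param tau embedding delay; default 1.
#' @param b number of quantization bins; default 3.
#' @param warn warn when the worst-case alphabet size \code{b^(2q+1)} exceeds
#'   the number of embedded samples (curse of dimensionality).
#' @return An \code{mf_measures} object.
#' @export
binning_measures <- function(pair, q = 2L, tau = 1L, b = 3L, warn = TRUE) {
  s1 <- quantize(pair$y1, b)
  s2 <- quantize(pair$y2, b)
  qp <- ts_pair(s1, s2, fs = pair$fs, labels = pair$labels,
                min_length = min(pair$L, 50L))
  emb <- build_embedding_uniform(qp, q, tau)
  if (warn && b^(2 * q + 1) > emb$N)
    warning("alphabet size b^(2q+1) = ", b^(2 * q + 1),
            " exceeds the number of embedded samples (", emb$N,
            "): estimates may be unreliable")
  H <- discrete_entropy
  H_1q2q <- H(cbind(emb$Y1q, emb$Y2q))
  H_2n1q2q <- H(cbind(emb$y2n, emb$Y1q, emb$Y2q))
  H_1n1q2q <- H(cbind(emb$y1n, emb$Y1q, emb$Y2q))
  H_full <- H(cbind(emb$y1n, emb$y2n, emb$Y1q, emb$Y2q))
  T_12 <- H(cbind(emb$y2n, emb$Y2q)) - H(emb$Y2q) - H_2n1q2q + H_1q2q
  T_21 <- H(cbind(emb$y1n, emb$Y1q)) - H(emb$Y1q) - H_1n1q2q + H_1q2q
  I_it <- H_1n1q2q + H_2n1q2q - H_1q2q - H_full
  mf_result(T_12, T_21, I_it, "binning",
            list(b = b, q = q, tau = tau))
}

#' Ordinal (rank) pattern of a window
#'
#' Assigns rank 1..d by ascending value; equal values are resolved by giving
#' the element appearing later in the window the smaller rank.
#'
#' @param window numeric vector of d values.
#' @return Integer vector of ranks (a permutation of 1..d).
#' @export
rank_pattern <- function(window) {
  d <- length(window)
  ord <- order(window, -seq_len(d))  # ties: later element ranks lower
  ranks <- integer(d)
  ranks[ord] <- seq_len(d)
  ranks
}

# rank patterns of each row of a matrix, as symbol rows
row_patterns <- function(M) {
  M <- as.matrix(M)
  matrix(apply(M, 1L, rank_pattern), ncol = ncol(M), byrow = TRUE)
}

#' Permutation (ordinal-pattern) estimates of TE, IT and MIR
#'
#' Same entropy-combination structure as \code{\link{binning_measures}}, with
#' each process block of a vector configuration replaced by its rank-ordering
#' pattern (alphabet q! for a past block, (q+1)! when the present state is
#' included).
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param q memory length; default 3 (the minimum advised for pattern
#'   variability).
#' @param tau embedding delay; default 1.
#' @return An \code{mf_measures} object.
#' @export
permutation_measures <- function(pair, q = 3L, tau = 1L) {
  stopifnot(q >= 1)
  emb <- build_embedding_uniform(pair, q, tau)
  pat_1q <- row_patterns(emb$Y1q)
  pat_2q <- row_patterns(emb$Y2q)
  pat_1n1q <- row_patterns(cbind(emb$y1n, emb$Y1q))
  pat_2n2q <- row_patterns(cbind(emb$y2n, emb$Y2q))
  H <- discrete_entropy
  H_1q2q <- H(cbind(pat_1q, pat_2q))
  H_2n1q2q <- H(cbind(pat_1q, pat_2n2q))
  H_1n1q2q <- H(cbind(pat_1n1q, pat_2q))
  H_full <- H(cbind(pat_1n1q, pat_2n2q))
  T_12 <- H(pat_2n2q) - H(pat_2q) - H_2n1q2q + H_1q2q
  T_21 <- H(pat_1n1q) - H(pat_1q) - H_1n1q2q + H_1q2q
  I_it <- H_1n1q2q + H_2n1q2q - H_1q2q - H_full
  mf_result(T_12, T_21, I_it, "perm", list(q = q, tau = tau))
}

#' Non-uniform embedding by greedy conditional-mutual-information selection
#'
#' Candidate terms are all (process, lag) pairs with lags 1..q_max*tau. At
#' each step the candidate maximizing the nearest-neighbour conditional MI
#' with the target's present state, given the already selected terms, is
#' retained only if its CMI exceeds the 100(1-alpha)-th percentile of CMIs
#' recomputed over random permutations of the target's present samples;
#' selection stops when no candidate passes.
#'
#' @param pair a \code{\link{ts_pair}}.
#' @param target target process (1 or 2).
#' @param q_max maximum memory length; candidate lags span 1..q_max*tau.
#' @param tau lag granularity multiplier for the candidate set.
#' @param n_shuffles permutations for the significance threshold.
#' @param alpha significance level of the percentile threshold.
#' @param k neighbours for the CMI estimator.
#' @param seed RNG seed for the shuffle stream.
#' @return A list of class \code{embedding_spec}: \code{candidates} (data
#'   frame with columns \code{process}, \code{lag}, \code{cmi}), \code{mode =
#'   "nonuniform"}, \code{target}, and the call parameters. Zero selected
#'   candidates is a valid result.
#' @export
select_embedding_nonuniform <- function(pair, target = 2L, q_max = 3L,
                                        tau = 1L, n_shuffles = 100L,
                                        alpha = 0.05, k = 10L, seed = 1L) {
  stopifnot(target %in% c(1L, 2L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  L <- pair$L
  span <- q_max * tau
  n_idx <- (span + 1):L
  tgt <- if (target == 1L) pair$y1 else pair$y2
  y_now <- tgt[n_idx]
  cand <- expand.grid(process = 1:2, lag = seq_len(span))
  cand_cols <- lapply(seq_len(nrow(cand)), function(i) {
    y <- if (cand$process[i] == 1L) pair$y1 else pair$y2
    y[n_idx - cand$lag[i]]
  })
  selected <- integer(0)
  sel_cmi <- numeric(0)
  Zsel <- NULL
  repeat {
    remaining <- setdiff(seq_len(nrow(cand)), selected)
    if (length(remaining) == 0L) break
    cmis <- vapply(remaining, function(i)
      knn_cmi(y_now, cand_cols[[i]], Zsel, k = k), numeric(1))
    best <- remaining[which.max(cmis)]
    best_cmi <- max(cmis)
    null_cmi <- vapply(seq_len(n_shuffles), function(s)
      knn_cmi(sample(y_now), cand_cols[[best]], Zsel, k = k), numeric(1))
    thr <- sort(null_cmi)[max(1L, ceiling((1 - alpha) * n_shuffles))]
    if (best_cmi <= thr) break
    selected <- c(selected, best)
    sel_cmi <- c(sel_cmi, best_cmi)
    Zsel <- do.call(cbind, cand_cols[selected])
  }
  structure(list(candidates = data.frame(process = cand$process[selected],
                                         lag = cand$lag[selected],
                                         cmi = sel_cmi),
                 mode = "nonuniform", target = as.integer(target),
                 q_max = q_max, tau = tau, n_shuffles = n_shuffles,
                 alpha = alpha, k = k, seed = seed),
            class = "embedding_spec")
}
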