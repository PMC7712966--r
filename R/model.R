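## Bernoulli mixture model of binary contact features.
##
## A frame i first picks a hidden conformational state z_i = k with
## probability pi_k, then forms every contact j independently with
## probability mu_kj.  The model parameters are theta = (K, pi, mu); the
## prior couples a symmetric Dirichlet on pi (concentration alpha = M + 1)
## with a uniqueness factor prod_{k<l} (1 - B(mu_k, mu_l)) built from the
## Bhattacharyya coefficient, which gives zero prior mass to duplicate
## categories.  Each mu_kj carries an independent flat Beta(1, 1) prior, so
## all conditionals and the collapsed marginal are conjugate and analytic.

as_x <- function(fm) {
  if (inherits(fm, "feature_matrix")) fm$x
  else if (is.matrix(fm)) fm
  else stop("expected a feature_matrix or a 0/1 matrix")
}

## a*log(b) with the 0*log(0) = 0 convention (a >= 0)
xlogy <- function(a, b) {
  out <- a * log(b)
  out[a == 0] <- 0
  out
}

#' Construct mixture model parameters
#'
#' @param pi mixture weights, length `K`, non-negative, summing to 1.
#' @param mu `K x M` matrix of per-category contact probabilities in
#'   `[0, 1]` (the category prototypes).
#' @param alpha Dirichlet concentration; the package default everywhere is
#'   `M + 1`, which keeps the cost of splitting a category asymptotically
#'   insensitive to the number of features.
#' @return an object of class `"model_params"` with fields `K`, `pi`, `mu`,
#'   `alpha`.
#' @export
model_params <- function(pi, mu, alpha = ncol(mu) + 1) {
  mu <- as.matrix(mu)
  K <- length(pi)
  if (nrow(mu) != K) stop("'mu' must have one row per mixture component")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-12)
    stop("'pi' must be a probability vector")
  if (any(mu < 0 | mu > 1)) stop("'mu' entries must lie in [0, 1]")
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be positive")
  structure(list(K = K, pi = as.numeric(pi), mu = mu, alpha = alpha),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> K = %d categories, M = %d features, alpha = %g\n",
              x$K, ncol(x$mu), x$alpha))
  invisible(x)
}

#' Sufficient statistics of a categorization
#'
#' `Nk` counts the frames assigned to each category and `Nkj` counts, per
#' category, how often each contact is formed among its frames.  Together
#' they determine the likelihood of any `(pi, mu)` given `(x, z)`.  Empty
#' categories are legal and yield zero rows.
#'
#' @param fm a [feature_matrix()] (or bare 0/1 matrix).
#' @param z integer vector of frame labels in `1..K`.
#' @param K number of categories.
#' @return list with `Nk` (length `K`) and `Nkj` (`K x M`).
#' @export
suff_stats <- function(fm, z, K) {
  x <- as_x(fm)
  z <- as.integer(z)
  if (length(z) != nrow(x)) stop("one label per frame required")
  if (any(z < 1L | z > K)) stop("labels out of range 1..K")
  Nk <- tabulate(z, nbins = K)
  Nkj <- matrix(0, K, ncol(x))
  rs <- rowsum(x + 0, z)             # numeric accumulation, grouped by label
  Nkj[as.integer(rownames(rs)), ] <- rs
  list(Nk = Nk, Nkj = Nkj)
}

#' Log joint likelihood of data and assignment given parameters
#'
#' The complete-data log likelihood
#' `sum_k [ Nk log pi_k + sum_j ( Nkj log mu_kj + (Nk - Nkj) log(1 - mu_kj) ) ]`.
#' Boundary prototype entries (`mu` of 0 or 1) are admissible: a zero
#' probability with zero count contributes nothing, while a zero-probability
#' event with positive count gives `-Inf`.
#'
#' @inheritParams suff_stats
#' @param theta a [model_params()].
#' @return a single number (possibly `-Inf`).
#' @export
log_joint <- function(fm, z, theta) {
  ss <- suff_stats(fm, z, theta$K)
  sum(xlogy(ss$Nk, theta$pi)) +
    sum(xlogy(ss$Nkj, theta$mu)) +
    sum(xlogy(ss$Nk - ss$Nkj, 1 - theta$mu))
}

## N x K matrix of per-category log "membership scores"
## log pi_k + sum_j [ x_ij log mu_kj + (1-x_ij) log(1-mu_kj) ]
log_resp_matrix <- function(x, theta, use_pi = TRUE) {
  mu <- theta$mu
  if (all(mu > 0 & mu < 1)) {          # hot path: single BLAS product
    lr <- tcrossprod(x, log(mu) - log1p(-mu))
    lr <- sweep(lr, 2L, rowSums(log1p(-mu)), "+")
  } else {                             # boundary-safe path
    K <- theta$K
    lr <- matrix(0, nrow(x), K)
    for (k in seq_len(K)) {
      l1 <- log(mu[k, ]); l0 <- log1p(-mu[k, ])
      lr[, k] <- x %*% ifelse(is.finite(l1), l1, 0) +
        (1 - x) %*% ifelse(is.finite(l0), l0, 0)
      bad1 <- which(mu[k, ] == 0); bad0 <- which(mu[k, ] == 1)
      if (length(bad1))
        lr[rowSums(x[, bad1, drop = FALSE]) > 0, k] <- -Inf
      if (length(bad0))
        lr[rowSums(1 - x[, bad0, drop = FALSE]) > 0, k] <- -Inf
    }
  }
  if (use_pi) sweep(lr, 2L, log(theta$pi), "+") else lr
}

#' Posterior category membership probabilities
#'
#' For each frame, the normalized posterior probability of each category
#' given the current parameters,
#' `P(z_i = k | x_i, theta) \propto pi_k prod_j mu_kj^x_ij (1-mu_kj)^(1-x_ij)`,
#' computed in log space.  The mixture weight `pi_k` is included by default;
#' `use_pi = FALSE` drops it for comparison with uniform-weight
#' classification.
#'
#' @param xi a single bit vector of length `M`, an `N x M` bit matrix, or a
#'   [feature_matrix()].
#' @param theta a [model_params()].
#' @param use_pi include the mixture-weight factor (default `TRUE`).
#' @return a probability vector of length `K` (vector input) or an `N x K`
#'   matrix with rows summing to 1.
#' @export
responsibilities <- function(xi, theta, use_pi = TRUE) {
  single <- is.null(dim(xi)) && !inherits(xi, "feature_matrix")
  x <- if (single) matrix(as.numeric(xi), nrow = 1L) else as_x(xi) + 0
  lr <- log_resp_matrix(x, theta, use_pi = use_pi)
  mx <- apply(lr, 1L, max)
  if (any(!is.finite(mx)))
    stop("datum impossible under every category (all responsibilities zero)")
  p <- exp(lr - mx)
  p <- p / rowSums(p)
  if (single) drop(p) else p
}

#' Bhattacharyya similarity between two category prototypes
#'
#' `B(p, q) = prod_j [ sqrt(p_j q_j) + sqrt((1-p_j)(1-q_j)) ]`, the
#' Bhattacharyya coefficient between the two product-Bernoulli distributions
#' defined by `p` and `q`.  It equals 1 exactly when `p = q` and 0 when the
#' distributions have disjoint support; `1 - B` is the uniqueness penalty
#' applied to every category pair in the prior.
#'
#' @param p,q probability vectors of equal length with entries in `[0, 1]`.
#' @return a number in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  if (length(p) != length(q)) stop("'p' and 'q' must have equal length")
  if (any(p < 0 | p > 1 | q < 0 | q > 1)) stop("entries must lie in [0, 1]")
  prod(sqrt(p * q) + sqrt((1 - p) * (1 - q)))
}

## sum_{k<l} log(1 - B_kl); -Inf when two prototypes coincide
log_uniqueness <- function(mu) {
  K <- nrow(mu)
  if (K < 2L) return(0)
  sm <- sqrt(mu); cm <- sqrt(1 - mu)
  tot <- 0
  for (k in seq_len(K - 1L)) for (l in (k + 1L):K) {
    b <- prod(sm[k, ] * sm[l, ] + cm[k, ] * cm[l, ])
    tot <- tot + log1p(-min(b, 1))
  }
  tot
}

#' Log prior density of the model parameters
#'
#' `log P(theta | U) + sum_{k<l} log(1 - B(mu_k, mu_l))`, where `P(theta|U)`
#' is the symmetric `Dirichlet(alpha)` density on `pi` (the flat Beta priors
#' on `mu` contribute a constant 0).  Returns `-Inf` when two categories
#' share a prototype, or when some `pi_k = 0` with `alpha > 1`.
#'
#' @param theta a [model_params()].
#' @return a single number (possibly `-Inf`).
#' @export
log_prior <- function(theta) {
  a <- theta$alpha
  lp <- lgamma(theta$K * a) - theta$K * lgamma(a) +
    sum(xlogy(rep(a - 1, theta$K), theta$pi))
  lp + log_uniqueness(theta$mu)
}

#' Draw parameters from their conjugate conditional given an assignment
#'
#' Samples `theta` from `P(theta | z, x, U)`: `pi` from
#' `Dirichlet(N_1 + alpha, ..., N_K + alpha)` and each `mu_kj` independently
#' from `Beta(N_kj + 1, N_k - N_kj + 1)`.  This is the proposal used by the
#' reclassification move; the uniqueness factor is applied by that move's
#' acceptance step, not here.
#'
#' @inheritParams suff_stats
#' @param alpha Dirichlet concentration; default `M + 1`.
#' @return a [model_params()].
#' @export
sample_theta_given_z <- function(fm, z, K, alpha = ncol(as_x(fm)) + 1) {
  x <- as_x(fm)
  ss <- suff_stats(x, z, K)
  g <- stats::rgamma(K, shape = ss$Nk + alpha)
  pi <- g / sum(g)
  M <- ncol(x)
  mu <- matrix(stats::rbeta(K * M, ss$Nkj + 1, ss$Nk - ss$Nkj + 1), K, M)
  ## guard against numerically degenerate draws at the boundary
  mu[mu < 1e-300] <- 1e-300
  mu[mu > 1 - 1e-16] <- 1 - 1e-16
  model_params(pi, mu, alpha)
}

#' Collapsed log marginal likelihood of an assignment
#'
#' `log P(x, z | K, U)` with `pi` integrated against its Dirichlet prior and
#' every `mu_kj` against its flat Beta prior:
#' `lgamma(K a) - lgamma(N + K a) + sum_k [lgamma(N_k + a) - lgamma(a)]
#'  + sum_{k,j} log Beta(N_kj + 1, N_k - N_kj + 1)`.
#' This is the quantity whose ratios drive split/join acceptance.
#'
#' @inheritParams suff_stats
#' @param alpha Dirichlet concentration; default `M + 1`.
#' @return a single number.
#' @export
log_marginal <- function(fm, z, K, alpha = ncol(as_x(fm)) + 1) {
  x <- as_x(fm)
  ss <- suff_stats(x, z, K)
  N <- nrow(x)
  lgamma(K * alpha) - lgamma(N + K * alpha) +
    sum(lgamma(ss$Nk + alpha)) - K * lgamma(alpha) +
    sum(lbeta(ss$Nkj + 1, ss$Nk - ss$Nkj + 1))
}

## --- fast integer-count internals used by the sampler --------------------

## lf[n + 1] = log(n!)
logfact_table <- function(nmax) lgamma(seq_len(nmax + 1))

## per-category contribution to log_marginal, from one row of counts;
## log Beta(Nkj+1, Nk-Nkj+1) = lf[Nkj] + lf[Nk-Nkj] - lf[Nk+1]
cat_marg_term <- function(Nk, Nkj, alpha, lf) {
  lgamma(Nk + alpha) - lgamma(alpha) +
    sum(lf[Nkj + 1]) + sum(lf[Nk - Nkj + 1]) - length(Nkj) * lf[Nk + 2]
}

#' Export category prototypes to CSV
#'
#' Writes the `K x M` matrix of contact probabilities with one row per
#' category and one column per contact, labelled `u:v` with 0-based point
#' indices (matching the pair-label sidecar convention), for inspection in
#' external tools.
#'
#' @param theta a [model_params()].
#' @param fm the [feature_matrix()] the model was fitted to (supplies pair
#'   labels); may be `NULL`, in which case columns are labelled `f1..fM`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_prototypes <- function(theta, fm = NULL, path) {
  mu <- theta$mu
  cols <- if (!is.null(fm))
    sprintf("%d:%d", fm$pairs[, 1] - 1L, fm$pairs[, 2] - 1L)
  else sprintf("f%d", seq_len(ncol(mu)))
  df <- as.data.frame(mu)
  names(df) <- cols
  df <- cbind(category = seq_len(nrow(mu)), pi = theta$pi, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
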