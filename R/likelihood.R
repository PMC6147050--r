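#' Linear predictors of the multinomial logit
#'
#' \eqn{\eta_k = \alpha_k + \sum_p x_p \beta_{p,k} + \sum_{levels} u_{level,k}}
#' for the five non-reference categories; the reference category contributes
#' \eqn{\eta = 0} implicitly.
#'
#' @param x covariate vector (length P, in [fixed_terms()] order), or NULL
#'   for an intercept-only model.
#' @param alpha length-5 intercepts.
#' @param beta P x 5 coefficient matrix (or NULL).
#' @param unit_effects optional list of length-5 random-effect vectors, one
#'   per active level.
#' @return named length-5 vector of linear predictors.
#' @export
linear_predictors <- function(x = NULL, alpha, beta = NULL,
                              unit_effects = NULL) {
  K1 <- length(nonreference_categories())
  stopifnot(length(alpha) == K1)
  eta <- as.numeric(alpha)
  if (!is.null(beta) && length(beta) > 0) {
    beta <- as.matrix(beta)
    if (is.null(x) || length(x) != nrow(beta))
      stop("covariate vector length ", length(x),
           " does not match coefficient rows ", nrow(beta))
    eta <- eta + as.numeric(crossprod(beta, x))
  } else if (!is.null(x) && length(x) > 0) {
    stop("covariates supplied but no coefficients")
  }
  for (u in unit_effects) {
    stopifnot(length(u) == K1)
    eta <- eta + as.numeric(u)
  }
  stats::setNames(eta, nonreference_categories())
}

#' Category probabilities from linear predictors
#'
#' Multinomial-logit inverse link with the reference category's predictor
#' fixed at zero, computed stably via log-sum-exp:
#' \eqn{p_{ref} = 1/(1+\sum_k e^{\eta_k})}, \eqn{p_k = e^{\eta_k} p_{ref}}.
#'
#' @param eta length-5 vector, or an n x 5 matrix of linear predictors for
#'   the non-reference categories.
#' @return named length-6 probability vector (or n x 6 matrix), columns in
#'   [behaviour_categories()] order.
#' @export
category_probabilities <- function(eta) {
  vec <- is.null(dim(eta))
  eta <- rbind(eta)
  stopifnot(ncol(eta) == length(nonreference_categories()))
  full <- cbind(eta, 0)  # reference last while computing
  m <- apply(full, 1, max)
  ex <- exp(full - m)
  p <- ex / rowSums(ex)
  colnames(p) <- c(nonreference_categories(), reference_category())
  p <- p[, behaviour_categories(), drop = FALSE]
  if (vec) p[1, ] else p
}

#' Noncentred random-effect transform
#'
#' Maps standard-normal innovations to correlated random effects:
#' \eqn{u = \mathrm{diag}(\sigma) L \zeta}, where L is the Cholesky factor of
#' the correlation matrix. This is the parameterization the sampler works in.
#'
#' @param z length-5 vector or 5 x n matrix of standard normals (one column
#'   per unit).
#' @param sigma length-5 SD vector.
#' @param L 5 x 5 lower-triangular correlation Cholesky factor with positive
#'   diagonal.
#' @return effects with the same shape as `z`.
#' @export
noncentred_effects <- function(z, sigma, L) {
  L <- as.matrix(L)
  K1 <- length(sigma)
  stopifnot(nrow(L) == K1, ncol(L) == K1)
  if (any(abs(L[upper.tri(L)]) > 1e-12))
    stop("L must be lower triangular")
  if (any(diag(L) <= 0)) stop("L must have a positive diagonal")
  vec <- is.null(dim(z))
  z <- if (vec) matrix(z, ncol = 1) else as.matrix(z)
  stopifnot(nrow(z) == K1)
  u <- diag(sigma, K1) %*% L %*% z
  if (vec) u[, 1] else u
}

#' Pointwise log-likelihood of observed behaviours
#'
#' Log probability of each event's observed category given its linear
#' predictors; the reference implementation used in tests and WAIC.
#'
#' @param behaviour character vector of observed categories (length n).
#' @param eta n x 5 matrix of non-reference linear predictors.
#' @return numeric vector of per-event log-likelihood values (all <= 0).
#' @export
log_likelihood <- function(behaviour, eta) {
  eta <- rbind(eta)
  stopifnot(length(behaviour) == nrow(eta),
            all(behaviour %in% behaviour_categories()))
  full <- cbind(eta, 0)
  colnames(full) <- c(nonreference_categories(), reference_category())
  lse <- apply(full, 1, log_sum_exp)
  full[cbind(seq_len(nrow(full)), match(behaviour, colnames(full)))] - lse
}

# Canonical-partial-correlation transform: unconstrained y (length
# K(K-1)/2, row-wise lower triangle) -> correlation Cholesky factor.
# R mirror of the sampler's internal transform.
cpc_to_chol <- function(y, K = length(nonreference_categories())) {
  stopifnot(length(y) == K * (K - 1) / 2)
  L <- matrix(0, K, K)
  L[1, 1] <- 1
  idx <- 1
  for (i in 2:K) {
    s <- 0
    for (j in 1:(i - 1)) {
      L[i, j] <- tanh(y[idx]) * sqrt(1 - s)
      s <- s + L[i, j]^2
      idx <- idx + 1
    }
    L[i, i] <- sqrt(1 - s)
  }
  L
}
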