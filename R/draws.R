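#' Extract posterior draws from a fitted model
#'
#' The fit stores draws on the sampler's unconstrained scale; these
#' extractors reconstruct the model-scale quantities. All of them stack the
#' chains, so the draw dimension has `chains * (iter - warmup)` rows.
#'
#' @param fit an [mmbm_fit()] result.
#' @return `alpha_draws()`: draws x 5 matrix of intercepts, columns named by
#'   category.
#' @export
alpha_draws <- function(fit) {
  d <- draws_matrix(fit)
  out <- d[, fit$param_map$alpha$offset + seq_len(fit$param_map$alpha$length),
           drop = FALSE]
  colnames(out) <- nonreference_categories()
  out
}

#' @rdname alpha_draws
#' @return `beta_draws()`: draws x P x 5 array of fixed-effect coefficients,
#'   dimensions named by term and category.
#' @export
beta_draws <- function(fit) {
  pm <- fit$param_map
  if (is.null(pm$beta)) stop("model ", fit$spec$variant, " has no fixed effects")
  d <- draws_matrix(fit)
  terms <- fit$spec$fixed_terms
  P <- length(terms)
  out <- array(d[, pm$beta$offset + seq_len(pm$beta$length)],
               dim = c(nrow(d), P, length(nonreference_categories())),
               dimnames = list(NULL, terms, nonreference_categories()))
  out
}

#' @rdname alpha_draws
#' @param level random-effect level name (`"individual"`, `"scan"`,
#'   `"litter"`, `"group"`).
#' @return `sigma_draws()`: draws x 5 matrix of random-effect SDs.
#' @export
sigma_draws <- function(fit, level = "individual") {
  l <- level_block(fit, level)
  d <- draws_matrix(fit)
  out <- exp(d[, l$log_sigma$offset + seq_len(l$log_sigma$length),
               drop = FALSE])
  colnames(out) <- nonreference_categories()
  out
}

#' @rdname alpha_draws
#' @return `correlation_draws()`: draws x 5 x 5 array of random-effect
#'   correlation matrices (unit diagonal, positive semi-definite by
#'   construction).
#' @export
correlation_draws <- function(fit, level = "individual") {
  l <- level_block(fit, level)
  if (is.null(l$y))
    stop("level '", level, "' was fitted with a diagonal (uncorrelated) ",
         "structure; no correlations to extract")
  d <- draws_matrix(fit)
  K1 <- length(nonreference_categories())
  y <- d[, l$y$offset + seq_len(l$y$length), drop = FALSE]
  out <- array(NA_real_, dim = c(nrow(d), K1, K1),
               dimnames = list(NULL, nonreference_categories(),
                               nonreference_categories()))
  for (s in seq_len(nrow(d))) {
    L <- cpc_to_chol(y[s, ], K1)
    out[s, , ] <- L %*% t(L)
  }
  out
}

#' @rdname alpha_draws
#' @return `unit_effect_draws()`: draws x units x 5 array of per-unit random
#'   effects \eqn{u = \mathrm{diag}(\sigma) L \zeta}.
#' @export
unit_effect_draws <- function(fit, level = "individual") {
  l <- level_block(fit, level)
  units <- fit$data$levels[[level]]$units
  d <- draws_matrix(fit)
  K1 <- length(nonreference_categories())
  n_units <- length(units)
  sig <- exp(d[, l$log_sigma$offset + seq_len(K1), drop = FALSE])
  out <- array(NA_real_, dim = c(nrow(d), n_units, K1),
               dimnames = list(NULL, units, nonreference_categories()))
  for (s in seq_len(nrow(d))) {
    Z <- matrix(d[s, l$z$offset + seq_len(l$z$length)], K1, n_units)
    L <- if (!is.null(l$y)) cpc_to_chol(d[s, l$y$offset + seq_len(l$y$length)],
                                        K1) else diag(K1)
    out[s, , ] <- t(diag(sig[s, ], K1) %*% L %*% Z)
  }
  out
}

#' @rdname alpha_draws
#' @return `draws_matrix()`: the raw draws x dim unconstrained matrix with
#'   chains stacked.
#' @export
draws_matrix <- function(fit) do.call(rbind, fit$draws)

level_block <- function(fit, level) {
  l <- fit$param_map$levels[[level]]
  if (is.null(l))
    stop("level '", level, "' is not part of model variant ",
         fit$spec$variant)
  l
}

# linear predictors (cells x 5) for one posterior draw; random effects
# included unless fixed_only
draw_eta <- function(fit, d, s, fixed_only = FALSE) {
  pm <- fit$param_map
  K1 <- length(nonreference_categories())
  alpha <- d[s, pm$alpha$offset + seq_len(K1)]
  n <- nrow(fit$data$counts)
  Eta <- matrix(alpha, n, K1, byrow = TRUE)
  if (!is.null(pm$beta)) {
    B <- matrix(d[s, pm$beta$offset + seq_len(pm$beta$length)],
                ncol(fit$data$X), K1)
    Eta <- Eta + fit$data$X %*% B
  }
  if (!fixed_only) {
    for (nm in names(pm$levels)) {
      l <- pm$levels[[nm]]
      lev <- fit$data$levels[[nm]]
      sig <- exp(d[s, l$log_sigma$offset + seq_len(K1)])
      Z <- matrix(d[s, l$z$offset + seq_len(l$z$length)], K1)
      L <- if (!is.null(l$y))
        cpc_to_chol(d[s, l$y$offset + seq_len(l$y$length)], K1) else diag(K1)
      U <- t(diag(sig, K1) %*% L %*% Z)   # units x 5
      Eta <- Eta + U[lev$uidx + 1L, , drop = FALSE]
    }
  }
  Eta
}

#' Pointwise log-likelihood over the posterior
#'
#' Per-draw log-likelihood of each sampling event. Events sharing an
#' (individual, scan) cell and a category have identical contributions, so
#' the matrix is returned in compressed form: one column per (cell, category)
#' combination actually observed, with the event multiplicities in the
#' `"weights"` attribute. Expanding by the weights gives the draws x events
#' matrix.
#'
#' @param fit an [mmbm_fit()].
#' @return draws x M matrix with attribute `weights` (length M counts).
#' @export
pointwise_loglik <- function(fit) {
  d <- draws_matrix(fit)
  counts <- fit$data$counts
  K <- ncol(counts)
  keep <- which(as.vector(counts) > 0)
  weights <- as.vector(counts)[keep]
  out <- matrix(NA_real_, nrow(d), length(keep))
  n <- nrow(counts)
  for (s in seq_len(nrow(d))) {
    Eta <- draw_eta(fit, d, s)
    full <- cbind(Eta, 0)
    m <- pmax(apply(Eta, 1, max), 0)
    lse <- m + log(rowSums(exp(full - m)))
    lp <- full - lse    # cells x K log-probabilities
    out[s, ] <- as.vector(lp)[keep]
  }
  attr(out, "weights") <- weights
  out
}
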