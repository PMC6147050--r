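#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x)))
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. With seed = NULL the global stream
# is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split-half potential scale reduction factor
#'
#' Computes split-\eqn{\hat R} from a matrix of post-warmup draws with one
#' column per chain: each chain is split in half and the usual
#' between/within-variance ratio is taken over the resulting 2m sequences.
#'
#' @param x numeric matrix, iterations x chains
#' @return scalar \eqn{\hat R}
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  pieces <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1L):n, j])
  }))
  m <- ncol(pieces)
  nn <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= .Machine$double.eps) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Weighted mean and (frequency-weighted, n-1 style) variance, used by WAIC
# standard errors where one aggregated cell stands for `w` identical events.
weighted_var <- function(x, w) {
  n <- sum(w)
  mu <- sum(w * x) / n
  sum(w * (x - mu)^2) / (n - 1)
}
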