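#' Widely applicable information criterion
#'
#' \eqn{WAIC = -2(lppd - p_{WAIC})} with
#' \eqn{lppd = \sum_i \log(\frac{1}{S}\sum_s e^{\ell_{s,i}})} (computed via
#' log-sum-exp) and \eqn{p_{WAIC} = \sum_i \mathrm{Var}_s(\ell_{s,i})}. The
#' standard error comes from the dispersion of the pointwise WAIC
#' contributions.
#'
#' @param x a draws x observations matrix of pointwise log-likelihood values,
#'   or an [mmbm_fit()] (whose compressed pointwise log-likelihood is used).
#' @param weights optional observation multiplicities (for compressed
#'   pointwise matrices); defaults to the matrix's `"weights"` attribute or
#'   all ones.
#' @param ... unused.
#' @return object of class `mmbm_waic` with `lppd`, `p_waic`, `waic`, `se`
#'   and a `pointwise` tibble.
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.default <- function(x, weights = NULL, ...) {
  ll <- as.matrix(x)
  if (nrow(ll) < 2) stop("WAIC needs at least 2 draws (variance undefined)")
  weights <- weights %||% attr(x, "weights") %||% rep(1, ncol(ll))
  stopifnot(length(weights) == ncol(ll), all(weights > 0))
  S <- nrow(ll)
  lppd_i <- apply(ll, 2, log_sum_exp) - log(S)
  p_i <- apply(ll, 2, stats::var)
  waic_i <- -2 * (lppd_i - p_i)
  n <- sum(weights)
  se <- sqrt(n * weighted_var(waic_i, weights))
  structure(list(
    lppd = sum(weights * lppd_i),
    p_waic = sum(weights * p_i),
    waic = -2 * (sum(weights * lppd_i) - sum(weights * p_i)),
    se = se,
    pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i, waic = waic_i,
                               weight = weights)
  ), class = "mmbm_waic")
}

#' @rdname waic
#' @export
waic.mmbm_fit <- function(x, ...) waic.default(pointwise_loglik(x))

#' @export
print.mmbm_waic <- function(x, ...) {
  cat("WAIC: ", round(x$waic, 1), " (SE ", round(x$se, 1), ")  lppd: ",
      round(x$lppd, 1), "  p_waic: ", round(x$p_waic, 1), "\n", sep = "")
  invisible(x)
}

#' Compare models by WAIC
#'
#' @param ... named `mmbm_waic` or `mmbm_fit` objects.
#' @return tibble sorted by ascending WAIC with differences to the best
#'   model.
#' @export
compare_waic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], c("mmbm_waic", "mmbm_fit")))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  ws <- lapply(fits, function(f) if (inherits(f, "mmbm_fit")) waic(f) else f)
  out <- tibble::tibble(
    model = names(ws),
    waic = vapply(ws, `[[`, 0, "waic"),
    se = vapply(ws, `[[`, 0, "se"),
    p_waic = vapply(ws, `[[`, 0, "p_waic"),
    lppd = vapply(ws, `[[`, 0, "lppd"))
  out <- out[order(out$waic), ]
  out$delta_waic <- out$waic - out$waic[1]
  out
}
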