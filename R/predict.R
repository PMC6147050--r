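#' Fixed-effects predicted-probability curves
#'
#' Category probabilities along a grid of one focal covariate, computed per
#' posterior draw from the fixed effects only (random effects excluded), with
#' all other continuous covariates held at their sample mean (0 on the
#' z-scale) and pup presence at its reference level (no pups). Returns the
#' posterior-mean curve and an equal-tailed 89% percentile band per
#' category, with the grid reported on the original covariate scale.
#'
#' @param fit an [mmbm_fit()] of a variant with fixed effects (M2/M3).
#' @param focal `"age"`, `"group_size"` or `"relative_mass"`.
#' @param grid_length number of evenly spaced grid points across the
#'   observed covariate range (default 50).
#' @param band percentile-band mass (default 0.89).
#' @return tibble with columns `focal`, value (original scale), `z` (model
#'   scale), `category`, `mean`, `lo`, `hi`. Attribute `"draws"` holds the
#'   grid x category x draw probability array.
#' @export
predicted_probabilities <- function(fit, focal = c("age", "group_size",
                                                   "relative_mass"),
                                    grid_length = 50, band = 0.89) {
  focal <- match.arg(focal)
  if (is.null(fit$param_map$beta))
    stop("model ", fit$spec$variant, " has no fixed effects")
  sc <- fit$scaling[[focal]]
  rg <- fit$covariate_range[[focal]]
  grid <- seq(rg[1], rg[2], length.out = grid_length)
  gz <- (grid - sc[["mean"]]) / sc[["sd"]]
  X <- grid_design(fit$spec$fixed_terms, focal, gz)

  al <- alpha_draws(fit)
  be <- beta_draws(fit)
  S <- nrow(al)
  cats <- behaviour_categories()
  arr <- array(NA_real_, dim = c(grid_length, length(cats), S),
               dimnames = list(NULL, cats, NULL))
  for (s in seq_len(S)) {
    Eta <- sweep(X %*% be[s, , ], 2, al[s, ], `+`)
    arr[, , s] <- category_probabilities(Eta)
  }
  a <- (1 - band) / 2
  rows <- lapply(cats, function(k) {
    p <- arr[, k, , drop = TRUE]
    tibble::tibble(focal = focal, value = grid, z = gz, category = k,
                   mean = rowMeans(p),
                   lo = apply(p, 1, stats::quantile, a),
                   hi = apply(p, 1, stats::quantile, 1 - a))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "draws") <- arr
  out
}

# design matrix for a focal-covariate grid: polynomial terms follow the
# focal z value, everything else sits at 0 (sample mean / no pups)
grid_design <- function(terms, focal, gz) {
  X <- matrix(0, length(gz), length(terms), dimnames = list(NULL, terms))
  if (focal == "age") {
    X[, "age_z"] <- gz; X[, "age_z2"] <- gz^2; X[, "age_z3"] <- gz^3
  } else if (focal == "group_size") {
    X[, "groupsize_z"] <- gz; X[, "groupsize_z2"] <- gz^2
  } else {
    X[, "relative_mass_z"] <- gz
  }
  X
}

#' Posterior contrast for a categorical fixed effect
#'
#' For a binary fixed effect (pup presence), computes per posterior draw the
#' difference in each category's fixed-effects predicted probability between
#' the two factor levels, holding continuous covariates at their mean.
#' Significance is judged from the draw-wise contrast distribution (95%
#' equal-tailed interval excluding zero), not from overlapping prediction
#' intervals.
#'
#' @param fit an [mmbm_fit()] with fixed effects.
#' @param factor name of the binary covariate (default `"pups_present"`).
#' @param prob interval mass (default 0.95).
#' @return tibble with one row per category: `mean`, `lo`, `hi`,
#'   `significant`. Attribute `"draws"` holds the draws x category contrast
#'   matrix.
#' @export
categorical_contrast <- function(fit, factor = "pups_present", prob = 0.95) {
  if (is.null(fit$param_map$beta))
    stop("model ", fit$spec$variant, " has no fixed effects")
  terms <- fit$spec$fixed_terms
  if (!factor %in% terms)
    stop("'", factor, "' is not a fixed effect of this model")
  al <- alpha_draws(fit)
  be <- beta_draws(fit)
  x0 <- stats::setNames(rep(0, length(terms)), terms)
  x1 <- x0; x1[factor] <- 1
  S <- nrow(al)
  cats <- behaviour_categories()
  ct <- matrix(NA_real_, S, length(cats), dimnames = list(NULL, cats))
  for (s in seq_len(S)) {
    p1 <- category_probabilities(drop(x1 %*% be[s, , ]) + al[s, ])
    p0 <- category_probabilities(drop(x0 %*% be[s, , ]) + al[s, ])
    ct[s, ] <- p1 - p0
  }
  a <- (1 - prob) / 2
  out <- tibble::tibble(
    category = cats,
    mean = colMeans(ct),
    lo = apply(ct, 2, stats::quantile, a),
    hi = apply(ct, 2, stats::quantile, 1 - a))
  out$significant <- out$lo > 0 | out$hi < 0
  attr(out, "draws") <- ct
  out
}
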