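#' Prior configuration
#'
#' Weakly informative defaults on the unconstrained model scale: Normal(0, 5)
#' intercepts, Normal(0, 2) slopes (covariates are z-scored, so these are
#' wide), Exponential(1) random-effect SDs and LKJ(2) correlation matrices.
#' All are configurable and recorded in the fit's metadata.
#'
#' @param beta_scale SD of the Normal prior on fixed-effect slopes.
#' @param intercept_scale SD of the Normal prior on intercepts.
#' @param sd_rate rate of the Exponential prior on random-effect SDs.
#' @param lkj_eta shape of the LKJ prior on correlation matrices (>= 1).
#' @return list of class `prior_config`.
#' @export
prior_config <- function(beta_scale = 2, intercept_scale = 5, sd_rate = 1,
                         lkj_eta = 2) {
  stopifnot(beta_scale > 0, intercept_scale > 0, sd_rate > 0, lkj_eta >= 1)
  structure(list(beta_scale = beta_scale, intercept_scale = intercept_scale,
                 sd_rate = sd_rate, lkj_eta = lkj_eta),
            class = "prior_config")
}

#' Specify a multilevel multinomial behaviour model
#'
#' Three nested variants are supported, always fitted per sex:
#' * **M1** -- intercepts plus correlated random effects at the individual
#'   level only. Its individual-level correlations are the raw
#'   within-individual behavioural correlations across development.
#' * **M2** -- M1 plus the fixed covariates (age polynomial to 3rd order,
#'   group-size polynomial to 2nd order, pup presence, relative mass).
#' * **M3** -- M2 plus further random effects at the scan, litter and group
#'   level, controlling for temporal pseudoreplication and clustering.
#'
#' Resting is the reference category: its linear predictor is fixed at zero
#' and no correlations involving it are estimated.
#'
#' @param variant `"M1"`, `"M2"` or `"M3"`.
#' @param sex `"F"` or `"M"`; sexes are always modelled separately.
#' @param priors a [prior_config()].
#' @param chains,iter,warmup MCMC settings (defaults 3 chains of 1000
#'   iterations, half warmup).
#' @param adapt_delta target acceptance statistic for step-size adaptation.
#' @param max_depth maximum trajectory doubling depth.
#' @param scan_grain grain of the scan-level random effect in M3:
#'   `"individual_scan"` (one effect per individual x scan, the default) or
#'   `"group_scan"` (shared by all individuals observed in a group's scan).
#' @param diagonal_levels random-effect levels whose correlation matrix is
#'   collapsed to diagonal (uncorrelated) for speed; only scan, litter and
#'   group may be collapsed, the individual level is always correlated.
#' @param reference reference category label (default `"rest"`).
#' @param seed integer seed for the sampler.
#' @return list of class `mmbm_spec`.
#' @export
mmbm_spec <- function(variant = c("M1", "M2", "M3"), sex = c("F", "M"),
                      priors = prior_config(), chains = 3, iter = 1000,
                      warmup = floor(iter / 2), adapt_delta = 0.9,
                      max_depth = 10, scan_grain = c("individual_scan",
                                                     "group_scan"),
                      diagonal_levels = character(0),
                      reference = reference_category(), seed = 1L) {
  variant <- match.arg(variant)
  sex <- match.arg(sex)
  scan_grain <- match.arg(scan_grain)
  stopifnot(inherits(priors, "prior_config"), chains >= 1, iter > warmup,
            warmup >= 0)
  if ("individual" %in% diagonal_levels)
    stop("the individual level is always estimated with correlations")
  re_levels <- if (variant == "M3")
    c("individual", "scan", "litter", "group") else "individual"
  bad <- setdiff(diagonal_levels, re_levels)
  if (length(bad) > 0)
    stop("diagonal_levels not in this variant's random effects: ",
         paste(bad, collapse = ", "))
  structure(list(variant = variant, sex = sex,
                 reference_category = reference,
                 fixed_terms = fixed_terms(variant), re_levels = re_levels,
                 priors = priors, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 adapt_delta = adapt_delta, max_depth = as.integer(max_depth),
                 scan_grain = scan_grain, diagonal_levels = diagonal_levels,
                 seed = as.integer(seed)),
            class = "mmbm_spec")
}
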