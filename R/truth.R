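#' Ground-truth configuration for the synthetic-data generator
#'
#' Bundles every generating parameter of the synthetic study: design counts
#' (groups, individuals per sex, scans, events per scan), the generating
#' multinomial model (intercepts, fixed-effect matrix, random-effect SDs and
#' correlation matrices per level), the log-log mass model, and the scenario
#' label. Defaults emulate the captive mole-rat study design: 35 groups, 60
#' nonreproductive females and 56 males, 10 scan sessions per individual and
#' 180 sampling events per 12 h scan (4 min intervals), with first-scan ages
#' near 136 days and ~64-day spacing between scans.
#'
#' Category order for all 5-vectors/matrix columns is
#' [nonreference_categories()]; covariate row order of `fixed_betas` is
#' [fixed_terms()] ("M2").
#'
#' @param scenario one of `"no_specialization"`, `"temporal_caste"`,
#'   `"permanent_caste"`, `"null"`; fills scenario-specific defaults via
#'   [scenario_preset()]. Explicit arguments override the preset.
#' @param n_groups,n_females,n_males,n_scans_per_individual,events_per_scan
#'   design counts.
#' @param intercepts length-5 intercepts of the non-reference categories
#'   (reference = rest has linear predictor 0).
#' @param fixed_betas 7 x 5 matrix of fixed-effect coefficients (z-scale).
#' @param re_sd named list of length-5 SD vectors for levels `individual`,
#'   `scan`, `litter`, `group`.
#' @param re_corr named list of 5 x 5 correlation matrices per level.
#' @param mass_params list `a`, `b`, `sigma_group`, `sigma_resid` of the
#'   log-log mass model (log grams / log days).
#' @param age_first_scan_mean,age_first_scan_sd mean/SD (days) of age at the
#'   first scan.
#' @param scan_interval_mean,scan_interval_sd spacing between scan sessions
#'   (days).
#' @param pup_interval_mean mean interval (days) between pup litters born in a
#'   group, driving the pups_present covariate.
#' @param scan_grain `"individual_scan"` (default: one scan-level effect per
#'   individual x scan) or `"group_scan"` (shared within a group's scan).
#' @param seed integer seed for full determinism.
#' @return list of class `truth_config` (validated).
#' @export
truth_config <- function(scenario = c("no_specialization", "temporal_caste",
                                      "permanent_caste", "null"),
                         n_groups = 35, n_females = 60, n_males = 56,
                         n_scans_per_individual = 10, events_per_scan = 180,
                         intercepts = NULL, fixed_betas = NULL,
                         re_sd = NULL, re_corr = NULL,
                         mass_params = list(a = 1.6, b = 0.5,
                                            sigma_group = 0.1,
                                            sigma_resid = 0.05),
                         age_first_scan_mean = 136, age_first_scan_sd = 15,
                         scan_interval_mean = 64.4, scan_interval_sd = 5,
                         pup_interval_mean = 133,
                         scan_grain = c("individual_scan", "group_scan"),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  scan_grain <- match.arg(scan_grain)
  preset <- scenario_preset(scenario)
  K1 <- length(nonreference_categories())

  intercepts <- intercepts %||% preset$intercepts
  fixed_betas <- fixed_betas %||% preset$fixed_betas
  re_sd <- re_sd %||% list(individual = rep(0.5, K1), scan = rep(0.3, K1),
                           litter = rep(0.2, K1), group = rep(0.2, K1))
  base_corr <- list(individual = preset$re_corr_individual,
                    scan = diag(K1), litter = diag(K1), group = diag(K1))
  re_corr <- utils::modifyList(base_corr, re_corr %||% list())

  cfg <- list(scenario = scenario, n_groups = n_groups, n_females = n_females,
              n_males = n_males,
              n_scans_per_individual = n_scans_per_individual,
              events_per_scan = events_per_scan, intercepts = intercepts,
              fixed_betas = fixed_betas, re_sd = re_sd, re_corr = re_corr,
              mass_params = mass_params,
              age_first_scan_mean = age_first_scan_mean,
              age_first_scan_sd = age_first_scan_sd,
              scan_interval_mean = scan_interval_mean,
              scan_interval_sd = scan_interval_sd,
              pup_interval_mean = pup_interval_mean,
              scan_grain = scan_grain, seed = as.integer(seed))
  validate_truth_config(cfg)
  class(cfg) <- "truth_config"
  cfg
}

validate_truth_config <- function(cfg) {
  K1 <- length(nonreference_categories())
  stopifnot(cfg$n_groups >= 1, cfg$n_females + cfg$n_males >= 1,
            cfg$n_scans_per_individual >= 1, cfg$events_per_scan >= 1,
            length(cfg$intercepts) == K1,
            is.matrix(cfg$fixed_betas),
            nrow(cfg$fixed_betas) == length(fixed_terms("M2")),
            ncol(cfg$fixed_betas) == K1)
  for (lev in c("individual", "scan", "litter", "group")) {
    sd <- cfg$re_sd[[lev]]
    if (length(sd) != K1 || any(sd < 0))
      stop("re_sd$", lev, " must be ", K1, " nonnegative values")
    R <- cfg$re_corr[[lev]]
    if (!isSymmetric(unname(R), tol = 1e-8) ||
        any(abs(diag(R) - 1) > 1e-8))
      stop("re_corr$", lev, " must be symmetric with unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("re_corr$", lev, " is not positive semi-definite (min eigenvalue ",
           signif(min(ev), 3), ")")
  }
  invisible(cfg)
}

#' Scenario presets for the generator
#'
#' Encodes the qualitative typology of individual variation in cooperative
#' behaviour as generating truths:
#' * `no_specialization` -- generalist helpers: positive pairwise
#'   individual-level correlations among all nonresting behaviours, and a
#'   shared hump-shaped age trajectory of helping (rising through ontogeny,
#'   declining after). This is the pattern the mole-rat analysis found.
#' * `temporal_caste` -- honeybee-style age polyethism: cooperative
#'   behaviours have crossing age trajectories (one rises while another
#'   falls) with near-zero random-effect correlations.
#' * `permanent_caste` -- insect-caste-style specialization: strong negative
#'   individual-level correlations between cooperative behaviours
#'   (work vs food carrying at -0.8).
#' * `null` -- no fixed effects, independent random effects; used for
#'   calibrating the credible-interval significance rule.
#'
#' @param name scenario name.
#' @return list with elements `intercepts`, `fixed_betas`,
#'   `re_corr_individual`.
#' @export
scenario_preset <- function(name) {
  cats <- nonreference_categories()
  coop <- cooperative_categories()
  K1 <- length(cats)
  terms <- fixed_terms("M2")
  beta0 <- matrix(0, length(terms), K1, dimnames = list(terms, cats))
  # time-budget-like intercepts: rest commonest, helping behaviours rarer
  alpha0 <- stats::setNames(c(-0.7, -1.3, -2.2, -2.5, -0.9), cats)
  corr0 <- diag(K1)
  dimnames(corr0) <- list(cats, cats)

  hump <- function(B, cols, b1 = 0.8, b2 = -0.6, b3 = 0) {
    B["age_z", cols] <- b1; B["age_z2", cols] <- b2; B["age_z3", cols] <- b3
    B
  }

  switch(name,
    no_specialization = {
      R <- matrix(0.4, K1, K1, dimnames = dimnames(corr0)); diag(R) <- 1
      B <- hump(beta0, coop)
      B <- hump(B, setdiff(cats, coop), b1 = 0.3, b2 = -0.2)
      list(intercepts = alpha0, fixed_betas = B, re_corr_individual = R)
    },
    temporal_caste = {
      B <- beta0
      B["age_z", "work"] <- 1.0          # late-life workers
      B["age_z", "nest_building"] <- -1.0 # young nest builders
      B <- hump(B, "food_carry")          # mid-life carriers
      list(intercepts = alpha0, fixed_betas = B, re_corr_individual = corr0)
    },
    permanent_caste = {
      R <- corr0
      R["food_carry", "work"] <- R["work", "food_carry"] <- -0.8
      R["nest_building", "work"] <- R["work", "nest_building"] <- -0.2
      R["nest_building", "food_carry"] <-
        R["food_carry", "nest_building"] <- -0.2
      list(intercepts = alpha0, fixed_betas = beta0, re_corr_individual = R)
    },
    null = list(intercepts = stats::setNames(rep(0, K1), cats),
                fixed_betas = beta0, re_corr_individual = corr0),
    stop("unknown scenario '", name, "'; valid scenarios: ",
         "no_specialization, temporal_caste, permanent_caste, null")
  )
}
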