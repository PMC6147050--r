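#' Fit the sex-specific relative-mass model
#'
#' "Relative mass" expresses how heavy an animal is for its sex, age and
#' group. It is defined as the residual from a sex-specific linear mixed model
#' of log mass on log age with a random intercept for group identity:
#' \deqn{\log(mass) = a + b\,\log(age) + u_{group} + \varepsilon.}
#' Residuals are conditional on the group effect, so a positive value means
#' heavier than expected for same-sex, same-age animals of the same group.
#'
#' @param masses mass records (individual_id, date, mass_g).
#' @param individuals individual table (individual_id, sex, birth_date,
#'   group_id).
#' @param sex `"F"` or `"M"`; only this sex's records are used.
#' @param method `"REML"` (default) or `"ML"` variance estimation.
#' @return object of class `relative_mass_fit` with elements `sex`,
#'   `intercept`, `slope`, `group_effects` (named, conditional modes),
#'   `sigma_group`, `sigma_resid`, `method`.
#' @export
fit_relative_mass <- function(masses, individuals, sex = c("F", "M"),
                              method = c("REML", "ML")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  ind <- individuals[individuals$sex == sex,
                     c("individual_id", "birth_date", "group_id")]
  d <- dplyr::inner_join(masses, ind, by = "individual_id")
  d$age <- as.numeric(d$date - d$birth_date)
  if (any(d$age <= 0)) stop("mass records at non-positive age for sex ", sex)
  if (nrow(d) < 3) stop("need at least 3 mass records for sex ", sex)
  d$log_mass <- log(d$mass_g)
  d$log_age <- log(d$age)

  n_groups <- length(unique(d$group_id))
  if (n_groups < 2) {
    warning("single group for sex ", sex,
            "; falling back to ordinary least squares (sigma_group = 0)")
    ols <- stats::lm(log_mass ~ log_age, data = d)
    fit <- list(sex = sex,
                intercept = unname(stats::coef(ols)[1]),
                slope = unname(stats::coef(ols)[2]),
                group_effects = stats::setNames(rep(0, n_groups),
                                                unique(d$group_id)),
                sigma_group = 0,
                sigma_resid = stats::sigma(ols),
                method = "OLS")
    class(fit) <- "relative_mass_fit"
    return(fit)
  }

  lmm <- lme4::lmer(log_mass ~ log_age + (1 | group_id), data = d,
                    REML = (method == "REML"))
  fe <- lme4::fixef(lmm)
  re <- lme4::ranef(lmm)$group_id
  vc <- as.data.frame(lme4::VarCorr(lmm))
  fit <- list(
    sex = sex,
    intercept = unname(fe[["(Intercept)"]]),
    slope = unname(fe[["log_age"]]),
    group_effects = stats::setNames(re[["(Intercept)"]], rownames(re)),
    sigma_group = vc$sdcor[vc$grp == "group_id"],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    method = method
  )
  class(fit) <- "relative_mass_fit"
  fit
}

#' Relative mass of an animal
#'
#' Conditional residual of `log(mass)` under a [fit_relative_mass()] fit.
#'
#' @param fit a `relative_mass_fit`.
#' @param group_id group identity (vectorized); groups unseen at fit time get
#'   a group effect of 0, with a warning.
#' @param mass body mass in grams, > 0.
#' @param age age in days, > 0.
#' @return numeric residuals on the log-gram scale.
#' @export
relative_mass <- function(fit, group_id, mass, age) {
  stopifnot(inherits(fit, "relative_mass_fit"))
  if (any(mass <= 0) || any(age <= 0)) stop("mass and age must be positive")
  ge <- fit$group_effects[as.character(group_id)]
  unseen <- is.na(ge)
  if (any(unseen)) {
    warning("group(s) not seen at fit time, using group effect 0: ",
            paste(unique(group_id[unseen]), collapse = ", "))
    ge[unseen] <- 0
  }
  log(mass) - (fit$intercept + fit$slope * log(age) + unname(ge))
}

#' @export
print.relative_mass_fit <- function(x, ...) {
  cat("Relative-mass fit (", x$method, "), sex ", x$sex, "\n",
      "  log(mass) = ", signif(x$intercept, 4), " + ", signif(x$slope, 4),
      " * log(age)\n",
      "  sigma_group = ", signif(x$sigma_group, 4),
      ", sigma_resid = ", signif(x$sigma_resid, 4),
      ", groups = ", length(x$group_effects), "\n", sep = "")
  invisible(x)
}

#' Serialize a relative-mass fit to JSON
#' @param fit a `relative_mass_fit`.
#' @param path output file.
#' @export
write_relative_mass_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
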