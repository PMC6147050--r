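#' Build the model covariate table for one sex
#'
#' Constructs, for every (individual, scan) pair in the analysis dataset, the
#' covariates entering Models 2 and 3: age polynomials (1st-3rd order),
#' group-size polynomials (1st-2nd order), pup presence, and relative mass.
#' Continuous covariates are z-scored within the sex-specific dataset
#' (sample-SD, n-1) *before* taking powers, so `age_z2 = age_z^2` etc.; the
#' powers themselves are not re-standardized, keeping the linear term
#' interpretable.
#'
#' Relative mass uses the mass record nearest in time to the scan (ties
#' resolved to the earlier record) and the [relative_mass()] residual at the
#' age on that record's date.
#'
#' @param individuals individual table (one sex is selected via `sex`).
#' @param scans scan-session table with `group_size` and `pups_present`.
#' @param masses mass records.
#' @param rm_fit a [fit_relative_mass()] fit for the same sex.
#' @param sex `"F"` or `"M"`.
#' @param participation optional tibble (individual_id, scan_id) restricting
#'   which pairs enter the dataset; by default every scan of the individual's
#'   group is used.
#' @return tibble with identifiers, raw covariates (`age_days`, `group_size`,
#'   `relative_mass`) and model columns (`age_z`, `age_z2`, `age_z3`,
#'   `groupsize_z`, `groupsize_z2`, `pups_present`, `relative_mass_z`).
#'   Attribute `scaling` records the centring/scaling constants used, for
#'   mapping prediction grids back to the original scale.
#' @export
build_covariates <- function(individuals, scans, masses, rm_fit,
                             sex = c("F", "M"), participation = NULL) {
  sex <- match.arg(sex)
  ind <- individuals[individuals$sex == sex & !individuals$is_breeder, ]
  if (nrow(ind) == 0) stop("no nonbreeding individuals of sex ", sex)

  if (is.null(participation)) {
    participation <- dplyr::inner_join(
      ind[, c("individual_id", "group_id")],
      scans[, c("scan_id", "group_id")], by = "group_id",
      relationship = "many-to-many")
    participation <- participation[, c("individual_id", "scan_id")]
  }
  d <- dplyr::inner_join(participation, ind, by = "individual_id")
  d <- dplyr::inner_join(d, scans, by = "scan_id",
                         suffix = c("", ".scan"))
  d$age_days <- as.numeric(d$date - d$birth_date)
  if (any(d$age_days < 0)) stop("negative age at scan; check birth dates")

  no_mass <- setdiff(unique(d$individual_id), unique(masses$individual_id))
  if (length(no_mass) > 0)
    stop("no mass records for individual(s): ", paste(no_mass, collapse = ", "))

  # nearest mass record per (individual, scan); equidistant -> earlier record
  mass_by_ind <- split(masses, masses$individual_id)
  picked <- lapply(seq_len(nrow(d)), function(i) {
    m <- mass_by_ind[[d$individual_id[i]]]
    dt <- abs(as.numeric(m$date - d$date[i]))
    j <- which(dt == min(dt))
    if (length(j) > 1) j <- j[which.min(m$date[j])]
    m[j, ]
  })
  picked <- dplyr::bind_rows(picked)
  mass_age <- as.numeric(picked$date - d$birth_date)
  d$relative_mass <- relative_mass(rm_fit, d$group_id, picked$mass_g, mass_age)

  zscore <- function(x, what) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < .Machine$double.eps)
      stop("cannot z-score '", what, "': zero variance in the dataset")
    list(z = (x - mean(x)) / s, mean = mean(x), sd = s)
  }
  za <- zscore(d$age_days, "age")
  zg <- zscore(d$group_size, "group_size")
  zm <- zscore(d$relative_mass, "relative_mass")

  out <- tibble::tibble(
    individual_id = d$individual_id,
    scan_id = d$scan_id,
    group_id = d$group_id,
    litter_id = d$litter_id,
    age_days = d$age_days,
    group_size = d$group_size,
    relative_mass = d$relative_mass,
    age_z = za$z, age_z2 = za$z^2, age_z3 = za$z^3,
    groupsize_z = zg$z, groupsize_z2 = zg$z^2,
    pups_present = as.integer(d$pups_present),
    relative_mass_z = zm$z
  )
  attr(out, "scaling") <- list(
    age = c(mean = za$mean, sd = za$sd),
    group_size = c(mean = zg$mean, sd = zg$sd),
    relative_mass = c(mean = zm$mean, sd = zm$sd)
  )
  attr(out, "sex") <- sex
  out
}

#' Fixed-effect terms of the model variants
#'
#' Model 1 has intercepts only; Models 2 and 3 share the covariate set, in
#' this fixed order.
#' @param variant `"M1"`, `"M2"` or `"M3"`.
#' @return character vector of covariate column names (empty for M1).
#' @export
fixed_terms <- function(variant = c("M2", "M3", "M1")) {
  variant <- match.arg(variant)
  if (variant == "M1") return(character(0))
  c("age_z", "age_z2", "age_z3", "groupsize_z", "groupsize_z2",
    "pups_present", "relative_mass_z")
}
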