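#' Generate a synthetic study population
#'
#' Simulates the observational design: groups, nonbreeding individuals of
#' both sexes allocated to groups (unequal group sizes), litters nested in
#' groups (litter mates share a birth date), 12 h scan sessions per group at
#' roughly the configured spacing, pup litters driving the pups_present flag,
#' and body-mass series from the log-log growth model
#' \eqn{\log m = a + b \log(age) + u_{group} + \varepsilon} at two-week
#' weighing intervals. Birth dates are placed so that ages at a group's first
#' scan centre on `age_first_scan_mean` (136 days by default, giving
#' last-scan ages near 716 days under the default spacing).
#'
#' @param config a [truth_config()].
#' @return list with tibbles `individuals`, `groups`, `scans`, `masses`, plus
#'   `pup_births` and the mass-model group effects used.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  n_ind <- cfg$n_females + cfg$n_males
  group_ids <- sprintf("g%02d", seq_len(cfg$n_groups))

  # unequal allocation of nonbreeders to groups; every group keeps >= 1
  w <- stats::rgamma(cfg$n_groups, shape = 2)
  counts <- as.vector(stats::rmultinom(1, n_ind, w / sum(w)))
  while (any(counts == 0) && n_ind >= cfg$n_groups) {
    i <- which(counts == 0)[1]; j <- which.max(counts)
    counts[i] <- counts[i] + 1L; counts[j] <- counts[j] - 1L
  }
  sex <- sample(c(rep("F", cfg$n_females), rep("M", cfg$n_males)))
  ind_group <- sample(rep(group_ids, counts))

  # scan sessions per group (shared by all group members)
  scans <- lapply(group_ids, function(g) {
    start <- as.Date("2014-01-01") + sample.int(365, 1)
    gaps <- pmax(14, stats::rnorm(cfg$n_scans_per_individual - 1,
                                  cfg$scan_interval_mean,
                                  cfg$scan_interval_sd))
    dates <- start + round(c(0, cumsum(gaps)))
    tibble::tibble(
      scan_id = sprintf("%s_s%02d", g, seq_along(dates)),
      group_id = g, date = dates)
  })
  scans <- dplyr::bind_rows(scans)

  # litters within groups; litter mates share a birth date chosen so that
  # age at the group's first scan centres on the configured mean
  individuals <- vector("list", cfg$n_groups)
  for (gi in seq_along(group_ids)) {
    g <- group_ids[gi]
    members <- which(ind_group == g)
    if (length(members) == 0) next
    first_scan <- min(scans$date[scans$group_id == g])
    sizes <- c()
    while (sum(sizes) < length(members))
      sizes <- c(sizes, sample(1:4, 1))
    litter_of <- rep(seq_along(sizes), sizes)[seq_along(members)]
    birth_by_litter <- first_scan -
      round(pmax(50, stats::rnorm(max(litter_of), cfg$age_first_scan_mean,
                                  cfg$age_first_scan_sd)))
    individuals[[gi]] <- tibble::tibble(
      individual_id = sprintf("%s_i%03d", g, seq_along(members)),
      sex = sex[members],
      birth_date = birth_by_litter[litter_of],
      group_id = g,
      litter_id = sprintf("%s_L%02d", g, litter_of),
      is_breeder = FALSE)
  }
  individuals <- dplyr::bind_rows(individuals)

  # pup litters (not part of the analysis dataset) set the pups_present flag
  pup_births <- lapply(group_ids, function(g) {
    gs <- scans$date[scans$group_id == g]
    span <- as.numeric(max(gs) - min(gs)) + 80
    t <- cumsum(stats::rexp(ceiling(span / cfg$pup_interval_mean) + 3,
                            1 / cfg$pup_interval_mean))
    tibble::tibble(group_id = g, birth_date = min(gs) - 40 + round(t[t <= span]))
  })
  pup_births <- dplyr::bind_rows(pup_births)

  scans$pups_present <- vapply(seq_len(nrow(scans)), function(i) {
    b <- pup_births$birth_date[pup_births$group_id == scans$group_id[i]]
    any(b <= scans$date[i] & b > scans$date[i] - 40)
  }, logical(1))

  # group size: nonbreeders plus the breeding pair
  nb <- table(individuals$group_id)
  scans$group_size <- as.integer(nb[scans$group_id]) + 2L
  scans <- scans[, c("scan_id", "group_id", "date", "group_size",
                     "pups_present")]

  # body-mass series from the log-log growth model
  mp <- cfg$mass_params
  g_eff <- stats::setNames(stats::rnorm(cfg$n_groups, 0, mp$sigma_group),
                           group_ids)
  masses <- lapply(seq_len(nrow(individuals)), function(i) {
    last_scan <- max(scans$date[scans$group_id == individuals$group_id[i]])
    dates <- seq(individuals$birth_date[i] + 56, last_scan + 14, by = 14)
    age <- as.numeric(dates - individuals$birth_date[i])
    lm_mu <- mp$a + mp$b * log(age) + g_eff[[individuals$group_id[i]]]
    tibble::tibble(individual_id = individuals$individual_id[i], date = dates,
                   mass_g = exp(lm_mu + stats::rnorm(length(age), 0,
                                                     mp$sigma_resid)))
  })
  masses <- dplyr::bind_rows(masses)

  groups <- tibble::tibble(group_id = group_ids,
                           n_nonbreeders = as.integer(nb[group_ids]),
                           group_size = as.integer(nb[group_ids]) + 2L)

  list(individuals = individuals, groups = groups, scans = scans,
       masses = masses, pup_births = pup_births, mass_group_effects = g_eff)
}

# draw correlated random effects: one row per unit, cov = diag(sd) R diag(sd)
draw_unit_effects <- function(units, sd, R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite")
  Z <- matrix(stats::rnorm(length(units) * length(sd)), length(units))
  U <- Z %*% chol(R + diag(1e-10, nrow(R)))
  U <- sweep(U, 2, sd, `*`)
  rownames(U) <- units
  U
}

#' Generate sampling events from a known generating model
#'
#' Draws behaviour for every sampling event of every (individual, scan) pair
#' from the categorical distribution with probabilities
#' \eqn{\mathrm{softmax}(\eta)}, where
#' \eqn{\eta_k = \alpha_k + x'\beta_k + u_{ind,k} + v_{scan,k} + w_{litter,k}
#' + z_{group,k}} and the reference (rest) has \eqn{\eta = 0}. Random effects
#' are drawn once per unit from multivariate normals with the configured SDs
#' and correlation matrices. Covariates are built through the package's own
#' pipeline (sex-specific relative-mass fit, within-sex z-scoring), so the
#' generating coefficients live on the same scale the fitted models see.
#' Events are conditionally independent given the random effects.
#'
#' @param population a [generate_population()] result.
#' @param truth the [truth_config()].
#' @param seed seed for the event draw (default derived from the config).
#' @return list with `events` (one row per sampling event), `covariates`
#'   (per-sex tibbles from [build_covariates()]), `rm_fits`, and
#'   `random_effects` (the drawn per-unit effect matrices).
#' @export
generate_events <- function(population, truth, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "truth_config"))
  with_seed(seed, generate_events_impl(population, truth))
}

generate_events_impl <- function(pop, truth) {
  cats <- nonreference_categories()
  K1 <- length(cats)
  ind <- pop$individuals

  scan_units <- if (truth$scan_grain == "group_scan") {
    pop$scans$scan_id
  } else NULL  # individual_scan units are formed per sex below

  u_ind <- draw_unit_effects(ind$individual_id, truth$re_sd$individual,
                             truth$re_corr$individual)
  u_litter <- draw_unit_effects(unique(ind$litter_id), truth$re_sd$litter,
                                truth$re_corr$litter)
  u_group <- draw_unit_effects(pop$groups$group_id, truth$re_sd$group,
                               truth$re_corr$group)
  u_scan_shared <- if (!is.null(scan_units))
    draw_unit_effects(scan_units, truth$re_sd$scan, truth$re_corr$scan)

  out_events <- list(); out_cov <- list(); rm_fits <- list()
  u_scan_all <- list()
  for (sx in c("F", "M")) {
    if (!any(ind$sex == sx)) next
    rm_fit <- fit_relative_mass(pop$masses, ind, sx)
    cov <- build_covariates(ind, pop$scans, pop$masses, rm_fit, sx)
    rm_fits[[sx]] <- rm_fit; out_cov[[sx]] <- cov

    if (is.null(scan_units)) {
      key <- paste(cov$individual_id, cov$scan_id, sep = ":")
      u_scan <- draw_unit_effects(key, truth$re_sd$scan, truth$re_corr$scan)
      scan_key <- key
    } else {
      u_scan <- u_scan_shared
      scan_key <- cov$scan_id
    }
    u_scan_all[[sx]] <- u_scan

    X <- as.matrix(cov[, fixed_terms("M2")])
    Eta <- matrix(truth$intercepts, nrow(cov), K1, byrow = TRUE) +
      X %*% truth$fixed_betas +
      u_ind[cov$individual_id, , drop = FALSE] +
      u_scan[scan_key, , drop = FALSE] +
      u_litter[cov$litter_id, , drop = FALSE] +
      u_group[cov$group_id, , drop = FALSE]

    P <- cbind(exp(Eta), 1)
    P <- P / rowSums(P)
    labels <- c(cats, reference_category())
    ev <- lapply(seq_len(nrow(cov)), function(i) {
      n <- stats::rmultinom(1, truth$events_per_scan, P[i, ])[, 1]
      tibble::tibble(individual_id = cov$individual_id[i],
                     scan_id = cov$scan_id[i],
                     event_index = seq_len(truth$events_per_scan),
                     behaviour = sample(rep(labels, n)))
    })
    out_events[[sx]] <- dplyr::bind_rows(ev)
  }

  list(events = dplyr::bind_rows(out_events), covariates = out_cov,
       rm_fits = rm_fits,
       random_effects = list(individual = u_ind, scan = u_scan_all,
                             litter = u_litter, group = u_group))
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_population()] then [generate_events()],
#' fully determined by `config$seed`.
#'
#' @param config a [truth_config()].
#' @return list combining the population tables, events, per-sex covariates,
#'   relative-mass fits, drawn random effects and the `truth` config itself.
#' @export
simulate_dataset <- function(config) {
  pop <- generate_population(config)
  ev <- generate_events(pop, config)
  c(pop, ev, list(truth = config))
}
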