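#' Fit a multilevel multinomial behaviour model
#'
#' Aggregates sampling events into (individual, scan) cells of multinomial
#' counts over the six categories and samples the posterior of the specified
#' model variant with the package's No-U-Turn sampler, using the noncentred
#' Cholesky parameterization of all correlated random-effect levels.
#'
#' Split-\eqn{\hat R} is computed for every non-innovation parameter
#' (intercepts, slopes, log SDs, correlation parameters); a warning (not an
#' error) is raised if any exceeds 1.05 or if post-warmup divergences
#' occurred.
#'
#' @param spec an [mmbm_spec()].
#' @param events event table (individual_id, scan_id, behaviour); only
#'   individuals present in `covariates` (i.e. of the spec's sex) are used.
#' @param covariates a [build_covariates()] table for the same sex. May be
#'   NULL for M1, in which case cell structure is taken from the events.
#' @return object of class `mmbm_fit`: per-chain draw matrices on the
#'   unconstrained scale plus a parameter map, the model data, covariate
#'   scaling, and sampler diagnostics. Use the extractors
#'   ([alpha_draws()], [beta_draws()], [sigma_draws()],
#'   [correlation_draws()], [unit_effect_draws()], [pointwise_loglik()]) to
#'   work with the posterior.
#' @export
mmbm_fit <- function(spec, events, covariates = NULL) {
  stopifnot(inherits(spec, "mmbm_spec"))
  cats <- nonreference_categories()
  K1 <- length(cats)
  if (is.null(covariates) && spec$variant != "M1")
    stop(spec$variant, " needs a covariate table")

  ev <- tibble::tibble(individual_id = as.character(events$individual_id),
                       scan_id = as.character(events$scan_id),
                       behaviour = events$behaviour)
  if (!all(ev$behaviour %in% behaviour_categories()))
    stop("events contain labels outside the six-category vocabulary")
  if (!is.null(covariates))
    ev <- ev[ev$individual_id %in% covariates$individual_id, ]
  if (nrow(ev) == 0) stop("no events to fit")

  cells <- dplyr::distinct(ev[, c("individual_id", "scan_id")])
  cells <- cells[order(cells$individual_id, cells$scan_id), ]
  key <- paste(cells$individual_id, cells$scan_id, sep = ":")
  counts <- unclass(table(
    factor(paste(ev$individual_id, ev$scan_id, sep = ":"), levels = key),
    factor(ev$behaviour, levels = c(cats, reference_category()))))
  counts <- matrix(as.numeric(counts), nrow(cells),
                   dimnames = list(key, c(cats, reference_category())))

  if (!is.null(covariates)) {
    ckey <- paste(covariates$individual_id, covariates$scan_id, sep = ":")
    pos <- match(key, ckey)
    if (anyNA(pos))
      stop("no covariate row for cell(s): ",
           paste(utils::head(key[is.na(pos)], 3), collapse = ", "))
    cov <- covariates[pos, ]
    cells$group_id <- cov$group_id
    cells$litter_id <- cov$litter_id
  } else cov <- NULL

  P <- length(spec$fixed_terms)
  X <- if (P > 0) as.matrix(cov[, spec$fixed_terms]) else
    matrix(0, nrow(cells), 0)

  # random-effect levels: cell -> unit index (0-based for the sampler)
  unit_key <- function(level) switch(level,
    individual = cells$individual_id,
    scan = if (spec$scan_grain == "group_scan") cells$scan_id else key,
    litter = cells$litter_id,
    group = cells$group_id)
  levels_list <- lapply(spec$re_levels, function(lev) {
    k <- unit_key(lev)
    if (is.null(k)) stop("cannot build level ", lev, " without covariates")
    units <- sort(unique(k))
    list(name = lev, units = units, uidx = match(k, units) - 1L,
         correlated = !(lev %in% spec$diagonal_levels))
  })
  names(levels_list) <- spec$re_levels
  if (any(vapply(levels_list, function(l) length(l$units), 1L) < 2))
    warning("random-effect level(s) with a single unit are weakly ",
            "identified: ",
            paste(spec$re_levels[vapply(levels_list,
              function(l) length(l$units), 1L) < 2], collapse = ", "))

  pm <- param_map(P, levels_list, K1)
  cpp_levels <- lapply(levels_list, function(l)
    list(uidx = l$uidx, n_units = length(l$units), correlated = l$correlated))
  cpp_priors <- list(intercept_scale = spec$priors$intercept_scale,
                     beta_scale = spec$priors$beta_scale,
                     sd_rate = spec$priors$sd_rate,
                     lkj_eta = spec$priors$lkj_eta)

  run_chain <- function() {
    .mmbm_nuts_chain(counts[, cats, drop = FALSE],
                     counts[, reference_category()], X, unname(cpp_levels),
                     cpp_priors, spec$iter, spec$warmup, spec$adapt_delta,
                     spec$max_depth, 0.1)
  }
  chains <- with_seed(spec$seed, lapply(seq_len(spec$chains),
                                        function(i) run_chain()))

  divergences <- sum(vapply(chains, `[[`, 0, "divergences"))
  rhat <- chain_rhat(chains, pm)
  fit <- structure(list(
    spec = spec,
    draws = lapply(chains, `[[`, "draws"),
    lp = lapply(chains, `[[`, "lp"),
    param_map = pm,
    data = list(counts = counts, X = X, cells = cells, levels = levels_list),
    scaling = if (!is.null(covariates)) attr(covariates, "scaling"),
    covariate_range = if (!is.null(cov)) list(
      age = range(cov$age_days), group_size = range(cov$group_size),
      relative_mass = range(cov$relative_mass)),
    diagnostics = list(
      rhat = rhat, divergences = divergences,
      step_size = vapply(chains, `[[`, 0, "step_size"),
      mean_accept = vapply(chains, `[[`, 0, "mean_accept"))
  ), class = "mmbm_fit")

  if (any(rhat$rhat > 1.05, na.rm = TRUE))
    warning("split-Rhat above 1.05 for ", sum(rhat$rhat > 1.05, na.rm = TRUE),
            " parameter(s); consider more iterations")
  if (divergences > 0)
    warning(divergences, " post-warmup divergence(s)")
  fit
}

# offsets (1-based) of each block in the unconstrained parameter vector;
# must mirror the sampler's layout exactly
param_map <- function(P, levels_list, K1 = 5) {
  ncorr <- K1 * (K1 - 1) / 2
  off <- 0L
  pm <- list(alpha = list(offset = off, length = K1))
  off <- off + K1
  if (P > 0) {
    pm$beta <- list(offset = off, length = P * K1)
    off <- off + P * K1
  }
  pm$levels <- list()
  for (l in levels_list) {
    entry <- list(log_sigma = list(offset = off, length = K1))
    off <- off + K1
    if (l$correlated) {
      entry$y <- list(offset = off, length = ncorr)
      off <- off + ncorr
    }
    entry$z <- list(offset = off, length = K1 * length(l$units))
    off <- off + entry$z$length
    pm$levels[[l$name]] <- entry
  }
  pm$dim <- off
  pm
}

chain_rhat <- function(chains, pm) {
  K1 <- length(nonreference_categories())
  idx <- c(pm$alpha$offset + seq_len(pm$alpha$length))
  labs <- paste0("alpha[", nonreference_categories(), "]")
  if (!is.null(pm$beta)) {
    idx <- c(idx, pm$beta$offset + seq_len(pm$beta$length))
    labs <- c(labs, paste0("beta[", seq_len(pm$beta$length), "]"))
  }
  for (nm in names(pm$levels)) {
    l <- pm$levels[[nm]]
    idx <- c(idx, l$log_sigma$offset + seq_len(K1))
    labs <- c(labs, paste0("log_sigma[", nm, ",",
                           nonreference_categories(), "]"))
    if (!is.null(l$y)) {
      idx <- c(idx, l$y$offset + seq_len(l$y$length))
      labs <- c(labs, paste0("corr_raw[", nm, ",", seq_len(l$y$length), "]"))
    }
  }
  rh <- vapply(idx, function(j)
    split_rhat(sapply(chains, function(ch) ch$draws[, j])), 1.0)
  tibble::tibble(param = labs, rhat = rh)
}

#' @export
print.mmbm_fit <- function(x, ...) {
  sp <- x$spec
  cat("Multilevel multinomial behaviour model ", sp$variant, " (sex ",
      sp$sex, ")\n", sep = "")
  cat("  cells: ", nrow(x$data$counts), "  events: ", sum(x$data$counts),
      "  fixed terms: ", length(sp$fixed_terms), "\n", sep = "")
  cat("  levels: ", paste(sp$re_levels, collapse = ", "), "\n", sep = "")
  cat("  chains: ", sp$chains, " x ", sp$iter - sp$warmup,
      " post-warmup draws; divergences: ", x$diagnostics$divergences,
      "; max split-Rhat: ",
      signif(max(x$diagnostics$rhat$rhat, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}
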