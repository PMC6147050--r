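#' Pipeline: simulate a dataset to disk
#'
#' Runs the synthetic-data generator and writes the standard file formats
#' (events CSV, scan-session CSV, mass CSV), a `truth.json` recording every
#' generating parameter, and a run manifest with seeds and software
#' versions. Any full pipeline run is reproducible from its manifest.
#'
#' @param config a [truth_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return (invisibly) named vector of the written file paths.
#' @export
run_simulate <- function(config = truth_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  paths <- c(
    events = file.path(out_dir, "events.csv"),
    scans = file.path(out_dir, "scans.csv"),
    masses = file.path(out_dir, "masses.csv"),
    truth = file.path(out_dir, "truth.json"))
  write_events(sim$events, sim$individuals, sim$scans, paths[["events"]])
  write_scans(sim$scans, paths[["scans"]])
  write_masses(sim$masses, paths[["masses"]])
  truth <- unclass(config)
  truth$fixed_betas <- as.data.frame(truth$fixed_betas)
  truth$re_corr <- lapply(truth$re_corr, as.data.frame)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  write_manifest(out_dir, "simulate",
                 list(seed = config$seed, scenario = config$scenario,
                      files = as.list(paths)))
  invisible(paths)
}

#' Pipeline: fit model variants to a dataset directory
#'
#' Reads the dataset written by [run_simulate()] (or hand-prepared files in
#' the same formats), rebuilds the sex-specific relative-mass fits and
#' covariates, fits the requested variants per sex, and writes per-fit draw
#' tables (intercepts, slopes, SDs, correlations per draw) plus a
#' diagnostics log. Fit objects are also saved for downstream summarising.
#'
#' @param data_dir directory holding `events.csv`, `scans.csv`,
#'   `masses.csv`.
#' @param out_dir output directory.
#' @param variants model variants to fit (default all three).
#' @param sexes sexes to fit (default both).
#' @param chains,iter,warmup,adapt_delta,diagonal_levels sampler settings
#'   passed to [mmbm_spec()]; the defaults here are a reduced demo scale,
#'   not the 3 x 1000 headline settings.
#' @param seed base seed; each (sex, variant) fit offsets it.
#' @return (invisibly) list of `mmbm_fit` objects keyed `"<sex>_<variant>"`.
#' @export
run_fit <- function(data_dir, out_dir, variants = c("M1", "M2", "M3"),
                    sexes = c("F", "M"), chains = 2, iter = 600,
                    warmup = 300, adapt_delta = 0.9,
                    diagonal_levels = c("scan", "litter", "group"),
                    seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- read_events(file.path(data_dir, "events.csv"),
                     scans_path = file.path(data_dir, "scans.csv"))
  masses <- read_masses(file.path(data_dir, "masses.csv"))
  fits <- list()
  k <- 0L
  for (sx in sexes) {
    rm_fit <- fit_relative_mass(masses, dat$individuals, sx)
    participation <- dplyr::distinct(dat$events[, c("individual_id",
                                                    "scan_id")])
    cov <- build_covariates(dat$individuals, dat$scans, masses, rm_fit, sx,
                            participation = participation)
    for (v in variants) {
      k <- k + 1L
      spec <- mmbm_spec(v, sx, chains = chains, iter = iter, warmup = warmup,
                        adapt_delta = adapt_delta,
                        diagonal_levels = if (v == "M3") diagonal_levels
                                          else character(0),
                        seed = seed + 1000L * k)
      fit <- mmbm_fit(spec, dat$events, cov)
      tag <- paste0(sx, "_", v)
      fits[[tag]] <- fit
      write_draws_csv(fit, file.path(out_dir, paste0("draws_", tag, ".csv")))
      saveRDS(fit, file.path(out_dir, paste0("fit_", tag, ".rds")))
      jsonlite::write_json(
        c(unclass(spec)[c("variant", "sex", "fixed_terms", "re_levels",
                          "chains", "iter", "warmup", "adapt_delta",
                          "scan_grain", "diagonal_levels", "seed")],
          list(priors = unclass(spec$priors))),
        file.path(out_dir, paste0("spec_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  diag_lines <- vapply(names(fits), function(tag) {
    f <- fits[[tag]]
    paste0(tag, ": divergences=", f$diagnostics$divergences,
           " max_rhat=", signif(max(f$diagnostics$rhat$rhat, na.rm = TRUE), 4))
  }, "")
  writeLines(diag_lines, file.path(out_dir, "diagnostics.log"))
  write_manifest(out_dir, "fit",
                 list(seed = seed, variants = variants, sexes = sexes,
                      chains = chains, iter = iter, warmup = warmup))
  invisible(fits)
}

# one row per draw: intercepts, slopes, per-level SDs and correlations
write_draws_csv <- function(fit, path) {
  al <- alpha_draws(fit)
  colnames(al) <- paste0("alpha.", colnames(al))
  out <- as.data.frame(al)
  if (!is.null(fit$param_map$beta)) {
    be <- beta_draws(fit)
    for (tm in dimnames(be)[[2]])
      for (ct in dimnames(be)[[3]])
        out[[paste0("beta.", tm, ".", ct)]] <- be[, tm, ct]
  }
  for (lev in fit$spec$re_levels) {
    sg <- sigma_draws(fit, lev)
    for (ct in colnames(sg)) out[[paste0("sd.", lev, ".", ct)]] <- sg[, ct]
    if (!(lev %in% fit$spec$diagonal_levels)) {
      om <- correlation_draws(fit, lev)
      pr <- utils::combn(nonreference_categories(), 2)
      for (j in seq_len(ncol(pr)))
        out[[paste0("corr.", lev, ".", pr[1, j], ".", pr[2, j])]] <-
          om[, pr[1, j], pr[2, j]]
    }
  }
  ndraw <- nrow(fit$draws[[1]])
  out <- cbind(chain = rep(seq_along(fit$draws), each = ndraw),
               iteration = rep(seq_len(ndraw), length(fit$draws)), out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline: summarize fitted models
#'
#' Writes per-fit correlation summaries, a combined two-variant
#' presentation-layout correlation matrix per sex (M1 upper / M2 lower
#' triangle) when both variants are present, and the task-specialization
#' verdict per sex (from M1, falling back to the first fitted variant).
#'
#' @param fit_dir directory written by [run_fit()].
#' @param out_dir output directory (defaults to `fit_dir`).
#' @return (invisibly) list of verdict reports per sex.
#' @export
run_summarize <- function(fit_dir, out_dir = fit_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- load_fits(fit_dir)
  verdicts <- list()
  for (sx in unique(sub("_M[123]$", "", names(fits)))) {
    summ <- list()
    for (v in c("M1", "M2", "M3")) {
      tag <- paste0(sx, "_", v)
      if (is.null(fits[[tag]])) next
      s <- summarize_correlations(fits[[tag]], "individual")
      summ[[v]] <- s
      utils::write.csv(s, file.path(out_dir,
                                    paste0("correlations_", tag, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(summ$M1) && !is.null(summ$M2)) {
      tab <- format_correlation_table(summ$M1, summ$M2)
      utils::write.csv(cbind(category = rownames(tab), tab),
                       file.path(out_dir,
                                 paste0("correlation_matrix_", sx, ".csv")),
                       row.names = FALSE)
    }
    base <- summ$M1 %||% summ[[1]]
    if (!is.null(base)) {
      rep <- specialization_verdict(base)
      verdicts[[sx]] <- rep
      jsonlite::write_json(
        list(sex = sx, verdict = rep$verdict,
             specialization_detected = rep$specialization_detected,
             sign_pattern = rep$sign_pattern),
        file.path(out_dir, paste0("verdict_", sx, ".json")),
        auto_unbox = TRUE, digits = NA)
      writeLines(c(paste("sex:", sx), paste("verdict:", rep$verdict),
                   rep$sign_pattern),
                 file.path(out_dir, paste0("verdict_", sx, ".txt")))
    }
  }
  write_manifest(out_dir, "summarize", list(fit_dir = fit_dir))
  invisible(verdicts)
}

#' Pipeline: compare fitted variants by WAIC
#'
#' @param fit_dir directory written by [run_fit()].
#' @param out_dir output directory (defaults to `fit_dir`).
#' @return (invisibly) list of per-sex WAIC comparison tibbles (ascending
#'   WAIC with deltas against the best variant).
#' @export
run_compare <- function(fit_dir, out_dir = fit_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- load_fits(fit_dir)
  out <- list()
  for (sx in unique(sub("_M[123]$", "", names(fits)))) {
    sel <- fits[grep(paste0("^", sx, "_"), names(fits))]
    names(sel) <- sub(paste0("^", sx, "_"), "", names(sel))
    tab <- compare_waic(sel)
    out[[sx]] <- tab
    utils::write.csv(tab, file.path(out_dir, paste0("waic_", sx, ".csv")),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "compare", list(fit_dir = fit_dir))
  invisible(out)
}

load_fits <- function(fit_dir) {
  files <- list.files(fit_dir, "^fit_.*\\.rds$", full.names = TRUE)
  if (length(files) == 0) stop("no fit_*.rds files in ", fit_dir)
  fits <- lapply(files, readRDS)
  names(fits) <- sub("^fit_(.*)\\.rds$", "\\1", basename(files))
  fits
}

write_manifest <- function(out_dir, command, extra) {
  manifest <- c(list(
    command = command,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("mmbm")),
    r_version = R.version.string), extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", command,
                                                 ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
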