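#' Summarize random-effect correlations
#'
#' Posterior summaries of the 10 pairwise correlations among the five
#' non-reference behaviours at a random-effect level, taken directly from
#' the draw-wise variance-covariance (correlation) matrices. A pair is
#' flagged significant when its equal-tailed 95% credible interval excludes
#' zero -- the rule behind the task-specialization test. Correlations
#' involving the reference category (rest) are not estimated.
#'
#' @param fit an [mmbm_fit()], or a draws x 5 x 5 correlation-draws array
#'   (as from [correlation_draws()]) with category dimnames.
#' @param level random-effect level (default `"individual"`; the
#'   specialization test is defined at this level).
#' @param prob credible-interval mass for the significance flag (default
#'   0.95).
#' @return tibble with one row per unordered category pair: `level`,
#'   `category_a`, `category_b`, `cooperative_pair`, `mean`, `sd`,
#'   `cri_low`, `cri_high`, `significant`.
#' @export
summarize_correlations <- function(fit, level = "individual", prob = 0.95) {
  om <- if (is.array(fit) && length(dim(fit)) == 3) fit
        else correlation_draws(fit, level)
  cats <- nonreference_categories()
  coop <- cooperative_categories()
  pairs <- utils::combn(cats, 2)
  a <- (1 - prob) / 2
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    ca <- pairs[1, j]; cb <- pairs[2, j]
    r <- om[, ca, cb]
    q <- stats::quantile(r, c(a, 1 - a), names = FALSE)
    tibble::tibble(level = level, category_a = ca, category_b = cb,
                   cooperative_pair = ca %in% coop && cb %in% coop,
                   mean = mean(r), sd = stats::sd(r),
                   cri_low = q[1], cri_high = q[2],
                   significant = q[1] > 0 || q[2] < 0)
  })
  dplyr::bind_rows(rows)
}

#' The task-specialization verdict
#'
#' Task specialization (in the caste sense) requires within-individual
#' trade-offs: significantly negative individual-level correlations between
#' cooperative behaviours (work, food carrying, nest building). The verdict
#' is `"specialization detected"` iff any cooperative pair's correlation is
#' significantly negative; when instead all cooperative pairs are
#' significantly positive the helpers are generalists and the verdict is
#' `"no specialization; generalist helpers"`; otherwise
#' `"no specialization detected"` with the observed sign pattern.
#'
#' @param summaries a [summarize_correlations()] table (individual level).
#' @return object of class `specialization_report`: `verdict`,
#'   `specialization_detected`, `cooperative_pairs` (the relevant rows) and
#'   `sign_pattern`.
#' @export
specialization_verdict <- function(summaries) {
  coop <- summaries[summaries$cooperative_pair, ]
  neg <- coop$significant & coop$mean < 0
  pos <- coop$significant & coop$mean > 0
  verdict <- if (any(neg)) "specialization detected"
  else if (all(pos)) "no specialization; generalist helpers"
  else "no specialization detected"
  pattern <- paste0(coop$category_a, "~", coop$category_b, ": ",
                    ifelse(coop$mean >= 0, "+", "-"),
                    ifelse(coop$significant, " (significant)", ""))
  structure(list(verdict = verdict, specialization_detected = any(neg),
                 cooperative_pairs = coop, sign_pattern = pattern),
            class = "specialization_report")
}

#' @export
print.specialization_report <- function(x, ...) {
  cat("Task-specialization test (individual-level random-effect",
      "correlations)\n")
  cat("  verdict:", x$verdict, "\n")
  for (s in x$sign_pattern) cat("   ", s, "\n")
  invisible(x)
}

#' Two-model correlation matrix in presentation layout
#'
#' Formats random-effect correlations from two model variants as a single
#' square table over the five non-reference behaviours: the upper triangle
#' holds the first model's estimates, the lower triangle the second's. Each
#' entry reads `"mean (sd)"` with a trailing `*` when the 95% credible
#' interval excludes zero.
#'
#' @param upper,lower [summarize_correlations()] tables (e.g. Model 1 and
#'   Model 2 for one sex).
#' @param digits decimal places (default 2).
#' @return data.frame of formatted strings with category row/column names.
#' @export
format_correlation_table <- function(upper, lower, digits = 2) {
  cats <- nonreference_categories()
  fmt <- function(row) sprintf(paste0("%.", digits, "f (%.", digits, "f)%s"),
                               row$mean, row$sd,
                               ifelse(row$significant, "*", ""))
  out <- matrix("", length(cats), length(cats),
                dimnames = list(cats, cats))
  for (j in seq_len(nrow(upper))) {
    r <- upper[j, ]
    out[r$category_a, r$category_b] <- fmt(r)
  }
  for (j in seq_len(nrow(lower))) {
    r <- lower[j, ]
    out[r$category_b, r$category_a] <- fmt(r)
  }
  as.data.frame(out)
}
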