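#' Subsample scan sessions for one individual
#'
#' Restricts an individual's scan sessions to `n`, always keeping the
#' chronologically first and last scan (to preserve age coverage) and drawing
#' the remaining `n - 2` uniformly without replacement from the interior
#' scans. If the individual has `n` or fewer scans, all are returned (with a
#' warning when fewer).
#'
#' @param scans data frame of this individual's scan sessions with at least
#'   columns `scan_id` and `date`.
#' @param n number of scans to keep (default 10); must be >= 2.
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return the selected rows of `scans`, in chronological order.
#' @export
select_scans <- function(scans, n = 10, seed = NULL) {
  if (n < 2) stop("n must be at least 2 (first and last scan are always kept)")
  stopifnot(all(c("scan_id", "date") %in% names(scans)))
  ord <- order(scans$date, scans$scan_id)
  scans <- scans[ord, , drop = FALSE]
  m <- nrow(scans)
  if (m <= n) {
    if (m < n) warning("individual has only ", m, " scans; returning all")
    return(scans)
  }
  interior <- 2:(m - 1)
  keep <- with_seed(seed, sample(interior, n - 2))
  idx <- sort(c(1L, keep, m))
  scans[idx, , drop = FALSE]
}
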