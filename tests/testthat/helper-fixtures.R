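# Shared in-code fixtures for the test suite. Everything is generated at
# test time; no data files are read.

`%||%` <- function(a, b) if (is.null(a)) b else a

cats6 <- behaviour_categories()
cats5 <- nonreference_categories()

# a tiny hand-written observational dataset: 2 groups, 3 individuals,
# 2 scans each, `events_per` events per (individual, scan)
tiny_dataset <- function(events_per = 6, seed = 99) {
  individuals <- tibble::tibble(
    individual_id = c("i1", "i2", "i3"),
    sex = c("F", "F", "M"),
    birth_date = as.Date(c("2014-01-01", "2014-01-15", "2014-02-01")),
    group_id = c("g1", "g2", "g1"),
    litter_id = c("g1_L1", "g2_L1", "g1_L2"),
    is_breeder = FALSE)
  scans <- tibble::tibble(
    scan_id = c("g1_s1", "g1_s2", "g2_s1", "g2_s2"),
    group_id = c("g1", "g1", "g2", "g2"),
    date = as.Date(c("2014-06-01", "2014-08-01", "2014-07-01", "2014-09-01")),
    group_size = c(4L, 4L, 3L, 3L),
    pups_present = c(TRUE, FALSE, FALSE, TRUE))
  pairs <- dplyr::inner_join(individuals[, c("individual_id", "group_id")],
                             scans[, c("scan_id", "group_id")],
                             by = "group_id", relationship = "many-to-many")
  events <- withr::with_seed(seed, dplyr::bind_rows(lapply(
    seq_len(nrow(pairs)), function(i) tibble::tibble(
      individual_id = pairs$individual_id[i],
      scan_id = pairs$scan_id[i],
      event_index = seq_len(events_per),
      behaviour = sample(cats6, events_per, replace = TRUE)))))
  masses <- dplyr::bind_rows(lapply(seq_len(nrow(individuals)), function(i) {
    dates <- individuals$birth_date[i] + seq(80, 260, by = 30)
    tibble::tibble(individual_id = individuals$individual_id[i], date = dates,
                   mass_g = 40 + 0.2 * seq(80, 260, by = 30))
  }))
  list(individuals = individuals, scans = scans, events = events,
       masses = masses)
}

# a small simulated dataset from a known truth, shared by several fit tests
small_truth <- function(scenario = "no_specialization", seed = 1, ...) {
  truth_config(scenario, n_groups = 5, n_females = 10, n_males = 8,
               n_scans_per_individual = 4, events_per_scan = 50,
               seed = seed, ...)
}

# reduced-scale sampler settings used throughout the tests
test_spec <- function(variant, sex = "F", iter = 500, warmup = 250, ...) {
  mmbm_spec(variant, sex, chains = 2, iter = iter, warmup = warmup,
            adapt_delta = 0.85, ...)
}

# brute-force multinomial-logit probabilities, independent of the package's
# log-sum-exp implementation (safe only for moderate eta)
naive_probs <- function(eta) {
  e <- c(exp(eta), 1)
  p <- e / sum(e)
  names(p) <- c(cats5, "rest")
  p[cats6]
}
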