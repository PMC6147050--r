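test_that("default design counts match the emulated study", {
  cfg <- truth_config("no_specialization", seed = 5)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$individuals), 116)
  expect_equal(sum(pop$individuals$sex == "F"), 60)
  expect_equal(sum(pop$individuals$sex == "M"), 56)
  expect_equal(length(unique(pop$individuals$group_id)), 35)
  expect_equal(nrow(pop$scans), 35 * 10)
  expect_false(any(pop$individuals$is_breeder))
  # litters nest within groups
  lit <- dplyr::distinct(pop$individuals[, c("litter_id", "group_id")])
  expect_false(anyDuplicated(lit$litter_id) > 0)

  # first/last-scan ages centre near the design's 136 and 716 days
  first_scan <- stats::aggregate(date ~ group_id, pop$scans, min)
  last_scan <- stats::aggregate(date ~ group_id, pop$scans, max)
  ind <- pop$individuals
  age1 <- as.numeric(first_scan$date[match(ind$group_id,
                                           first_scan$group_id)] -
                       ind$birth_date)
  age2 <- as.numeric(last_scan$date[match(ind$group_id,
                                          last_scan$group_id)] -
                       ind$birth_date)
  expect_gt(mean(age1), 110); expect_lt(mean(age1), 165)
  expect_gt(mean(age2), 640); expect_lt(mean(age2), 800)
})

test_that("the generator is deterministic and scales as a product", {
  cfg <- small_truth(seed = 21)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$masses, s2$masses)
  # events per individual = scans x events_per_scan
  per_ind <- table(s1$events$individual_id)
  expect_true(all(per_ind == cfg$n_scans_per_individual *
                    cfg$events_per_scan))
})

test_that("event frequencies follow the analytic softmax", {
  # all generating parameters zero: each category lands at 1/6
  cfg <- truth_config("null", n_groups = 3, n_females = 7, n_males = 0,
                      n_scans_per_individual = 4, events_per_scan = 4000,
                      re_sd = list(individual = rep(0, 5), scan = rep(0, 5),
                                   litter = rep(0, 5), group = rep(0, 5)),
                      seed = 31)
  sim <- simulate_dataset(cfg)
  N <- nrow(sim$events)
  freq <- table(factor(sim$events$behaviour, levels = cats6)) / N
  mc <- 3 * sqrt((1 / 6) * (5 / 6) / N)
  expect_true(all(abs(freq - 1 / 6) < mc))

  # intercepts (log 2, 0, 0, 0, 0): first category 2/7, reference 1/7
  cfg2 <- truth_config("null", n_groups = 3, n_females = 7, n_males = 0,
                       n_scans_per_individual = 4, events_per_scan = 4000,
                       intercepts = c(log(2), 0, 0, 0, 0),
                       re_sd = list(individual = rep(0, 5),
                                    scan = rep(0, 5), litter = rep(0, 5),
                                    group = rep(0, 5)),
                       seed = 32)
  sim2 <- simulate_dataset(cfg2)
  freq2 <- table(factor(sim2$events$behaviour, levels = cats6)) / N
  mc2 <- 3 * sqrt((2 / 7) * (5 / 7) / N)
  expect_lt(abs(freq2[["active_nonhelping"]] - 2 / 7), mc2)
  expect_lt(abs(freq2[["rest"]] - 1 / 7), mc2)
})

test_that("scenario presets encode the intended correlation structures", {
  ns <- scenario_preset("no_specialization")
  coop <- cooperative_categories()
  R <- ns$re_corr_individual
  expect_true(all(R[coop, coop][upper.tri(diag(3))] > 0))
  expect_true(all(R[upper.tri(R)] > 0))

  expect_equal(unname(scenario_preset("null")$re_corr_individual), diag(5))

  pc <- scenario_preset("permanent_caste")$re_corr_individual
  expect_lte(min(pc[coop, coop]), -0.5)
  expect_gte(min(eigen(pc, symmetric = TRUE)$values), 0)

  tc <- scenario_preset("temporal_caste")
  expect_true(any(tc$fixed_betas["age_z", coop] > 0) &&
                any(tc$fixed_betas["age_z", coop] < 0))

  expect_error(scenario_preset("flying_caste"), "no_specialization")
  expect_error(truth_config("bogus"))
})

test_that("invalid correlation inputs are rejected", {
  R <- diag(5); R[1, 2] <- R[2, 1] <- 1.2  # not PSD
  expect_error(truth_config("null", re_corr = list(individual = R)),
               "positive semi-definite")
  R2 <- diag(5); R2[1, 2] <- 0.5           # asymmetric
  expect_error(truth_config("null", re_corr = list(individual = R2)),
               "symmetric")
})

test_that("simulated unit effects reproduce the target covariance", {
  withr::local_seed(41)
  sd <- c(0.3, 0.5, 0.7, 1.0, 0.4)
  R <- scenario_preset("permanent_caste")$re_corr_individual
  U <- mmbm:::draw_unit_effects(seq_len(1e5), sd, R)
  target <- diag(sd) %*% R %*% diag(sd)
  emp <- stats::cov(U)
  expect_lt(max(abs(emp - target) / max(abs(target))), 0.05)
})

test_that("a permanent-caste truth leaves its trace in raw behaviour counts", {
  # individual-level empirical log-odds of work vs food carrying should be
  # negatively correlated when the generating correlation is -0.8
  negs <- vapply(1:5, function(r) {
    cfg <- truth_config("permanent_caste", n_groups = 6, n_females = 30,
                        n_males = 0, n_scans_per_individual = 4,
                        events_per_scan = 250, seed = 100 + r)
    sim <- simulate_dataset(cfg)
    tab <- table(sim$events$individual_id,
                 factor(sim$events$behaviour, levels = cats6))
    lo <- log((tab + 0.5) / (tab[, "rest"] + 0.5))
    stats::cor(lo[, "work"], lo[, "food_carry"]) < 0
  }, logical(1))
  expect_gte(sum(negs), 4)
})
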