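# helpers to simulate mass data from the log-log growth model
make_mass_data <- function(n_groups, n_per_group, a = 1.5, b = 0.8,
                           sigma_group = 0.1, sigma_resid = 0.05,
                           group_offsets = NULL) {
  groups <- sprintf("g%02d", seq_len(n_groups))
  off <- group_offsets %||% stats::rnorm(n_groups, 0, sigma_group)
  rows <- lapply(seq_len(n_groups), function(g) {
    age <- round(stats::runif(n_per_group, 60, 700))
    id <- sprintf("%s_i%02d", groups[g], seq_len(n_per_group))
    tibble::tibble(
      individual_id = id, group_id = groups[g], sex = "F",
      birth_date = as.Date("2014-01-01"),
      age = age,
      mass_g = exp(a + b * log(age) + off[g] +
                     stats::rnorm(n_per_group, 0, sigma_resid)))
  })
  d <- dplyr::bind_rows(rows)
  list(individuals = tibble::tibble(
         individual_id = d$individual_id, sex = d$sex,
         birth_date = d$birth_date, group_id = d$group_id,
         litter_id = d$group_id, is_breeder = FALSE),
       masses = tibble::tibble(individual_id = d$individual_id,
                               date = d$birth_date + round(d$age),
                               mass_g = d$mass_g),
       offsets = off)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("noise-free data are fitted exactly and residuals vanish", {
  withr::local_seed(1)
  d <- make_mass_data(1, 30, a = 1.5, b = 0.8, sigma_resid = 0,
                      group_offsets = 0)
  expect_warning(fit <- fit_relative_mass(d$masses, d$individuals, "F"),
                 "single group")
  expect_equal(fit$intercept, 1.5, tolerance = 1e-8)
  expect_equal(fit$slope, 0.8, tolerance = 1e-8)
  expect_equal(fit$sigma_group, 0)

  age <- as.numeric(d$masses$date - as.Date("2014-01-01"))
  res <- relative_mass(fit, d$individuals$group_id, d$masses$mass_g, age)
  expect_lt(max(abs(res)), 1e-6)
  expect_lt(abs(mean(res)), 1e-6)

  # mass exactly e times the fitted mass gives residual 1
  res_e <- relative_mass(fit, "g01", exp(1) * exp(1.5 + 0.8 * log(200)), 200)
  expect_equal(unname(res_e), 1, tolerance = 1e-8)
})

test_that("group effects are the shrunken group means (BLUP formula)", {
  withr::local_seed(2)
  d <- make_mass_data(2, 200, sigma_resid = 0.05,
                      group_offsets = c(0.3, -0.3))
  fit <- fit_relative_mass(d$masses, d$individuals, "F")
  age <- as.numeric(d$masses$date - as.Date("2014-01-01"))
  # closed-form conditional mode given the estimated variance components:
  # u_g = tau^2 / (tau^2 + sigma^2 / n_g) * mean marginal residual of group g
  marg <- log(d$masses$mass_g) - (fit$intercept + fit$slope * log(age))
  for (g in names(fit$group_effects)) {
    sel <- d$individuals$group_id == g
    shrink <- fit$sigma_group^2 /
      (fit$sigma_group^2 + fit$sigma_resid^2 / sum(sel))
    expect_equal(unname(fit$group_effects[g]), shrink * mean(marg[sel]),
                 tolerance = 1e-3)
  }
  # large n per group: effects approach the true +/- 0.3 offsets
  expect_equal(sort(unname(fit$group_effects)), c(-0.3, 0.3),
               tolerance = 0.1)
  expect_equal(mean(fit$group_effects), 0, tolerance = 0.02)
})

test_that("the growth-model slope is recovered across replicate simulations", {
  withr::local_seed(3)
  covered <- vapply(1:20, function(r) {
    d <- make_mass_data(20, 30, a = 1.5, b = 0.8, sigma_group = 0.1,
                        sigma_resid = 0.05)
    ind <- d$individuals
    age <- as.numeric(d$masses$date - ind$birth_date)
    lmm <- lme4::lmer(log(mass_g) ~ log(age) + (1 | group_id),
                      data = cbind(d$masses, group_id = ind$group_id,
                                   age = age))
    est <- lme4::fixef(lmm)[["log(age)"]]
    se <- sqrt(diag(as.matrix(stats::vcov(lmm))))[2]
    abs(est - 0.8) <= 1.96 * se
  }, logical(1))
  expect_gte(sum(covered), 18)
})

test_that("residuals are invariant to mass units and unseen groups warn", {
  withr::local_seed(4)
  d <- make_mass_data(5, 40)
  fit_g <- fit_relative_mass(d$masses, d$individuals, "F")
  masses_kg <- d$masses
  masses_kg$mass_g <- masses_kg$mass_g / 1000
  fit_kg <- fit_relative_mass(masses_kg, d$individuals, "F")
  expect_equal(fit_kg$intercept, fit_g$intercept - log(1000),
               tolerance = 1e-6)
  expect_equal(fit_kg$slope, fit_g$slope, tolerance = 1e-6)
  age <- as.numeric(d$masses$date - d$individuals$birth_date)
  expect_equal(
    relative_mass(fit_kg, d$individuals$group_id, masses_kg$mass_g, age),
    relative_mass(fit_g, d$individuals$group_id, d$masses$mass_g, age),
    tolerance = 1e-6)

  expect_warning(r <- relative_mass(fit_g, "never_seen", 100, 300),
                 "never_seen")
  expect_equal(unname(r),
               log(100) - (fit_g$intercept + fit_g$slope * log(300)))
})

test_that("with no group variance the mixed fit matches ordinary regression", {
  withr::local_seed(5)
  d <- make_mass_data(10, 25, sigma_group = 0,
                      group_offsets = rep(0, 10))
  fit <- fit_relative_mass(d$masses, d$individuals, "F")
  age <- as.numeric(d$masses$date - d$individuals$birth_date)
  ols <- stats::lm(log(d$masses$mass_g) ~ log(age))
  expect_equal(fit$slope, unname(stats::coef(ols)[2]), tolerance = 1e-4)
  expect_equal(fit$intercept, unname(stats::coef(ols)[1]), tolerance = 1e-3)
  expect_lt(fit$sigma_group, 0.02)
})
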