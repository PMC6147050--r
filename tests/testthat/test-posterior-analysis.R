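# hand-built correlation-draws arrays for exercising the CrI rule without
# an MCMC run
corr_array <- function(draws_by_pair) {
  S <- length(draws_by_pair[[1]])
  om <- array(0, dim = c(S, 5, 5), dimnames = list(NULL, cats5, cats5))
  for (s in seq_len(S)) om[s, , ] <- diag(5)
  for (nm in names(draws_by_pair)) {
    pr <- strsplit(nm, "\\|")[[1]]
    om[, pr[1], pr[2]] <- draws_by_pair[[nm]]
    om[, pr[2], pr[1]] <- draws_by_pair[[nm]]
  }
  om
}

test_that("WAIC matches the direct formula", {
  # identical draws: no posterior variance, so p_waic = 0
  ll1 <- matrix(rep(c(-1.2, -0.4, -2.2), each = 3), 3)
  w1 <- waic(ll1)
  expect_equal(w1$p_waic, 0)
  expect_equal(w1$waic, -2 * sum(ll1[1, ]))

  # 2 draws x 2 observations against a longhand evaluation
  ll2 <- matrix(c(-1.0, -0.5,
                  -2.0, -0.2), 2, 2, byrow = TRUE)
  w2 <- waic(ll2)
  lppd_hand <- sum(log(colMeans(exp(ll2))))
  p_hand <- sum(apply(ll2, 2, stats::var))
  expect_equal(w2$lppd, lppd_hand, tolerance = 1e-12)
  expect_equal(w2$p_waic, p_hand, tolerance = 1e-12)
  expect_equal(w2$waic, -2 * (lppd_hand - p_hand), tolerance = 1e-12)

  expect_error(waic(matrix(-1, 1, 4)), "at least 2 draws")
})

test_that("WAIC is invariant to reordering and to duplicating draws", {
  withr::local_seed(11)
  ll <- matrix(-abs(stats::rnorm(200 * 30)), 200, 30)
  w <- waic(ll)
  o <- sample(30)
  wo <- waic(ll[, o])
  expect_equal(wo$waic, w$waic, tolerance = 1e-12)
  expect_equal(wo$se, w$se, tolerance = 1e-12)
  # duplicating every draw leaves lppd exactly, p_waic asymptotically
  wd <- waic(rbind(ll, ll))
  expect_equal(wd$lppd, w$lppd, tolerance = 1e-12)
  expect_equal(wd$p_waic, w$p_waic, tolerance = 0.01)

  # compressed (weighted) form equals the expanded computation
  wts <- sample(1:5, 30, replace = TRUE)
  expanded <- ll[, rep(seq_len(30), wts)]
  expect_equal(waic(ll, weights = wts)$waic, waic(expanded)$waic,
               tolerance = 1e-10)
})

test_that("correlation summaries apply the credible-interval rule", {
  om <- corr_array(list("food_carry|work" = rep(0.5, 200),
                        "eat|work" = seq(-0.5, 0.5, length.out = 200)))
  s <- summarize_correlations(om)
  expect_equal(nrow(s), 10)  # 5 choose 2
  fcw <- s[s$category_a == "food_carry" & s$category_b == "work", ]
  expect_equal(fcw$mean, 0.5)
  expect_equal(fcw$sd, 0)
  expect_true(fcw$significant)
  ew <- s[s$category_a == "eat" & s$category_b == "work", ]
  expect_false(ew$significant)
  expect_equal(ew$mean, 0, tolerance = 1e-12)

  # symmetry: the summary is about unordered pairs
  expect_true(all(s$category_a < s$category_b))

  # widening the interval never creates significance
  withr::local_seed(21)
  for (r in 1:10) {
    draws <- stats::rnorm(300, stats::runif(1, -0.3, 0.3), 0.15)
    om_r <- corr_array(list("food_carry|work" = draws))
    s95 <- summarize_correlations(om_r, prob = 0.95)
    s99 <- summarize_correlations(om_r, prob = 0.99)
    expect_true(all(s99$significant <= s95$significant))
  }
})

test_that("the specialization verdict follows the trade-off rule", {
  # all cooperative pairs positive and significant: generalist helpers
  om_pos <- corr_array(list("food_carry|work" = stats::rnorm(200, 0.4, 0.05),
                            "food_carry|nest_building" =
                              stats::rnorm(200, 0.3, 0.05),
                            "nest_building|work" =
                              stats::rnorm(200, 0.35, 0.05)))
  v1 <- specialization_verdict(summarize_correlations(om_pos))
  expect_equal(v1$verdict, "no specialization; generalist helpers")
  expect_false(v1$specialization_detected)

  # one significantly negative cooperative pair triggers detection
  om_neg <- corr_array(list("food_carry|work" =
                              stats::rnorm(200, -0.6, 0.05)))
  v2 <- specialization_verdict(summarize_correlations(om_neg))
  expect_equal(v2$verdict, "specialization detected")
  expect_true(v2$specialization_detected)
  expect_output(print(v2), "specialization detected")

  # a significant negative NON-cooperative pair must not trigger it
  om_other <- corr_array(list("active_nonhelping|eat" =
                                stats::rnorm(200, -0.6, 0.05)))
  v3 <- specialization_verdict(summarize_correlations(om_other))
  expect_false(v3$specialization_detected)
})

test_that("fixed-effects curves and contrasts recompute from the draws", {
  sim <- simulate_dataset(small_truth(seed = 31))
  fit <- mmbm_fit(test_spec("M2", iter = 300, warmup = 150, seed = 32),
                  sim$events, sim$covariates$F)

  pp <- predicted_probabilities(fit, "age", grid_length = 20)
  arr <- attr(pp, "draws")
  sums <- apply(arr, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(pp$lo <= pp$mean + 1e-12 & pp$mean <= pp$hi + 1e-12))
  expect_equal(range(pp$value), fit$covariate_range$age)

  # collapsing the posterior to a point mass collapses the band to zero
  # width and the curve to the plug-in softmax
  fit_pt <- fit
  row1 <- fit$draws[[1]][1, , drop = FALSE]
  for (i in seq_along(fit_pt$draws))
    fit_pt$draws[[i]] <- row1[rep(1, nrow(fit_pt$draws[[i]])), , drop = FALSE]
  pp_pt <- predicted_probabilities(fit_pt, "age", grid_length = 5)
  expect_equal(pp_pt$lo, pp_pt$hi, tolerance = 1e-12)
  al <- alpha_draws(fit_pt)[1, ]
  be <- beta_draws(fit_pt)[1, , ]
  x <- mmbm:::grid_design(fit$spec$fixed_terms, "age", pp_pt$z[1])
  plug <- category_probabilities(drop(x %*% be) + al)
  expect_equal(pp_pt$mean[pp_pt$value == pp_pt$value[1]],
               unname(plug[pp_pt$category[pp_pt$value == pp_pt$value[1]]]),
               tolerance = 1e-12)

  # contrast equals a longhand softmax difference per draw
  cc <- categorical_contrast(fit)
  ct <- attr(cc, "draws")
  al_d <- alpha_draws(fit); be_d <- beta_draws(fit)
  for (s in c(1, 57, 200)) {
    x1 <- stats::setNames(as.numeric(fit$spec$fixed_terms == "pups_present"),
                          fit$spec$fixed_terms)
    hand <- naive_probs(drop(x1 %*% be_d[s, , ]) + al_d[s, ]) -
      naive_probs(al_d[s, ])
    expect_equal(ct[s, ], hand, tolerance = 1e-10)
  }

  # point-mass posterior with zero pup effect: contrast identically zero
  fit_pt2 <- fit_pt
  pm <- fit_pt2$param_map
  ip <- pm$beta$offset + which(rep(fit$spec$fixed_terms, 5) ==
                                 "pups_present")
  for (i in seq_along(fit_pt2$draws)) fit_pt2$draws[[i]][, ip] <- 0
  cc0 <- categorical_contrast(fit_pt2)
  expect_equal(unname(cc0$mean), rep(0, 6), tolerance = 1e-14)
  expect_equal(cc0$lo, cc0$hi, tolerance = 1e-14)

  expect_error(categorical_contrast(fit, "moon_phase"), "not a fixed effect")
  expect_error(predicted_probabilities(
    mmbm_fit(test_spec("M1", iter = 100, warmup = 50, seed = 33),
             sim$events, sim$covariates$F), "age"), "no fixed effects")
})

test_that("formatted correlation tables round-trip through CSV", {
  withr::local_seed(41)
  om1 <- corr_array(list("food_carry|work" = stats::rnorm(100, 0.31, 0.12)))
  om2 <- corr_array(list("food_carry|work" = stats::rnorm(100, -0.13, 0.15)))
  s1 <- summarize_correlations(om1)
  s2 <- summarize_correlations(om2)
  tab <- format_correlation_table(s1, s2)
  expect_equal(dim(tab), c(5, 5))
  # entries carry mean (sd) with a significance mark
  entry <- tab["food_carry", "work"]
  expect_match(entry, "^-?0\\.\\d{2} \\(0\\.\\d{2}\\)\\*?$")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cbind(category = rownames(tab), tab), path,
                   row.names = FALSE)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back[["work"]][3], entry)
  expect_equal(back$category, cats5)
})
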