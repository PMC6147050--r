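test_that("events round-trip through write and read unchanged", {
  d <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(d$events, d$individuals, d$scans, path)
  spath <- withr::local_tempfile(fileext = ".csv")
  write_scans(d$scans, spath)
  back <- read_events(path, scans_path = spath)
  expect_equal(dplyr::arrange(back$events, individual_id, scan_id,
                              event_index),
               dplyr::arrange(d$events, individual_id, scan_id, event_index))
  expect_equal(dplyr::arrange(back$individuals, individual_id),
               dplyr::arrange(d$individuals, individual_id))
  expect_equal(dplyr::arrange(back$scans, scan_id),
               dplyr::arrange(d$scans, scan_id))
})

test_that("invalid event files are rejected with the offending row cited", {
  d <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(d$events, d$individuals, d$scans, path)
  df <- utils::read.csv(path)

  bad <- df
  bad$behaviour[5] <- "fly"
  p1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p1, row.names = FALSE)
  expect_error(read_events(p1), "fly")
  expect_error(read_events(p1), "row 5")

  dup <- rbind(df, df[1, ])
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, p2, row.names = FALSE)
  expect_error(read_events(p2), "duplicate")
})

test_that("ethogram collapse maps 16 raw labels onto exactly six categories", {
  raw <- sprintf("raw%02d", 1:16)
  mapping <- stats::setNames(rep(cats6, length.out = 16), raw)
  out <- collapse_ethogram(raw, mapping)
  expect_length(out, 16)
  expect_setequal(unique(out), cats6)

  # identity mapping on the six category names leaves labels unchanged
  idmap <- stats::setNames(cats6, cats6)
  expect_identical(collapse_ethogram(cats6, idmap), cats6)

  # unmapped raw label and non-surjective mappings both fail
  expect_error(collapse_ethogram(c(raw, "novel"), mapping), "novel")
  expect_error(collapse_ethogram("a", c(a = "rest")), "not surjective")
  expect_error(collapse_ethogram("a", c(a = "flying")), "unknown categories")
})

test_that("scan selection keeps the chronological extremes and is seeded", {
  scans <- tibble::tibble(scan_id = sprintf("s%02d", 1:15),
                          date = as.Date("2014-01-01") + seq(0, 700, 50))
  sel <- select_scans(scans, n = 10, seed = 3)
  expect_equal(nrow(sel), 10)
  expect_true(all(c("s01", "s15") %in% sel$scan_id))
  expect_identical(sel, select_scans(scans, n = 10, seed = 3))
  # shuffled input yields the same chronological choice
  expect_identical(select_scans(scans[sample(15), ], n = 10, seed = 3)$scan_id,
                   sel$scan_id)

  expect_identical(select_scans(scans[1:10, ], n = 10), scans[1:10, ])
  expect_warning(sel8 <- select_scans(scans[1:8, ], n = 10), "only 8")
  expect_equal(nrow(sel8), 8)
  expect_error(select_scans(scans, n = 1), "at least 2")
})

test_that("covariates are z-scored before powers and use the nearest mass", {
  d <- tiny_dataset()
  rm_fit <- fit_relative_mass(d$masses, d$individuals, "F")
  cov <- build_covariates(d$individuals, d$scans, d$masses, rm_fit, "F")
  expect_equal(nrow(cov), 4)  # 2 females x 2 scans
  for (col in c("age_z", "groupsize_z", "relative_mass_z")) {
    expect_lt(abs(mean(cov[[col]])), 1e-10)
    expect_lt(abs(stats::sd(cov[[col]]) - 1), 1e-10)
  }
  expect_equal(cov$age_z2, cov$age_z^2)
  expect_equal(cov$age_z3, cov$age_z^3)
  expect_equal(cov$groupsize_z2, cov$groupsize_z^2)

  # symmetric age triple standardizes to (-1, 0, 1) with the sample SD
  ages <- c(100, 400, 700)
  z <- (ages - mean(ages)) / stats::sd(ages)
  expect_equal(z, c(-1, 0, 1))

  # scan equidistant between two mass records resolves to the earlier one
  ind <- d$individuals[1, ]
  scans1 <- tibble::tibble(scan_id = c("sx", "sy"), group_id = "g1",
                           date = ind$birth_date + c(15, 19),
                           group_size = c(4L, 5L), pups_present = FALSE)
  masses1 <- tibble::tibble(individual_id = "i1",
                            date = ind$birth_date + c(10, 20),
                            mass_g = c(30, 60))
  rm1 <- structure(list(sex = "F", intercept = 0, slope = 0,
                        group_effects = c(g1 = 0), sigma_group = 0,
                        sigma_resid = 1, method = "OLS"),
                   class = "relative_mass_fit")
  # with a null relative-mass model the residual is just log(mass picked):
  # day-15 scan ties between days 10 and 20 -> earlier record (30 g);
  # day-19 scan is nearest day 20 -> 60 g
  cov1 <- build_covariates(ind, scans1, masses1, rm1, "F")
  expect_equal(cov1$relative_mass[order(cov1$scan_id)], log(c(30, 60)))
})

test_that("degenerate covariate inputs fail loudly", {
  d <- tiny_dataset()
  rm_fit <- fit_relative_mass(d$masses, d$individuals, "F")
  # constant group size across the dataset cannot be standardized
  scans_const <- d$scans
  scans_const$group_size <- 5L
  expect_error(build_covariates(d$individuals, scans_const, d$masses, rm_fit,
                                "F"), "zero variance")
  # missing mass records name the individual
  expect_error(
    build_covariates(d$individuals, d$scans,
                     d$masses[d$masses$individual_id != "i2", ], rm_fit, "F"),
    "i2")
})

test_that("pup presence is an under-40-days flag over all group members", {
  scans <- tibble::tibble(scan_id = c("s1", "s2"), group_id = "g1",
                          date = as.Date("2014-06-01") + c(0, 60))
  members <- tibble::tibble(individual_id = c("a", "pup"), group_id = "g1",
                            birth_date = as.Date(c("2013-01-01",
                                                   "2014-05-01")))
  expect_equal(derive_pups_present(scans, members), c(TRUE, FALSE))
  # exactly 40 days old is no longer a pup
  members$birth_date[2] <- scans$date[1] - 40
  expect_false(derive_pups_present(scans, members)[1])
})
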