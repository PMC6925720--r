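test_that("the altitude adjustment is zero at sea level and monotone", {
  expect_equal(adjust_hb_for_altitude(11.5, 0), 11.5)
  expect_equal(hb_altitude_correction(300), 0)
  alts <- seq(0, 4000, by = 50)
  corr <- hb_altitude_correction(alts)
  expect_true(all(diff(corr) >= 0))
  expect_gte(hb_altitude_correction(2000), hb_altitude_correction(1000))
  expect_error(adjust_hb_for_altitude(-1, 100), "positive")
})

test_that("the altitude correction matches a hand evaluation at 2500 m", {
  # independent arithmetic: A = 2500 m in thousands of feet, then the
  # quadratic -0.032 A + 0.022 A^2
  A <- 2500 * 3.28084 / 1000
  expected <- -0.032 * A + 0.022 * A^2
  expect_equal(adjust_hb_for_altitude(12.0, 2500), 12.0 - expected,
               tolerance = 1e-12)
})

test_that("anaemia classification uses a strict 11 g/dl threshold", {
  expect_equal(classify_anaemia(10.9), 1L)
  expect_equal(classify_anaemia(11.0), 0L)
  expect_equal(classify_anaemia(14.2), 0L)
  expect_error(classify_anaemia(NaN), "finite")
  # classification of stored outcomes is idempotent through the Hb path
  ds <- tiny_dataset(n = 300, seed = 8,
                     truth = true_model(hb_mode = "hb_threshold"))
  rec <- ds$records
  again <- classify_anaemia(adjust_hb_for_altitude(rec$hb, rec$altitude))
  expect_identical(again, rec$y)
})

test_that("record validation enforces closed level sets and ranges", {
  rec <- tiny_dataset(n = 60, seed = 2)$records
  bad <- rec
  bad$education[4] <- "tertiary"
  expect_error(validate_records(bad), "Row 4.*tertiary.*education")
  bad2 <- rec
  bad2$age_months[10] <- 70
  expect_error(validate_records(bad2), "Row 10")
  dropped <- validate_records(bad, action = "drop")
  expect_equal(nrow(dropped$records), 59)
  expect_equal(dropped$report$n, 1)
  no_y <- rec[setdiff(names(rec), c("y", "hb"))]
  expect_error(validate_records(no_y), "outcome")
})

test_that("the design matrix uses the study's reference coding", {
  rec <- tiny_dataset(n = 500, seed = 3)$records
  d <- encode_design(rec)
  X <- d$X
  # exact column count: intercept + sum(levels - 1) + continuous + interactions
  expect_equal(ncol(X), 1 + (1 + 1 + 1 + 3 + 1 + 3 + 3) + 5 + 3)
  expect_true("(Intercept)" %in% colnames(X))
  expect_true(all(X[, "(Intercept)"] == 1))
  # reference cell: urban Malawi rows have zero residence/country columns
  ref_rows <- which(rec$residence == "urban" & rec$country == "Malawi")
  cols <- grep("residence|country", colnames(X), value = TRUE)
  expect_true(all(X[ref_rows, cols] == 0))
  # a rural Kenyan child activates exactly its dummies and interaction
  rk <- which(rec$residence == "rural" & rec$country == "Kenya")[1]
  expect_equal(unname(X[rk, "residence_rural"]), 1)
  expect_equal(unname(X[rk, "country_Kenya"]), 1)
  expect_equal(unname(X[rk, "residence_rural:country_Kenya"]), 1)
  expect_equal(unname(X[rk, "residence_rural:country_Tanzania"]), 0)
  expect_equal(unname(X[rk, "residence_rural:country_Uganda"]), 0)
  # rescaled continuous covariates
  expect_equal(unname(X[, "altitude_100m"]), rec$altitude / 100)
  expect_equal(unname(X[, "evi_1000"]), rec$evi / 1000)
  # district indicators: one district per row
  expect_equal(length(d$district), nrow(rec))
  expect_error(
    encode_design(dplyr::mutate(rec, toilet = "longdrop")),
    "closed set"
  )
})

test_that("univariate screening has the right operating characteristics", {
  geo <- tiny_geography(40)
  base <- generate_cohort(geo, 5000, seed = 41)
  n_rep <- 100
  # type-I: an independent covariate is dropped in the vast majority of runs
  keep_null <- logical(n_rep)
  keep_signal <- logical(n_rep)
  withr::with_seed(42, {
    for (r in seq_len(n_rep)) {
      rec <- base
      rec$y <- rbinom(nrow(rec), 1, 0.5)
      rec$wealth_z <- rnorm(nrow(rec))
      keep_null[r] <- univariate_screen(rec, "wealth_z")$keep
      # power: a covariate with true log-odds slope 1
      rec2 <- base
      rec2$wealth_z <- rnorm(nrow(rec2))
      rec2$y <- rbinom(nrow(rec2), 1, plogis(rec2$wealth_z))
      keep_signal[r] <- univariate_screen(rec2, "wealth_z")$keep
    }
  })
  expect_gte(mean(!keep_null), 0.85)
  expect_gte(mean(keep_signal), 0.99)
})

test_that("screening edge cases and invariances hold", {
  rec <- tiny_dataset(n = 2000, seed = 50)$records
  # vacuous threshold keeps everything
  expect_true(univariate_screen(rec, "head_age", alpha = 1)$keep)
  # constant outcome is inestimable
  rec0 <- dplyr::mutate(rec, y = 1L)
  expect_error(univariate_screen(rec0, "gender"), "constant")
  # multi-level categoricals use the LR test with levels-1 df
  out <- univariate_screen(rec, "education")
  expect_equal(out$df, 3)
  expect_equal(out$test, "lr")
  # decisions are invariant to row order
  perm <- withr::with_seed(51, sample(nrow(rec)))
  expect_equal(univariate_screen(rec[perm, ], "wealth_z")$p_value,
               univariate_screen(rec, "wealth_z")$p_value, tolerance = 1e-10)
  # wald and lr agree closely on a single-column covariate at this n
  w <- univariate_screen(rec, "wealth_z", test = "wald")
  l <- univariate_screen(rec, "wealth_z", test = "lr")
  expect_equal(w$p_value, l$p_value, tolerance = 0.02)
  # a single fixed term yields no interaction pairs
  expect_equal(nrow(screen_interactions(rec, "gender")), 0)
})

test_that("interaction screening recovers a true residence-by-country interaction", {
  geo <- generate_geography(
    geography_config(districts_per_country = rep(10L, 4),
                     clusters_per_district = 8L), seed = 60
  )
  rec <- generate_cohort(geo, 20000, seed = 61)
  truth <- true_model(
    beta = c("(Intercept)" = -0.2, residence_rural = -0.3,
             country_Kenya = -0.5, country_Tanzania = 0.3,
             country_Uganda = -0.4,
             "residence_rural:country_Kenya" = 0.8,
             "residence_rural:country_Tanzania" = -0.6,
             "residence_rural:country_Uganda" = 0.7),
    f_age = function(a) 0 * a, f_spat = function(lon, lat) 0 * lon,
    sigma2_district = 0
  )
  ds <- simulate_outcomes(rec, truth, seed = 62)
  found <- screen_interactions(ds$records,
                               c("residence", "country", "gender"),
                               alpha = 0.05)
  hit <- found[found$term1 == "residence" & found$term2 == "country", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$significant)
  expect_equal(found$p_value[1], hit$p_value) # smallest p-value of all pairs
})

test_that("interaction screening has roughly nominal false-flag behaviour", {
  geo <- tiny_geography(70)
  n_rep <- 10
  alpha <- 0.10
  flags <- withr::with_seed(71, {
    vapply(seq_len(n_rep), function(r) {
      rec <- generate_cohort(geo, 4000, seed = 7100 + r)
      rec$y <- rbinom(nrow(rec), 1, 0.5)
      out <- suppressWarnings(
        screen_interactions(rec, c("residence", "country", "gender"), alpha)
      )
      sum(out$significant)
    }, numeric(1))
  })
  # 3 pairs at the 10% level: expect ~0.3 false flags per run on average
  expect_lte(mean(flags), 1.0)
})
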