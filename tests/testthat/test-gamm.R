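make_state <- function(n = 400, seed = 1, spec = small_spec(),
                       truth = true_model(), districts = 5L) {
  ds <- tiny_dataset(n = n, seed = seed, truth = truth,
                     districts = districts)
  design <- encode_design(ds$records, spec)
  age_rep <- reparameterize(spline_term(
    design$smooth_inputs[[spec$smooth]], n_segments = spec$smooth_segments,
    degree = spec$smooth_degree, order = spec$smooth_order
  ))
  spat_rep <- if (isTRUE(spec$spatial)) {
    reparameterize(tensor_term(design$smooth_inputs$lon,
                               design$smooth_inputs$lat,
                               n_segments = spec$spatial_segments))
  }
  list(state = assemble_model(design, age_rep, spat_rep), dataset = ds)
}

test_that("model assembly absorbs null spaces and checks rank", {
  ms <- make_state(n = 300, seed = 1)
  st <- ms$state
  # the order-2 age smooth contributes its linear null-space column to the
  # fixed block (the constant is carried by the intercept)
  expect_true("age_months_null1" %in% colnames(st$A)[seq_len(st$n_fixed)])
  expect_equal(sum(st$pen_map == ""), st$n_fixed)
  expect_true(all(c("tau2_age", "tau2_spatial") %in% unique(st$pen_map)))
  # no smooths and no spatial: reduces to a plain logistic design
  rec <- ms$dataset$records
  spec0 <- model_spec(linear = c("gender", "wealth_z"), smooth = NULL,
                      spatial = FALSE, interactions = list())
  st0 <- assemble_model(encode_design(rec, spec0))
  expect_equal(ncol(st0$A), 3)
  expect_true(all(st0$pen_map == ""))
  # duplicated column triggers the rank check with the column named
  d <- encode_design(rec, spec0)
  d$X <- cbind(d$X, gender_female2 = d$X[, "gender_female"])
  expect_error(assemble_model(d), "collinear")
  # fewer than two districts is rejected
  one <- dplyr::filter(rec, district_id == rec$district_id[1])
  expect_error(
    assemble_model(encode_design(one, spec0)),
    "at least 2 levels"
  )
})

test_that("the first working response at zero coefficients is 4(y - 1/2)", {
  y <- c(0, 1, 1, 0)
  wr <- anaemiagamm:::working_response(y, rep(0, 4))
  expect_equal(wr$z, 4 * (y - 0.5))
  expect_equal(wr$w, rep(0.25, 4))
})

test_that("each PIWLS step matches a dense Newton step on the full system", {
  ms <- make_state(n = 350, seed = 3)
  st <- ms$state
  theta <- list(tau2_age = 0.2, tau2_spatial = 0.4, sigma2_district = 0.3)
  parts <- dense_model_parts(st, theta)
  coefs <- NULL
  beta_dense <- numeric(ncol(parts$C))
  for (iter in 1:3) {
    coefs <- piwls_step(st, theta, coefs)
    beta_dense <- drop(dense_newton_step(st$y, parts$C, parts$Pmat,
                                         beta_dense))
    mine <- c(coefs$deltaA, coefs$u)
    expect_lt(max(abs(mine - beta_dense)), 1e-10)
  }
})

test_that("PIWLS at fixed variance components maximizes the penalized likelihood", {
  ms <- make_state(n = 400, seed = 4)
  st <- ms$state
  theta <- list(tau2_age = 0.3, tau2_spatial = 0.5, sigma2_district = 0.25)
  conv <- anaemiagamm:::piwls_run(st, theta)
  parts <- dense_model_parts(st, theta)
  oracle <- penalized_logistic_bfgs(st$y, parts$C, parts$Pmat,
                                    start = c(conv$deltaA, conv$u) * 0)
  expect_lt(max(abs(c(conv$deltaA, conv$u) - oracle)), 1e-6)
})

test_that("penalized deviance is monotone along accepted PIWLS iterations", {
  ms <- make_state(n = 500, seed = 5)
  theta <- list(tau2_age = 0.1, tau2_spatial = 0.1, sigma2_district = 0.1)
  conv <- anaemiagamm:::piwls_run(ms$state, theta)
  expect_true(all(diff(conv$pdev_trace) <= 1e-8))
})

test_that("infinite smoothing collapses the smooth onto its null space", {
  ms <- make_state(n = 400, seed = 6)
  st <- ms$state
  theta <- list(tau2_age = 1e-10, tau2_spatial = 1e-10,
                sigma2_district = 0.2)
  conv <- anaemiagamm:::piwls_run(st, theta)
  expect_lt(max(abs(conv$deltaA[st$pen_map != ""])), 1e-4)
  # the remaining fit is the parametric model: compare with glm on the
  # fixed block alone (district effects still shrunk, so compare the
  # penalized fit refitted without penalized columns)
  theta0 <- list(tau2_age = 1e-12, tau2_spatial = 1e-12,
                 sigma2_district = 0.2)
  conv0 <- anaemiagamm:::piwls_run(st, theta0, conv)
  keep <- st$pen_map == ""
  st_par <- st
  st_par$A <- st$A[, keep, drop = FALSE]
  st_par$pen_map <- st$pen_map[keep]
  conv_par <- anaemiagamm:::piwls_run(st_par, list(sigma2_district = 0.2))
  expect_lt(max(abs(conv0$deltaA[keep] - conv_par$deltaA)), 1e-4)
})

test_that("working-model REML matches the balanced one-way closed form", {
  # Gaussian analog with known unit residual variance: group means are
  # i.i.d. with variance sigma2_u + 1/n, whose REML estimate is the sample
  # variance of the group means (divisor H - 1) minus 1/n
  H <- 30L
  n_per <- 20L
  withr::with_seed(77, {
    u <- rnorm(H, 0, sqrt(0.5))
    y <- rep(u, each = n_per) + rnorm(H * n_per)
  })
  dist_idx <- rep(seq_len(H), each = n_per)
  A <- matrix(1, H * n_per, 1)
  bl <- anaemiagamm:::working_blocks(A, dist_idx, H, rep(1, H * n_per), y)
  crit <- function(s2) {
    anaemiagamm:::reml_criterion(bl, "", setNames(numeric(0), character(0)),
                                 list(sigma2_district = s2))
  }
  opt <- optimize(crit, c(1e-6, 5), tol = 1e-10)
  gm <- tapply(y, dist_idx, mean)
  closed <- max(0, var(gm) - 1 / n_per)
  expect_equal(opt$minimum, closed, tolerance = 1e-6)
})

test_that("REML is invariant to the lambda = 1/tau2 correspondence", {
  # doubling all penalties' lambda equals halving tau2: the criterion is a
  # function of tau2 only through 1/tau2 ridges plus log terms, so the two
  # parameterizations give identical values
  ms <- make_state(n = 300, seed = 8)
  st <- ms$state
  coefs <- anaemiagamm:::piwls_run(
    st, list(tau2_age = 0.2, tau2_spatial = 0.2, sigma2_district = 0.2)
  )
  eta <- drop(st$A %*% coefs$deltaA) + coefs$u[st$dist_idx]
  wr <- anaemiagamm:::working_response(st$y, eta)
  bl <- anaemiagamm:::working_blocks(st$A, st$dist_idx, st$H, wr$w, wr$z)
  pc <- table(st$pen_map[st$pen_map != ""])
  pc <- setNames(as.numeric(pc), names(pc))
  v1 <- anaemiagamm:::reml_criterion(
    bl, st$pen_map, pc,
    list(tau2_age = 0.5, tau2_spatial = 0.3, sigma2_district = 0.2)
  )
  v2 <- anaemiagamm:::reml_criterion(
    bl, st$pen_map, pc,
    list(tau2_age = 1 / (2 * (1 / 0.5)), tau2_spatial = 1 / (2 * (1 / 0.3)),
         sigma2_district = 0.2)
  )
  v1_half <- anaemiagamm:::reml_criterion(
    bl, st$pen_map, pc,
    list(tau2_age = 0.25, tau2_spatial = 0.15, sigma2_district = 0.2)
  )
  expect_equal(v2, v1_half, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("a zero-variance district effect is pushed to the boundary", {
  spec <- model_spec(linear = c("gender", "rdt_result", "wealth_z"),
                     smooth = NULL, spatial = FALSE, interactions = list())
  truth <- true_model(
    beta = c("(Intercept)" = 0.2, gender_female = -0.13,
             rdt_result_positive = 1.46, wealth_z = -0.17),
    f_age = function(a) 0 * a, f_spat = function(lon, lat) 0 * lon,
    sigma2_district = 0
  )
  n_rep <- 20
  at_boundary <- vapply(seq_len(n_rep), function(r) {
    ds <- tiny_dataset(n = 2000, seed = 900 + 7 * r, truth = truth)
    fit <- fit_anaemia_gamm(ds$records, spec)
    fit$theta$sigma2_district < 0.01
  }, logical(1))
  expect_gt(mean(at_boundary), 0.5)
})

test_that("refitting the identical dataset is bit-identical", {
  ds <- tiny_dataset(n = 900, seed = 10)
  f1 <- fit_anaemia_gamm(ds$records, small_spec())
  f2 <- fit_anaemia_gamm(ds$records, small_spec())
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$blups$blup, f2$blups$blup)
})

test_that("complete separation is reported with the offending covariate", {
  ds <- tiny_dataset(n = 400, seed = 11)
  rec <- ds$records
  rec$y <- as.integer(rec$gender == "female")
  spec <- model_spec(linear = c("gender", "wealth_z"), smooth = NULL,
                     spatial = FALSE, interactions = list())
  expect_error(fit_anaemia_gamm(rec, spec), class = "anaemiagamm_separation")
})

test_that("odds-ratio reporting is a closed-form transform of the fit", {
  ds <- tiny_dataset(n = 1200, seed = 12)
  fit <- fit_anaemia_gamm(ds$records, small_spec())
  td <- tidy(fit, exponentiate = FALSE)
  tab <- aor_table(fit)
  joined <- dplyr::inner_join(
    tab, td[, c("term", "estimate", "std.error")], by = "term"
  )
  z <- qnorm(0.975)
  expect_equal(joined$aor, exp(joined$estimate), tolerance = 1e-10)
  expect_equal(joined$conf.low, exp(joined$estimate - z * joined$std.error),
               tolerance = 1e-10)
  expect_equal(joined$conf.high, exp(joined$estimate + z * joined$std.error),
               tolerance = 1e-10)
  # the significance star is exactly "CI excludes 1"
  expect_equal(tab$significant, tab$conf.low > 1 | tab$conf.high < 1)
  # interactions are reported after the main effects
  expect_true(all(diff(match(
    dplyr::inner_join(tab, fit$column_map[, c("column", "role")],
                      by = c(term = "column"))$role,
    c("parametric", "interaction")
  )) >= 0))
  # a null coefficient with SE 0.1 has the textbook Wald interval
  fake <- fit
  fake$coefficients["wealth_z"] <- 0
  fake$cov["wealth_z", "wealth_z"] <- 0.1^2
  row <- aor_table(fake)
  row <- row[row$term == "wealth_z", ]
  expect_equal(row$aor, 1)
  expect_equal(row$conf.low, exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(row$conf.high, exp(qnorm(0.975) * 0.1), tolerance = 1e-12)
})

test_that("the fitted smooth is centered and evaluation is linear", {
  ds <- tiny_dataset(n = 1500, seed = 13)
  fit <- fit_anaemia_gamm(ds$records, small_spec())
  obs_curve <- smooth_curve(fit, grid = ds$records$age_months)
  expect_lt(abs(mean(obs_curve$estimate)), 1e-8)
  # evaluation at arbitrary points is the basis-row dot product with the
  # fitted coefficients
  rows <- anaemiagamm:::smooth_rows(fit, "age", z = c(12, 30, 48))
  direct <- drop(rows$L %*% fit$coefficients[rows$cols])
  expect_equal(smooth_curve(fit, grid = c(12, 30, 48))$estimate, direct,
               tolerance = 1e-10)
  expect_error(smooth_curve(fit, grid = c(4, 30)), "outside")
  # the spatial surface evaluates linearly at the fitted clusters too
  surf <- spatial_surface(fit)
  rows_s <- anaemiagamm:::smooth_rows(fit, "spatial", lon = surf$lon,
                                      lat = surf$lat)
  expect_equal(surf$estimate, drop(rows_s$L %*% fit$coefficients[rows_s$cols]),
               tolerance = 1e-10)
})

test_that("the age-smooth band narrows with n and the peak is recovered", {
  spec <- model_spec(spatial = FALSE, interactions = list(),
                     linear = c("gender", "rdt_result", "wealth_z"))
  truth <- true_model(
    beta = c("(Intercept)" = 0.1, gender_female = -0.13,
             rdt_result_positive = 1.46, wealth_z = -0.17),
    # a pronounced, well-resolved single bump peaking at 10 months
    f_age = function(a) 1.2 * exp(-(a - 10)^2 / 18),
    f_spat = function(lon, lat) 0 * lon, sigma2_district = 0.05
  )
  geo <- tiny_geography(14, districts = 10L)
  small <- simulate_outcomes(generate_cohort(geo, 2000, seed = 15),
                             truth, seed = 16)
  large <- simulate_outcomes(generate_cohort(geo, 20000, seed = 17),
                             truth, seed = 18)
  grid <- seq(8, 56, by = 2)
  f_small <- fit_anaemia_gamm(small$records, spec)
  f_large <- fit_anaemia_gamm(large$records, spec)
  c_small <- smooth_curve(f_small, grid = grid)
  c_large <- smooth_curve(f_large, grid = grid)
  expect_true(all(c_large$std.error < c_small$std.error))
  # the default truth peaks near 10 months; the estimate localizes it
  fine <- seq(6, 59, by = 0.25)
  est <- smooth_curve(f_large, grid = fine)
  true_peak <- fine[which.max(truth$f_age(fine))]
  est_peak <- fine[which.max(est$estimate)]
  expect_lte(abs(est_peak - true_peak), 3)
})

test_that("dropping an absent spatial term barely moves the fixed effects", {
  # a fully null spatial truth: no surface and no district heterogeneity
  # (with district variance active, country dummies and a free surface are
  # genuinely confounded, which is a property of the model, not the code)
  truth <- true_model(f_spat = function(lon, lat) 0 * lon,
                      sigma2_district = 0)
  ds <- tiny_dataset(n = 20000, seed = 19, truth = truth, districts = 10L)
  with_sp <- fit_anaemia_gamm(ds$records, small_spec())
  no_sp <- fit_anaemia_gamm(ds$records, small_spec(spatial = FALSE))
  t1 <- tidy(with_sp, exponentiate = FALSE)
  t2 <- tidy(no_sp, exponentiate = FALSE)
  j <- dplyr::inner_join(t1, t2, by = "term")
  expect_lt(max(abs(j$estimate.x - j$estimate.y)), 0.05)
})

test_that("total residence-by-country effects sum the right coefficients", {
  ds <- tiny_dataset(n = 1500, seed = 20)
  fit <- fit_anaemia_gamm(ds$records, small_spec())
  cells <- total_residence_country_effects(fit)
  ref <- cells[cells$residence == "urban" & cells$country == "Malawi", ]
  expect_equal(ref$total_log_odds, 0)
  expect_equal(ref$std.error, 0)
  rk <- cells[cells$residence == "rural" & cells$country == "Kenya", ]
  b <- fit$coefficients
  expect_equal(
    rk$total_log_odds,
    unname(b["residence_rural"] + b["country_Kenya"] +
             b["residence_rural:country_Kenya"]),
    tolerance = 1e-12
  )
  # fixture check with published-style odds ratios as inputs: the rural
  # Kenya cell is the log-sum of the three printed AORs
  fake <- fit
  fake$coefficients["residence_rural"] <- log(0.738)
  fake$coefficients["country_Kenya"] <- log(0.316)
  fake$coefficients["residence_rural:country_Kenya"] <- log(1.376)
  cells2 <- total_residence_country_effects(fake)
  rk2 <- cells2[cells2$residence == "rural" & cells2$country == "Kenya", ]
  expect_equal(rk2$total_log_odds, log(0.738) + log(0.316) + log(1.376),
               tolerance = 1e-12)
  expect_equal(round(rk2$total_log_odds, 3), -1.137)
  # without the interaction the helper refuses
  no_int <- fit_anaemia_gamm(
    ds$records, small_spec(interactions = list())
  )
  expect_error(total_residence_country_effects(no_int), "interaction")
})

test_that("the fit agrees with an independent GAMM implementation", {
  skip_if_not_installed("mgcv")
  truth <- true_model(sigma2_district = 0.1)
  ds <- tiny_dataset(n = 4000, seed = 21, truth = truth, districts = 8L)
  fit <- fit_anaemia_gamm(ds$records, small_spec())
  rec <- ds$records
  rec$district <- factor(rec$district_id)
  rec$female <- as.numeric(rec$gender == "female")
  rec$rdt_pos <- as.numeric(rec$rdt_result == "positive")
  g <- mgcv::gam(
    y ~ female + rdt_pos + s(age_months, bs = "ps", k = 10) +
      te(lon, lat, bs = "ps", k = c(6, 6)) + s(district, bs = "re"),
    family = binomial(), data = rec, method = "REML"
  )
  expect_lt(abs(coef(g)[["female"]] -
                  tidy(fit, exponentiate = FALSE) |>
                  dplyr::filter(term == "gender_female") |>
                  dplyr::pull(estimate)), 0.1)
  expect_lt(abs(coef(g)[["rdt_pos"]] -
                  tidy(fit, exponentiate = FALSE) |>
                  dplyr::filter(term == "rdt_result_positive") |>
                  dplyr::pull(estimate)), 0.1)
})
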