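#' Parameter-recovery simulation study
#'
#' Repeatedly simulates cohorts from the default true model (female effect
#' log(0.876), malaria-RDT effect log(4.315), district variance 0.15,
#' nonlinear age effect and smooth spatial surface all active), fits the
#' full additive mixed model, and collects the estimates of the female and
#' malaria log-odds coefficients and of the district variance, together
#' with Wald confidence-interval coverage indicators.
#'
#' @param n_reps Number of replicates.
#' @param n_children Cohort size per replicate.
#' @param districts_per_country Districts per country (4 countries).
#' @param clusters_per_district Clusters per district.
#' @param spatial_segments Marginal segments of the fitted spatial basis.
#' @param seed Base seed; each replicate derives its own sub-seed.
#' @return A list: `reps` (tibble with one row per replicate), `truth`
#'   (named true values) and `summary` (means, Monte-Carlo SEs, CI
#'   coverage).
#' @export
recovery_study <- function(n_reps = 25, n_children = 50000,
                           districts_per_country = 50L,
                           clusters_per_district = 2L,
                           spatial_segments = 6, seed = 1L) {
  gc <- geography_config(
    districts_per_country = rep(districts_per_country, 4L),
    clusters_per_district = clusters_per_district
  )
  truth <- c(beta_female = log(0.876), beta_malaria = log(4.315),
             sigma2_district = 0.15)
  spec <- model_spec(spatial_segments = spatial_segments)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    ds <- simulate_anaemia_data(
      n_children = n_children, geography_config = gc,
      truth = true_model(sigma2_district = truth[["sigma2_district"]]),
      seed = child_seed(seed, 1000 + r)
    )
    fit <- fit_anaemia_gamm(ds$records, spec)
    td <- tidy(fit, exponentiate = FALSE)
    row <- function(term) td[td$term == term, ]
    f <- row("gender_female")
    m <- row("rdt_result_positive")
    tibble::tibble(
      rep = r,
      beta_female = f$estimate, se_female = f$std.error,
      beta_malaria = m$estimate, se_malaria = m$std.error,
      sigma2_district = fit$theta$sigma2_district,
      cover_female = f$conf.low <= truth[["beta_female"]] &
        truth[["beta_female"]] <= f$conf.high,
      cover_malaria = m$conf.low <= truth[["beta_malaria"]] &
        truth[["beta_malaria"]] <= m$conf.high
    )
  })
  summary <- tibble::tibble(
    parameter = c("beta_female", "beta_malaria", "sigma2_district"),
    truth = unname(truth),
    mean = c(mean(reps$beta_female), mean(reps$beta_malaria),
             mean(reps$sigma2_district)),
    mc_se = c(sd(reps$beta_female), sd(reps$beta_malaria),
              sd(reps$sigma2_district)) / sqrt(n_reps),
    coverage = c(mean(reps$cover_female), mean(reps$cover_malaria), NA)
  )
  list(reps = reps, truth = truth, summary = summary)
}

#' BLUP ranking-recovery simulation study
#'
#' Simulates cohorts with a strong district signal, fits the model, ranks
#' districts by standardized BLUP and measures Kendall's tau between the
#' estimated and the true district-effect rankings.
#'
#' @param n_reps Number of replicates.
#' @param children_per_district Children per district.
#' @param districts_per_country Districts per country (4 countries).
#' @param sigma2_district True district variance (large by default so the
#'   ranking signal is strong).
#' @param spatial_segments Marginal segments of the fitted spatial basis.
#' @param seed Base seed.
#' @return A list: `reps` (tibble with `rep`, `kendall_tau`,
#'   `top_bottom_disjoint`) and `mean_tau`.
#' @export
ranking_study <- function(n_reps = 25, children_per_district = 250L,
                          districts_per_country = 10L,
                          sigma2_district = 1.0,
                          spatial_segments = 3, seed = 1L) {
  gc <- geography_config(
    districts_per_country = rep(districts_per_country, 4L),
    clusters_per_district = 4L
  )
  n_children <- children_per_district * 4L * districts_per_country
  spec <- model_spec(spatial_segments = spatial_segments)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    ds <- simulate_anaemia_data(
      n_children = n_children, geography_config = gc,
      truth = true_model(sigma2_district = sigma2_district),
      seed = child_seed(seed, 2000 + r)
    )
    fit <- fit_anaemia_gamm(ds$records, spec)
    app <- appraise_districts(fit, k = 3)
    joined <- dplyr::inner_join(app, ds$district_effects, by = "district_id")
    best <- joined$district_id[!is.na(joined$flag) & joined$flag == "best"]
    worst <- joined$district_id[!is.na(joined$flag) & joined$flag == "worst"]
    # tau is measured within country and averaged, matching the scope of
    # the ranking itself: district appraisal is a per-country league
    # table, and cross-country level differences are carried by the
    # country fixed effects, not by the BLUPs
    tau_by_country <- vapply(
      split(joined, joined$country),
      function(d) cor(d$standardized, d$u, method = "kendall"),
      numeric(1)
    )
    tibble::tibble(
      rep = r,
      kendall_tau = mean(tau_by_country),
      top_bottom_disjoint = length(intersect(best, worst)) == 0
    )
  })
  list(reps = reps, mean_tau = mean(reps$kendall_tau))
}

#' Null-model sanity study
#'
#' Simulates cohorts whose truth has no spatial surface and no district
#' heterogeneity (`f_spat = 0`, `sigma2_district = 0`) while the fixed and
#' age effects stay active, fits the full model, and records the largest
#' absolute fitted spatial effect over the clusters and whether the
#' district variance was estimated at the boundary.
#'
#' @param n_reps Number of replicates.
#' @param n_children Cohort size per replicate.
#' @param spatial_segments Marginal segments of the fitted spatial basis.
#' @param seed Base seed.
#' @return A tibble: `rep`, `max_abs_surface`, `sigma2_district`,
#'   `sigma2_at_boundary`.
#' @export
null_surface_study <- function(n_reps = 5, n_children = 20000,
                               spatial_segments = 6, seed = 1L) {
  gc <- geography_config(clusters_per_district = 4L)
  truth <- true_model(
    f_spat = function(lon, lat) 0 * lon,
    sigma2_district = 0
  )
  spec <- model_spec(spatial_segments = spatial_segments)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    ds <- simulate_anaemia_data(
      n_children = n_children, geography_config = gc, truth = truth,
      seed = child_seed(seed, 3000 + r)
    )
    fit <- fit_anaemia_gamm(ds$records, spec)
    surf <- spatial_surface(fit)
    tibble::tibble(
      rep = r,
      max_abs_surface = max(abs(surf$estimate)),
      sigma2_district = fit$theta$sigma2_district,
      sigma2_at_boundary = fit$theta$sigma2_district < 0.01
    )
  })
}
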