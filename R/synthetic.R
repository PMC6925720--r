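#' Covariate marginals for the synthetic cohort
#'
#' Marginal distributions used by [generate_cohort()]. Defaults are chosen
#' as plausible for under-five household-survey populations in the study
#' region and are freely overridable; they are conveniences for simulation,
#' not survey estimates.
#'
#' @param p_female Probability a child is female.
#' @param p_rdt_positive Probability of a positive malaria RDT.
#' @param education_probs Named probabilities over mother's education levels
#'   `none`, `primary`, `secondary_higher`, `unknown`.
#' @param toilet_probs Named probabilities over toilet-facility levels
#'   `none`, `pit`, `flush`, `other`.
#' @param p_head_female Probability the household head is female.
#' @param head_age_mean,head_age_sd,head_age_range Household-head age (years).
#' @param household_size_lambda Household size is `1 + Poisson(lambda)`.
#' @param p_sibling Probability a child shares the previous child's
#'   household within the cluster.
#' @param wealth_sd SD of the household wealth index Z-score (mean 0).
#' @param altitude_range Cluster altitude range (metres).
#' @param evi_range Cluster Enhanced Vegetation Index range (raw units;
#'   entered in the model per 1000).
#' @param lst_range Cluster day land-surface temperature range (deg C).
#' @return An object of class `covariate_config`.
#' @export
covariate_config <- function(p_female = 0.5,
                             p_rdt_positive = 0.25,
                             education_probs = c(none = 0.25, primary = 0.45,
                                                 secondary_higher = 0.20,
                                                 unknown = 0.10),
                             toilet_probs = c(none = 0.30, pit = 0.50,
                                              flush = 0.15, other = 0.05),
                             p_head_female = 0.30,
                             head_age_mean = 45, head_age_sd = 12,
                             head_age_range = c(18, 95),
                             household_size_lambda = 4,
                             p_sibling = 0.25,
                             wealth_sd = 1,
                             altitude_range = c(0, 2000),
                             evi_range = c(1000, 6000),
                             lst_range = c(20, 40)) {
  probs <- c(p_female, p_rdt_positive, p_head_female, p_sibling)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (abs(sum(education_probs) - 1) > 1e-8 || abs(sum(toilet_probs) - 1) > 1e-8) {
    abort("`education_probs` and `toilet_probs` must each sum to 1.")
  }
  structure(as.list(environment()), class = "covariate_config")
}

#' Generate a synthetic child cohort
#'
#' Draws `n_children` child records on a [generate_geography()] skeleton:
#' children are assigned uniformly to clusters, grouped into households
#' within clusters, and given the full covariate set (gender, age 6-59
#' months, malaria RDT result, mother's education, household size, wealth
#' Z-score, toilet facility, head-of-household age and gender) plus
#' cluster-level covariates (altitude, EVI, LST) that are constant within a
#' cluster. Outcomes are added separately by [simulate_outcomes()].
#'
#' @param geography A `geography` object.
#' @param n_children Number of children (>= 1).
#' @param config A [covariate_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per child.
#' @export
generate_cohort <- function(geography, n_children,
                            config = covariate_config(), seed = 1L) {
  if (!inherits(geography, "geography")) abort("`geography` must come from generate_geography().")
  if (!inherits(config, "covariate_config")) abort("`config` must come from covariate_config().")
  if (!is_scalar_number(n_children) || n_children < 1) {
    abort("`n_children` must be a positive integer.")
  }
  cl <- geography$clusters
  if (nrow(cl) == 0) abort("Geography has zero clusters.")
  n <- as.integer(n_children)
  local_seed(seed, {
    idx <- sort(sample.int(nrow(cl), n, replace = TRUE))
    rec <- cl[idx, c("country", "district_id", "cluster_id", "lon", "lat",
                     "residence")]
    # cluster-level environmental covariates, one draw per cluster
    env <- tibble::tibble(
      cluster_id = cl$cluster_id,
      altitude = runif(nrow(cl), config$altitude_range[1], config$altitude_range[2]),
      evi = runif(nrow(cl), config$evi_range[1], config$evi_range[2]),
      lst = runif(nrow(cl), config$lst_range[1], config$lst_range[2])
    )
    rec <- dplyr::left_join(rec, env, by = "cluster_id")
    # household grouping: a child joins the previous child's household with
    # probability p_sibling, else starts a new household in the cluster
    new_hh <- runif(n) >= config$p_sibling
    first_in_cluster <- !duplicated(rec$cluster_id)
    new_hh[first_in_cluster] <- TRUE
    hh_num <- stats::ave(as.numeric(new_hh), rec$cluster_id, FUN = cumsum)
    rec$household_id <- sprintf("%s_h%04d", rec$cluster_id, as.integer(hh_num))
    # household-level covariates, one draw per household
    hh <- rec |>
      dplyr::distinct(.data$household_id) |>
      dplyr::mutate(
        household_size = 1L + rpois(dplyr::n(), config$household_size_lambda),
        wealth_z = rnorm(dplyr::n(), 0, config$wealth_sd),
        toilet = sample(names(config$toilet_probs), dplyr::n(),
                        replace = TRUE, prob = config$toilet_probs),
        head_gender = ifelse(runif(dplyr::n()) < config$p_head_female,
                             "female", "male"),
        head_age = pmin(pmax(rnorm(dplyr::n(), config$head_age_mean,
                                   config$head_age_sd),
                             config$head_age_range[1]),
                        config$head_age_range[2]),
        education = sample(names(config$education_probs), dplyr::n(),
                           replace = TRUE, prob = config$education_probs)
      )
    rec <- dplyr::left_join(rec, hh, by = "household_id")
    rec |>
      dplyr::mutate(
        child_id = sprintf("%s_k%02d", .data$household_id,
                           stats::ave(rep(1, n), .data$household_id,
                                      FUN = cumsum)),
        gender = ifelse(runif(n) < config$p_female, "female", "male"),
        age_months = sample(6:59, n, replace = TRUE),
        rdt_result = ifelse(runif(n) < config$p_rdt_positive,
                            "positive", "negative")
      ) |>
      dplyr::relocate("child_id", "household_id", "cluster_id", "district_id",
                      "country") |>
      tibble::as_tibble()
  })
}

#' Define the true data-generating model
#'
#' The known truth used for forward simulation: linear fixed effects on the
#' log-odds scale (named by design-matrix column, see [encode_design()]),
#' a true nonlinear age effect, a true spatial surface over (lon, lat),
#' and the district random-effect variance. Outcomes can be drawn directly
#' as Bernoulli from the model probabilities, or via a latent haemoglobin
#' value that is thresholded at 11 g/dl after altitude adjustment.
#'
#' @param beta Named numeric vector of log-odds coefficients; names must
#'   match design columns (`"(Intercept)"`, `"gender_female"`, ...). Columns
#'   not named carry a zero effect.
#' @param f_age Function of age in months giving the true nonlinear age
#'   effect (log-odds scale).
#' @param f_spat Function `(lon, lat)` giving the true spatial surface.
#' @param sigma2_district Variance of the i.i.d. district effect (>= 0).
#' @param hb_mode `"direct"` (Bernoulli draw from the model probability) or
#'   `"hb_threshold"` (draw a continuous Hb and dichotomize).
#' @param hb_noise_sd SD (g/dl) of the latent Hb around the threshold in
#'   `"hb_threshold"` mode; as it shrinks the two modes agree in prevalence.
#' @return An object of class `true_model`.
#' @export
true_model <- function(beta = default_true_beta(),
                       f_age = default_f_age,
                       f_spat = default_f_spat,
                       sigma2_district = 0.15,
                       hb_mode = c("direct", "hb_threshold"),
                       hb_noise_sd = 1.0) {
  hb_mode <- match.arg(hb_mode)
  if (!is_scalar_number(sigma2_district) || sigma2_district < 0) {
    abort("`sigma2_district` must be nonnegative.")
  }
  if (!is_scalar_number(hb_noise_sd) || hb_noise_sd <= 0) {
    abort("`hb_noise_sd` must be positive.")
  }
  if (is.null(names(beta)) && length(beta) > 0) abort("`beta` must be named.")
  if (!is.function(f_age) || !is.function(f_spat)) {
    abort("`f_age` and `f_spat` must be functions.")
  }
  structure(
    list(beta = beta, f_age = f_age, f_spat = f_spat,
         sigma2_district = sigma2_district, hb_mode = hb_mode,
         hb_noise_sd = hb_noise_sd),
    class = "true_model"
  )
}

#' Default true fixed effects for simulation
#'
#' Log-odds coefficients informed by adjusted odds ratios typical of
#' childhood-anaemia risk-factor studies in the region (e.g. a strong
#' positive malaria-RDT effect and a modest protective female effect). The
#' intercept is set so overall prevalence lands near one half.
#'
#' @return A named numeric vector.
#' @export
default_true_beta <- function() {
  c(
    "(Intercept)" = 0.40,
    gender_female = log(0.876),
    rdt_result_positive = log(4.315),
    household_size = log(1.014),
    residence_rural = log(0.738),
    education_primary = log(0.843),
    education_secondary_higher = log(0.794),
    education_unknown = log(0.845),
    head_gender_female = log(1.016),
    toilet_pit = log(0.780),
    toilet_flush = log(0.725),
    toilet_other = log(0.663),
    wealth_z = log(0.847),
    country_Kenya = log(0.316),
    country_Tanzania = log(0.639),
    country_Uganda = log(0.433),
    altitude_100m = log(0.986),
    evi_1000 = log(1.026),
    lst = log(1.015),
    "residence_rural:country_Kenya" = log(1.376),
    "residence_rural:country_Tanzania" = log(1.237),
    "residence_rural:country_Uganda" = log(1.119)
  )
}

#' Default true age effect
#'
#' A single-bump curve: the effect rises from 6 months to a peak near 10
#' months, then declines and turns protective from roughly 25 months.
#'
#' @param age Age in months.
#' @export
default_f_age <- function(age) {
  0.5 * exp(-(age - 10)^2 / 50) - 0.01 * (age - 10) - 0.15
}

#' Default true spatial surface
#'
#' A smooth bivariate surface over the study window: a positive bump near
#' the Lake Victoria region and a negative bump to the south-east, so
#' spatial recovery is visually and numerically checkable.
#'
#' @param lon,lat Coordinates in degrees.
#' @export
default_f_spat <- function(lon, lat) {
  0.9 * exp(-((lon - 33)^2 + (lat + 1)^2) / (2 * 3^2)) -
    0.7 * exp(-((lon - 38)^2 + (lat + 8)^2) / (2 * 3.5^2))
}

#' Simulate anaemia outcomes on a cohort
#'
#' Draws district effects `U_h ~ N(0, sigma2_district)` (one per district),
#' forms the linear predictor `x'beta + f_age(age) + f_spat(lon, lat) +
#' U_h`, and draws each child's outcome. In `"direct"` mode the outcome is
#' Bernoulli with probability `plogis(eta)`; in `"hb_threshold"` mode a
#' continuous altitude-adjusted Hb is drawn so that the probability of
#' falling below 11 g/dl equals `plogis(eta)`, the outcome is the
#' threshold classification, and the stored raw `hb` back-adds the altitude
#' correction so that [adjust_hb_for_altitude()] plus [classify_anaemia()]
#' reproduce the stored outcome.
#'
#' @param records Cohort tibble from [generate_cohort()].
#' @param truth A [true_model()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: a list with `records`
#'   (the cohort plus `y`, `hb`, `true_eta`, `true_pi`), `truth`,
#'   `district_effects` (tibble of true `u` per district) and `seed`.
#' @export
simulate_outcomes <- function(records, truth = true_model(), seed = 1L) {
  stop_not_df(records)
  if (nrow(records) == 0) abort("`records` is empty.")
  if (!inherits(truth, "true_model")) abort("`truth` must come from true_model().")
  local_seed(seed, {
    districts <- sort(unique(records$district_id))
    u <- rnorm(length(districts), 0, sqrt(truth$sigma2_district))
    if (truth$sigma2_district == 0) u <- rep(0, length(districts))
    names(u) <- districts
    eta_fixed <- true_fixed_predictor(records, truth$beta)
    eta <- eta_fixed + truth$f_age(records$age_months) +
      truth$f_spat(records$lon, records$lat) + u[records$district_id]
    bad <- which(!is.finite(eta))
    if (length(bad)) {
      abort(sprintf("Non-finite linear predictor for record %s.",
                    records$child_id[bad[1]] %||% bad[1]))
    }
    prob <- plogis(eta)
    if (truth$hb_mode == "direct") {
      y <- rbinom(nrow(records), 1L, prob)
      hb <- rep(NA_real_, nrow(records))
    } else {
      scale <- truth$hb_noise_sd * sqrt(3) / pi
      hb_adj <- 11 - scale * (eta - rlogis(nrow(records)))
      hb_adj <- pmin(pmax(hb_adj, 1), 25)
      y <- classify_anaemia(hb_adj)
      hb <- hb_adj + hb_altitude_correction(records$altitude)
    }
    out <- records
    out$y <- as.integer(y)
    out$hb <- hb
    out$true_eta <- eta
    out$true_pi <- prob
    structure(
      list(
        records = tibble::as_tibble(out), truth = truth,
        district_effects = tibble::tibble(district_id = districts, u = unname(u)),
        seed = as.integer(seed)
      ),
      class = "synthetic_dataset"
    )
  })
}

# Fixed-effect part of the true predictor: encode the default design and
# apply the named true coefficients (unnamed columns carry zero effect).
true_fixed_predictor <- function(records, beta) {
  if (length(beta) == 0) return(rep(0, nrow(records)))
  design <- encode_design(records, model_spec(), require_outcome = FALSE)
  X <- design$X
  missing_cols <- setdiff(names(beta), colnames(X))
  if (length(missing_cols)) {
    abort(paste0("True-model coefficients with no matching design column: ",
                 paste(missing_cols, collapse = ", ")))
  }
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' One-shot synthetic dataset
#'
#' Convenience wrapper: [generate_geography()] + [generate_cohort()] +
#' [simulate_outcomes()] with sub-seeds derived from `seed`.
#'
#' @param n_children Cohort size.
#' @param geography_config Geography configuration.
#' @param truth A [true_model()].
#' @param covariates A [covariate_config()].
#' @param seed Integer seed.
#' @return A `synthetic_dataset` (with the geography attached as
#'   `$geography`).
#' @export
simulate_anaemia_data <- function(n_children = 8000,
                                  geography_config = anaemiagamm::geography_config(),
                                  truth = true_model(),
                                  covariates = covariate_config(),
                                  seed = 1L) {
  geo <- generate_geography(geography_config, child_seed(seed, 1))
  cohort <- generate_cohort(geo, n_children, covariates, child_seed(seed, 2))
  ds <- simulate_outcomes(cohort, truth, child_seed(seed, 3))
  ds$geography <- geo
  ds$seed <- as.integer(seed)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d children, %d districts, prevalence %.3f (seed %d)\n",
    nrow(x$records), length(unique(x$records$district_id)),
    mean(x$records$y), x$seed
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the child records as CSV, the cluster points as GeoJSON, and a
#' JSON sidecar holding the seed, the true coefficients and the true
#' district effects.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_dataset")) {
    abort("`dataset` must be a synthetic_dataset.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    records = file.path(dir, "records.csv"),
    clusters = file.path(dir, "clusters.geojson"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(dataset$records, paths[["records"]])
  clusters <- dataset$records |>
    dplyr::distinct(.data$cluster_id, .data$district_id, .data$country,
                    .data$lon, .data$lat, .data$residence)
  write_geojson_points(clusters, paths[["clusters"]],
                       props = c("cluster_id", "district_id", "country",
                                 "residence"))
  truth_out <- list(
    seed = dataset$seed,
    beta = as.list(dataset$truth$beta),
    sigma2_district = dataset$truth$sigma2_district,
    hb_mode = dataset$truth$hb_mode,
    district_effects = dataset$district_effects
  )
  jsonlite::write_json(truth_out, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
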