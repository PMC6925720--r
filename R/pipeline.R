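#' Pipeline configuration
#'
#' One configuration object for the end-to-end run: simulate (or read) a
#' cohort, screen covariates, fit the model, appraise districts, export
#' artifacts. The resolved configuration is archived next to the outputs so
#' every run can be regenerated.
#'
#' @param seed Integer seed driving every random stage.
#' @param mode `"synthetic"` (generate data) or `"file"` (read
#'   `data_path`).
#' @param data_path CSV of child records when `mode = "file"`.
#' @param n_children Cohort size in synthetic mode.
#' @param geography A [geography_config()].
#' @param truth A [true_model()] (synthetic mode).
#' @param covariates A [covariate_config()] (synthetic mode).
#' @param model A [model_spec()]; required.
#' @param control A [gamm_control()].
#' @param screen Run the univariate and interaction screens and drop
#'   non-significant candidate covariates before fitting?
#' @param candidates Covariates subjected to the univariate screen (the
#'   age of the household head is screened on the same footing as the
#'   rest).
#' @param appraisal_k,appraisal_method,appraisal_within District appraisal
#'   options, see [appraise_districts()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            mode = c("synthetic", "file"),
                            data_path = NULL,
                            n_children = 8000,
                            geography = geography_config(),
                            truth = true_model(),
                            covariates = covariate_config(),
                            model = model_spec(),
                            control = gamm_control(),
                            screen = TRUE,
                            candidates = c("gender", "rdt_result",
                                           "household_size", "residence",
                                           "education", "head_gender",
                                           "toilet", "wealth_z", "country",
                                           "altitude", "evi", "lst",
                                           "head_age"),
                            appraisal_k = 3,
                            appraisal_method = "se",
                            appraisal_within = "country") {
  mode <- match.arg(mode)
  if (is.null(model) || !inherits(model, "model_spec")) {
    abort("`model` must be a model_spec(); the pipeline cannot run without one.")
  }
  if (mode == "file" && (is.null(data_path) || !file.exists(data_path))) {
    abort("`data_path` must point to an existing CSV in file mode.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Cohort composition summary
#'
#' Per-country child counts, percentage shares (half-up rounding to one
#' decimal) and observed anaemia prevalence, with an overall row appended.
#'
#' @param records Child records with `country` and (optionally) `y`.
#' @return A tibble: `country`, `n`, `share_pct`, `prevalence`; the last
#'   row (`country = "overall"`) summarizes the pooled cohort.
#' @export
summarize_cohort <- function(records) {
  stop_not_df(records, "records")
  if (nrow(records) == 0) abort("`records` is empty.")
  has_y <- "y" %in% names(records)
  by_country <- records |>
    dplyr::count(.data$country, name = "n") |>
    dplyr::mutate(
      share_pct = round_half_up(100 * .data$n / sum(.data$n), 1),
      prevalence = if (has_y) {
        purrr::map_dbl(.data$country,
                       ~ mean(records$y[records$country == .x]))
      } else {
        NA_real_
      }
    )
  overall <- tibble::tibble(
    country = "overall", n = nrow(records), share_pct = 100,
    prevalence = if (has_y) mean(records$y) else NA_real_
  )
  dplyr::bind_rows(by_country, overall)
}

# Minimal GeoJSON point-feature writer.
write_geojson_points <- function(df, path, props = character(0)) {
  features <- purrr::map(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df$lon[i], df$lat[i])),
      properties = as.list(df[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Run the full pipeline
#'
#' Orchestrates generate (or load) -> summarize -> screen -> fit ->
#' appraise and writes every artifact into `dir`: the dataset snapshot and
#' cluster GeoJSON, the cohort summary, the screening reports, the fit
#' summary JSON, the AOR table, the variance components, the age-smooth
#' grid, the spatial-surface CSV, the district appraisal CSV and GeoJSON,
#' the resolved configuration and a structured stage log. Reruns with the
#' same configuration and seed regenerate identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the fit, the appraisal, the screening
#'   tables and the paths written.
#' @export
run_pipeline <- function(config, dir) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stage_log <- list()
  log_stage <- function(stage, message) {
    stage_log[[length(stage_log) + 1]] <<- tibble::tibble(
      stage = stage, message = message, time = format(Sys.time(), "%H:%M:%S")
    )
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                    conditionMessage(e)),
            class = "anaemiagamm_pipeline_error", parent = e)
    })
  }
  paths <- list()

  # data
  if (config$mode == "synthetic") {
    dataset <- run_stage("simulate", simulate_anaemia_data(
      n_children = config$n_children, geography_config = config$geography,
      truth = config$truth, covariates = config$covariates,
      seed = config$seed
    ))
    records <- dataset$records
    paths <- c(paths, as.list(run_stage("simulate",
                                        write_dataset(dataset, dir))))
    log_stage("simulate", sprintf("%d children simulated", nrow(records)))
  } else {
    records <- run_stage("load", read_children_csv(config$data_path))
    log_stage("load", sprintf("%d children read", nrow(records)))
  }

  summary <- run_stage("summarize", summarize_cohort(records))
  paths$cohort_summary <- file.path(dir, "cohort_summary.csv")
  readr::write_csv(summary, paths$cohort_summary)
  log_stage("summarize", "cohort summary written")

  # screening
  model <- config$model
  if (isTRUE(config$screen)) {
    uni <- run_stage("screen", screen_covariates(
      records, intersect(config$candidates, names(records)),
      alpha = model$alpha
    ))
    paths$screening_univariate <- file.path(dir, "screening_univariate.csv")
    readr::write_csv(uni, paths$screening_univariate)
    kept <- uni$variable[uni$keep]
    inter <- run_stage("screen", suppressWarnings(
      screen_interactions(records, kept, alpha = model$alpha)
    ))
    paths$screening_interactions <- file.path(dir, "screening_interactions.csv")
    readr::write_csv(inter, paths$screening_interactions)
    model$linear <- intersect(model$linear, kept)
    model$interactions <- purrr::keep(model$interactions, function(pr) {
      all(pr %in% kept) && any(
        (inter$term1 == pr[1] & inter$term2 == pr[2] & inter$significant) |
          (inter$term1 == pr[2] & inter$term2 == pr[1] & inter$significant)
      )
    })
    log_stage("screen", sprintf("%d of %d candidates kept", length(kept),
                                nrow(uni)))
  }

  fit <- run_stage("fit", fit_anaemia_gamm(records, model, config$control))
  log_stage("fit", sprintf("converged in %d outer iterations",
                           nrow(fit$convergence)))

  paths$fit <- file.path(dir, "fit.json")
  jsonlite::write_json(
    list(
      coefficients = as.list(fit$coefficients[seq_len(fit$state$n_fixed)]),
      variance_components = fit$theta,
      deviance = fit$deviance, reml = fit$reml,
      convergence = fit$convergence
    ),
    paths$fit, auto_unbox = TRUE, digits = NA
  )
  paths$aor_table <- file.path(dir, "aor_table.csv")
  readr::write_csv(aor_table(fit), paths$aor_table)
  paths$variance_components <- file.path(dir, "variance_components.csv")
  readr::write_csv(variance_components(fit), paths$variance_components)
  if (!is.null(model$smooth)) {
    paths$age_curve <- file.path(dir, "age_curve.csv")
    readr::write_csv(smooth_curve(fit), paths$age_curve)
  }
  if (isTRUE(model$spatial)) {
    paths$spatial_surface <- file.path(dir, "spatial_surface.csv")
    readr::write_csv(spatial_surface(fit), paths$spatial_surface)
  }
  if (any(fit$column_map$role == "interaction")) {
    paths$total_effects <- file.path(dir, "total_effects.csv")
    readr::write_csv(total_residence_country_effects(fit),
                     paths$total_effects)
  }

  appraisal <- run_stage("appraise", appraise_districts(
    fit, k = config$appraisal_k, method = config$appraisal_method,
    within = config$appraisal_within
  ))
  paths$appraisal <- file.path(dir, "appraisal.csv")
  readr::write_csv(appraisal, paths$appraisal)
  clusters <- records |>
    dplyr::distinct(.data$district_id, .keep_all = TRUE) |>
    dplyr::select("district_id", "country", "lon", "lat") |>
    dplyr::left_join(appraisal, by = c("district_id", "country"))
  paths$appraisal_geojson <- file.path(dir, "appraisal.geojson")
  write_geojson_points(clusters, paths$appraisal_geojson,
                       props = c("district_id", "country", "blup",
                                 "prediction_se", "standardized", "rank",
                                 "flag"))
  log_stage("appraise", sprintf("%d districts appraised", nrow(appraisal)))

  paths$config <- file.path(dir, "config.json")
  jsonlite::write_json(serialize_config(config), paths$config,
                       auto_unbox = TRUE, digits = NA)
  paths$log <- file.path(dir, "log.csv")
  readr::write_csv(dplyr::bind_rows(stage_log), paths$log)

  invisible(list(fit = fit, appraisal = appraisal, summary = summary,
                 paths = paths))
}

# JSON-serializable view of the resolved configuration (functions are
# represented by their deparsed source).
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.function(x)) return(paste(deparse(x), collapse = "\n"))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(config)
}
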