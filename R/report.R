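#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

z975 <- function(conf.level = 0.95) qnorm(1 - (1 - conf.level) / 2)

#' Tidy the fixed effects of a fitted model
#'
#' One row per parametric fixed-effect coefficient (smooth-basis columns are
#' excluded), with the adjusted odds ratio `exp(estimate)` and Wald
#' confidence limits.
#'
#' @param x An `anaemia_gamm` fit.
#' @param conf.level Confidence level (default 0.95).
#' @param exponentiate Report odds-ratio scale columns (default `TRUE`).
#' @param ... Unused.
#' @return A tibble: `term`, `variable`, `level`, `reference`, `role`,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high` (the last three on the odds-ratio scale when
#'   `exponentiate = TRUE`).
#' @exportS3Method generics::tidy
tidy.anaemia_gamm <- function(x, conf.level = 0.95, exponentiate = TRUE, ...) {
  if (is.null(x$cov)) abort("Fit carries no covariance matrix.")
  map <- x$column_map |>
    dplyr::filter(.data$role %in% c("parametric", "interaction"))
  est <- x$coefficients[map$column]
  se <- sqrt(diag(x$cov))[map$column]
  zq <- z975(conf.level)
  out <- tibble::tibble(
    term = map$column, variable = map$variable, level = map$level,
    reference = map$reference, role = map$role,
    estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - zq * se),
    conf.high = unname(est + zq * se)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out,
      estimate = exp(.data$estimate),
      conf.low = exp(.data$conf.low),
      conf.high = exp(.data$conf.high)
    )
  }
  out
}

#' Adjusted odds-ratio table
#'
#' The reporting table of the fit: adjusted odds ratios `exp(beta)` with
#' Wald 95% confidence intervals, a significance flag at the 5% level
#' (equivalently, the CI excluding 1), main effects first and interaction
#' rows last, with reference levels annotated.
#'
#' @param fit An `anaemia_gamm` fit.
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble: `term`, `variable`, `level`, `reference`, `aor`,
#'   `conf.low`, `conf.high`, `significant`.
#' @export
aor_table <- function(fit, conf.level = 0.95) {
  td <- tidy(fit, conf.level = conf.level, exponentiate = TRUE)
  td |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::arrange(match(.data$role, c("parametric", "interaction"))) |>
    dplyr::transmute(
      term = .data$term, variable = .data$variable, level = .data$level,
      reference = .data$reference,
      aor = .data$estimate, conf.low = .data$conf.low,
      conf.high = .data$conf.high,
      significant = .data$conf.low > 1 | .data$conf.high < 1
    )
}

#' Variance estimates of the nonlinear terms
#'
#' The variance components of the fit: the age-smooth variance
#' `tau^2_age`, the cluster-level spatial variance `tau^2_spatial`, and the
#' district-level random-effect variance `sigma^2_district`. Components
#' that finished on the boundary floor are reported as 0.
#'
#' @param fit An `anaemia_gamm` fit.
#' @return A tibble: `term`, `variance`, `boundary`.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "anaemia_gamm"))
  nm <- names(fit$theta)
  label <- c(tau2_age = "nonlinear smooth", tau2_spatial = "cluster-level spatial effect",
             sigma2_district = "district-level random effect")[nm]
  tibble::tibble(
    component = nm, term = unname(label),
    variance = unname(unlist(fit$theta)),
    boundary = unname(fit$theta_boundary[nm])
  )
}

#' @exportS3Method generics::glance
glance.anaemia_gamm <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_districts = x$n_districts, deviance = x$deviance,
    reml = x$reml,
    tau2_age = x$theta$tau2_age %||% NA_real_,
    tau2_spatial = x$theta$tau2_spatial %||% NA_real_,
    sigma2_district = x$theta$sigma2_district,
    outer_iterations = nrow(x$convergence)
  )
}

# Joint rows (L matrix) evaluating a centered smooth at new inputs, with
# the matching coefficient columns.
smooth_rows <- function(fit, which = c("age", "spatial"), ...) {
  which <- match.arg(which)
  rep_term <- fit$state$reparams[[which]]
  if (is.null(rep_term)) abort(sprintf("The fit has no %s term.", which))
  new <- reparam_eval(rep_term, ...)
  if (which == "age") {
    obs <- list(X_pen = rep_term$X_pen, X_null = rep_term$X_null)
  } else {
    obs <- list(X_pen = rep_term$X_pen, X_null = rep_term$X_null)
  }
  # drop the constant null column (absorbed by the intercept); center the
  # remaining columns at their observed means so the curve averages zero
  # over the fitted records
  keep_null <- seq_len(ncol(obs$X_null))[-1]
  L_new <- cbind(new$X_null[, keep_null, drop = FALSE], new$X_pen)
  L_obs_mean <- c(colMeans(obs$X_null[, keep_null, drop = FALSE]),
                  colMeans(obs$X_pen))
  L <- sweep(L_new, 2, L_obs_mean)
  smooth_var <- fit$spec$smooth %||% "smooth"
  null_names <- if (length(keep_null)) {
    if (which == "age") {
      paste0(smooth_var, "_null", seq_along(keep_null))
    } else {
      paste0("spatial_null", seq_along(keep_null))
    }
  } else character(0)
  pen_names <- if (which == "age") {
    paste0(smooth_var, "_pen", seq_len(ncol(new$X_pen)))
  } else {
    paste0("spatial_pen", seq_len(ncol(new$X_pen)))
  }
  list(L = L, cols = c(null_names, pen_names))
}

smooth_estimate <- function(fit, rows, conf.level = 0.95) {
  beta <- fit$coefficients[rows$cols]
  V <- fit$cov[rows$cols, rows$cols, drop = FALSE]
  est <- drop(rows$L %*% beta)
  se <- sqrt(pmax(rowSums((rows$L %*% V) * rows$L), 0))
  zq <- z975(conf.level)
  tibble::tibble(estimate = est, std.error = se,
                 conf.low = est - zq * se, conf.high = est + zq * se)
}

#' Estimated nonlinear smooth with a pointwise confidence band
#'
#' Evaluates the centered estimated smooth (by default the age effect) on a
#' grid with pointwise Wald bands from the coefficient covariance. The
#' curve is centered to average zero over the observed covariate values.
#'
#' @param fit An `anaemia_gamm` fit.
#' @param grid Evaluation points (default: 100 points over the observed
#'   domain). Must lie inside the smooth's domain.
#' @param conf.level Confidence level for the band.
#' @return A tibble with the grid value, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
smooth_curve <- function(fit, grid = NULL, conf.level = 0.95) {
  stopifnot(inherits(fit, "anaemia_gamm"))
  rep_term <- fit$state$reparams$age
  if (is.null(rep_term)) abort("The fit has no 1-D smooth term.")
  kn <- rep_term$term$knots
  if (is.null(grid)) grid <- seq(kn$z_min, kn$z_max, length.out = 100)
  rows <- smooth_rows(fit, "age", z = grid)
  out <- smooth_estimate(fit, rows, conf.level)
  smooth_var <- fit$spec$smooth %||% "z"
  dplyr::bind_cols(tibble::tibble("{smooth_var}" := grid), out)
}

#' Estimated cluster-level spatial effect
#'
#' Evaluates the centered spatial surface at the given points (default: the
#' distinct observed cluster coordinates), suitable for point maps or
#' choropleth joins.
#'
#' @param fit An `anaemia_gamm` fit.
#' @param points Data frame with `lon` and `lat` (default: observed
#'   clusters, with their `cluster_id`).
#' @param conf.level Confidence level for the pointwise band.
#' @return `points` with `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
spatial_surface <- function(fit, points = NULL, conf.level = 0.95) {
  stopifnot(inherits(fit, "anaemia_gamm"))
  if (is.null(fit$state$reparams$spatial)) {
    abort("The fit has no spatial term.")
  }
  if (is.null(points)) {
    points <- fit$state$design$records |>
      dplyr::distinct(.data$cluster_id, .data$district_id, .data$country,
                      .data$lon, .data$lat)
  }
  rows <- smooth_rows(fit, "spatial", lon = points$lon, lat = points$lat)
  dplyr::bind_cols(tibble::as_tibble(points),
                   smooth_estimate(fit, rows, conf.level))
}

#' Total residence-by-country effects on the log-odds
#'
#' The residence and country main effects and their interaction cannot be
#' read separately; this returns, for every (residence, country) cell, the
#' total log-odds contribution relative to the reference cell (urban
#' Malawi): the sum of the relevant main-effect and interaction
#' coefficients, with a delta-method standard error.
#'
#' @param fit An `anaemia_gamm` fit including residence, country and their
#'   interaction.
#' @param conf.level Confidence level.
#' @return A tibble: `residence`, `country`, `total_log_odds`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
total_residence_country_effects <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "anaemia_gamm"))
  map <- fit$column_map
  if (!any(map$role == "interaction" &
             grepl("residence", map$variable) & grepl("country", map$variable))) {
    abort(paste0("The fit has no residence-by-country interaction; ",
                 "use the main effects directly."))
  }
  lv <- anaemia_levels()
  cells <- tidyr::expand_grid(residence = lv$residence, country = lv$country)
  cols <- map$column
  L <- matrix(0, nrow(cells), length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(nrow(cells))) {
    res_col <- paste0("residence_", cells$residence[i])
    ctry_col <- paste0("country_", cells$country[i])
    int_col <- paste0(res_col, ":", ctry_col)
    for (cc in c(res_col, ctry_col, int_col)) {
      if (cc %in% cols) L[i, cc] <- 1
    }
  }
  beta <- fit$coefficients[cols]
  V <- fit$cov[cols, cols]
  est <- drop(L %*% beta)
  se <- sqrt(pmax(rowSums((L %*% V) * L), 0))
  zq <- z975(conf.level)
  dplyr::bind_cols(cells, tibble::tibble(
    total_log_odds = est, std.error = se,
    conf.low = est - zq * se, conf.high = est + zq * se
  ))
}
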