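#' Control parameters for the GAMM fitter
#'
#' Numerical knobs of the penalized-IWLS / REML fit. Defaults: inner
#' (coefficient) relative tolerance 1e-6 with at most 200 iterations, outer
#' (variance-component) relative tolerance 1e-3 with at most 50 iterations
#' (the alternating coefficient/variance scheme settles into a tiny limit
#' cycle below that amplitude on binary data, so a tighter outer tolerance
#' buys nothing),
#' fitted probabilities clipped to `[clip, 1 - clip]` when forming working
#' weights, and variance components floored at `theta_floor` during
#' optimization (reported as 0 when they finish at the floor).
#'
#' @param inner_tol,max_inner Inner PIWLS convergence tolerance / cap.
#' @param outer_tol,max_outer Outer REML convergence tolerance / cap.
#' @param clip Probability clipping bound for working weights.
#' @param theta_floor Lower bound for variance components.
#' @param theta_init Starting value for every variance component.
#' @return A list of class `gamm_control`.
#' @export
gamm_control <- function(inner_tol = 1e-6, max_inner = 200,
                         outer_tol = 1e-3, max_outer = 50,
                         clip = 1e-10, theta_floor = 1e-8,
                         theta_init = 0.1) {
  structure(as.list(environment()), class = "gamm_control")
}

# Working response and weights of the logit IWLS step.
working_response <- function(y, eta, clip = 1e-10) {
  prob <- plogis(eta)
  prob <- pmin(pmax(prob, clip), 1 - clip)
  w <- prob * (1 - prob)
  list(prob = prob, w = w, z = eta + (y - prob) / w)
}

# Weighted cross-product blocks of the working penalized LMM, exploiting
# the district indicator structure (A is the dense fixed + smooth block).
working_blocks <- function(A, dist_idx, H, w, z) {
  sw <- sqrt(w)
  Asw <- A * sw
  G1 <- crossprod(Asw)
  B2 <- rowsum(A * w, dist_idx)            # H x p
  G3 <- drop(rowsum(w, dist_idx))
  a <- drop(crossprod(A, w * z))
  cvec <- drop(rowsum(w * z, dist_idx))
  list(G1 = G1, B2 = B2, G3 = G3, a = a, cvec = cvec,
       zWz = sum(w * z^2), sumlogw = sum(log(w)), H = H)
}

# Solve the working mixed-model equations at fixed variance components via
# the Schur complement over the diagonal district block. `pvec` holds the
# ridge precision (1/tau^2) for each column of A (0 = unpenalized).
solve_working <- function(bl, pvec, sigma2) {
  d <- bl$G3 + 1 / sigma2
  B2d <- bl$B2 / sqrt(d)
  S <- bl$G1 - crossprod(B2d)
  diag(S) <- diag(S) + pvec
  R <- chol(S)
  rhs <- bl$a - drop(crossprod(bl$B2, bl$cvec / d))
  deltaA <- backsolve(R, forwardsolve(t(R), rhs))
  u <- drop(bl$cvec - bl$B2 %*% deltaA) / d
  list(deltaA = deltaA, u = u, S = S, chol = R, d = d,
       quad = bl$zWz - sum(bl$a * deltaA) - sum(bl$cvec * u))
}

# Penalized deviance of the binary model at given coefficients.
penalized_deviance <- function(state, coefs, pvec, sigma2, clip = 1e-10) {
  eta <- drop(state$A %*% coefs$deltaA) + coefs$u[state$dist_idx]
  prob <- pmin(pmax(plogis(eta), clip), 1 - clip)
  dev <- -2 * sum(state$y * log(prob) + (1 - state$y) * log1p(-prob))
  dev + sum(pvec * coefs$deltaA^2) + sum(coefs$u^2) / sigma2
}

# Map active variance components onto a per-column ridge-precision vector.
ridge_precisions <- function(state, theta) {
  pvec <- numeric(ncol(state$A))
  for (nm in setdiff(names(theta), "sigma2_district")) {
    pvec[state$pen_map == nm] <- 1 / theta[[nm]]
  }
  pvec
}

#' One penalized IWLS step
#'
#' Performs a single weighted penalized least-squares solve on the working
#' response at the current coefficients, with step-halving so that the
#' penalized deviance does not increase.
#'
#' @param state A `model_state` from [assemble_model()].
#' @param theta Named variance components (`tau2_age`, `tau2_spatial`,
#'   `sigma2_district`, as present in the model).
#' @param coefs Current coefficients (`NULL` starts from zero).
#' @return Updated coefficients: a list with `deltaA`, `u`, `pdev`,
#'   `halvings` and `step_norm`.
#' @export
piwls_step <- function(state, theta, coefs = NULL) {
  stopifnot(inherits(state, "model_state"))
  clip <- state$control$clip
  pvec <- ridge_precisions(state, theta)
  sigma2 <- theta[["sigma2_district"]]
  if (is.null(coefs)) {
    coefs <- list(deltaA = numeric(ncol(state$A)), u = numeric(state$H))
  }
  eta <- drop(state$A %*% coefs$deltaA) + coefs$u[state$dist_idx]
  wr <- working_response(state$y, eta, clip)
  bl <- working_blocks(state$A, state$dist_idx, state$H, wr$w, wr$z)
  sol <- solve_working(bl, pvec, sigma2)
  pdev_old <- penalized_deviance(state, coefs, pvec, sigma2, clip)
  step <- 1
  halvings <- 0
  repeat {
    prop <- list(
      deltaA = coefs$deltaA + step * (sol$deltaA - coefs$deltaA),
      u = coefs$u + step * (sol$u - coefs$u)
    )
    pdev_new <- penalized_deviance(state, prop, pvec, sigma2, clip)
    if (pdev_new <= pdev_old + 1e-10 || halvings >= 30) break
    step <- step / 2
    halvings <- halvings + 1
  }
  prop$pdev <- pdev_new
  prop$halvings <- halvings
  prop$step_norm <- max(abs(c(prop$deltaA - coefs$deltaA, prop$u - coefs$u)))
  prop
}

# Iterate piwls_step to convergence at fixed theta.
piwls_run <- function(state, theta, coefs = NULL) {
  ctrl <- state$control
  trace <- numeric(0)
  par_idx <- seq_len(min(state$n_fixed %||% ncol(state$A), ncol(state$A)))
  for (it in seq_len(ctrl$max_inner)) {
    coefs <- piwls_step(state, theta, coefs)
    trace <- c(trace, coefs$pdev)
    big <- which(abs(coefs$deltaA[par_idx]) > 15)
    if (length(big)) {
      worst <- par_idx[big][which.max(abs(coefs$deltaA[par_idx][big]))]
      abort(paste0("Apparent complete separation: coefficient for `",
                   colnames(state$A)[worst], "` is diverging."),
            class = "anaemiagamm_separation")
    }
    scale <- max(abs(c(coefs$deltaA, coefs$u)), 1e-4)
    if (coefs$step_norm / scale < ctrl$inner_tol) {
      coefs$iterations <- it
      coefs$pdev_trace <- trace
      return(coefs)
    }
  }
  abort("Inner PIWLS did not converge within `max_inner` iterations.",
        class = "anaemiagamm_maxit", state = list(coefs = coefs, theta = theta))
}

# -2 x (restricted log-likelihood) of the working linear mixed model, up to
# an additive constant, with working weights and response held fixed.
reml_criterion <- function(bl, pvec_unit, pen_counts, theta) {
  pvec <- numeric(length(pvec_unit))
  for (nm in names(pen_counts)) {
    pvec[pvec_unit == nm] <- 1 / theta[[nm]]
  }
  sol <- solve_working(bl, pvec, theta[["sigma2_district"]])
  logdet <- sum(log(sol$d)) + 2 * sum(log(diag(sol$chol)))
  pen_logdet <- sum(vapply(names(pen_counts), function(nm) {
    pen_counts[[nm]] * log(theta[[nm]])
  }, numeric(1))) + bl$H * log(theta[["sigma2_district"]])
  sol$quad + logdet + pen_logdet - bl$sumlogw
}

#' REML update of the variance components
#'
#' With the inner PIWLS converged at the current variance components, holds
#' the working weights and response fixed and maximizes the restricted
#' likelihood of the working linear mixed model over the variance
#' components (smoothing variances `tau^2 = 1/lambda` and the district
#' variance), on the log scale, bounded below by the configured floor.
#'
#' @param state A `model_state`.
#' @param theta Current named variance components.
#' @param coefs Converged coefficients at `theta`.
#' @return A list with `theta` (updated), `reml` (the criterion value) and
#'   `boundary` (logical, per component at the floor).
#' @export
reml_update <- function(state, theta, coefs) {
  stopifnot(inherits(state, "model_state"))
  ctrl <- state$control
  eta <- drop(state$A %*% coefs$deltaA) + coefs$u[state$dist_idx]
  wr <- working_response(state$y, eta, ctrl$clip)
  bl <- working_blocks(state$A, state$dist_idx, state$H, wr$w, wr$z)
  pen_counts <- table(state$pen_map[state$pen_map != ""])
  pen_counts <- setNames(as.numeric(pen_counts), names(pen_counts))
  fn <- function(lt) {
    th <- setNames(exp(lt), names(theta))
    val <- reml_criterion(bl, state$pen_map, pen_counts, th)
    if (!is.finite(val)) {
      abort(paste0("REML criterion non-finite at theta = ",
                   paste(signif(th, 4), collapse = ", ")))
    }
    val
  }
  opt <- optim(log(unlist(theta)), fn, method = "L-BFGS-B",
               lower = log(ctrl$theta_floor), upper = log(1e6),
               control = list(maxit = 200))
  theta_new <- setNames(exp(opt$par), names(theta))
  list(theta = as.list(theta_new), reml = opt$value,
       boundary = exp(opt$par) <= ctrl$theta_floor * (1 + 1e-6))
}

#' Assemble the model state
#'
#' Combines the encoded fixed design, the reparameterized smooth terms and
#' the district factor into one state ready for fitting: null-space columns
#' of the smooths (minus the constant, which the intercept carries) are
#' absorbed into the fixed block; penalized columns carry identity
#' penalties tied to their variance components; the district indicator
#' block is kept in factor form and handled analytically by the solver.
#'
#' @param design A `design_matrices` from [encode_design()].
#' @param age_reparam Optional `reparam_term` for the 1-D smooth.
#' @param spatial_reparam Optional `reparam_term` for the spatial surface.
#' @param control A [gamm_control()].
#' @return An object of class `model_state`.
#' @export
assemble_model <- function(design, age_reparam = NULL, spatial_reparam = NULL,
                           control = gamm_control()) {
  stopifnot(inherits(design, "design_matrices"))
  if (is.null(design$y)) abort("The design carries no outcome `y`.")
  if (nlevels(design$district) < 2) {
    abort("The district factor must have at least 2 levels.")
  }
  X <- design$X
  map <- design$column_map
  smooth_var <- design$spec$smooth %||% "smooth"
  if (!is.null(age_reparam)) {
    nn <- age_reparam$null_dim
    if (nn > 1) {
      null_cols <- age_reparam$X_null[, -1, drop = FALSE]
      colnames(null_cols) <- paste0(smooth_var, "_null", seq_len(nn - 1))
      X <- cbind(X, null_cols)
      map <- dplyr::bind_rows(map, tibble::tibble(
        column = colnames(null_cols), variable = smooth_var,
        level = NA_character_, reference = NA_character_, role = "smooth_null"
      ))
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Fixed design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  blocks <- list(X)
  pen_map <- rep("", ncol(X))
  if (!is.null(age_reparam)) {
    P <- age_reparam$X_pen
    colnames(P) <- paste0(smooth_var, "_pen", seq_len(ncol(P)))
    blocks <- c(blocks, list(P))
    pen_map <- c(pen_map, rep("tau2_age", ncol(P)))
    map <- dplyr::bind_rows(map, tibble::tibble(
      column = colnames(P), variable = smooth_var, level = NA_character_,
      reference = NA_character_, role = "smooth_pen"
    ))
  }
  if (!is.null(spatial_reparam)) {
    P <- spatial_reparam$X_pen
    colnames(P) <- paste0("spatial_pen", seq_len(ncol(P)))
    blocks <- c(blocks, list(P))
    pen_map <- c(pen_map, rep("tau2_spatial", ncol(P)))
    map <- dplyr::bind_rows(map, tibble::tibble(
      column = colnames(P), variable = "spatial", level = NA_character_,
      reference = NA_character_, role = "smooth_pen"
    ))
  }
  A <- do.call(cbind, blocks)
  dist_idx <- as.integer(design$district)
  structure(
    list(
      y = design$y, A = A, pen_map = pen_map,
      dist_idx = dist_idx, H = nlevels(design$district),
      district_ids = levels(design$district),
      column_map = map, n_fixed = ncol(X),
      reparams = list(age = age_reparam, spatial = spatial_reparam),
      design = design, control = control
    ),
    class = "model_state"
  )
}

#' Fit the spatial additive mixed model for anaemia
#'
#' Fits the logit additive mixed model: linear fixed effects, a P-spline
#' smooth of one covariate (default the child's age in months), a
#' tensor-product P-spline spatial surface over cluster coordinates with a
#' four-nearest-neighbour penalty, and an i.i.d. district random effect.
#' Coefficients are estimated by penalized iteratively weighted least
#' squares; variance components (equivalently, smoothing parameters
#' `lambda = 1/tau^2`) by REML on the working linear mixed model at PIWLS
#' convergence, alternated to joint convergence (empirical Bayes). The fit
#' is deterministic given the data and starting values.
#'
#' @param data Child records (a data frame; see [generate_cohort()] for the
#'   column dictionary).
#' @param spec A [model_spec()].
#' @param control A [gamm_control()].
#' @return An object of class `anaemia_gamm` with coefficient estimates and
#'   covariance, variance components, district BLUPs with prediction SEs,
#'   and a convergence log. Use [tidy()] / [aor_table()],
#'   [variance_components()], [smooth_curve()], [spatial_surface()] and
#'   [extract_blups()] on it.
#' @export
fit_anaemia_gamm <- function(data, spec = model_spec(),
                             control = gamm_control()) {
  design <- encode_design(data, spec)
  age_rep <- NULL
  spat_rep <- NULL
  theta <- list()
  if (!is.null(spec$smooth)) {
    z <- design$smooth_inputs[[spec$smooth]]
    age_rep <- reparameterize(spline_term(
      z, n_segments = spec$smooth_segments, degree = spec$smooth_degree,
      order = spec$smooth_order
    ))
    theta$tau2_age <- control$theta_init
  }
  if (isTRUE(spec$spatial)) {
    spat_rep <- reparameterize(tensor_term(
      design$smooth_inputs$lon, design$smooth_inputs$lat,
      n_segments = spec$spatial_segments, degree = spec$spatial_degree
    ))
    theta$tau2_spatial <- control$theta_init
  }
  theta$sigma2_district <- control$theta_init
  state <- assemble_model(design, age_rep, spat_rep, control)

  coefs <- NULL
  conv_log <- list()
  reml_val <- NA_real_
  boundary <- rep(FALSE, length(theta))
  converged <- FALSE
  for (outer in seq_len(control$max_outer)) {
    coefs <- piwls_run(state, theta, coefs)
    up <- reml_update(state, theta, coefs)
    # relative change with an absolute cushion: variance components below
    # 0.01 are judged on absolute movement (< outer_tol/100 per sweep), so
    # near-null components crawling along a flat restricted likelihood do
    # not keep the loop alive
    delta <- abs(unlist(up$theta) - unlist(theta))
    rel <- max(delta / pmax(abs(unlist(theta)), 0.01))
    conv_log[[outer]] <- tibble::tibble(
      outer = outer, inner_iterations = coefs$iterations,
      pdev = coefs$pdev, reml = up$reml, theta_change = rel
    )
    boundary <- up$boundary
    reml_val <- up$reml
    theta <- up$theta
    if (rel < control$outer_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort("Outer REML loop did not converge within `max_outer` iterations.",
          class = "anaemiagamm_maxit",
          state = list(theta = theta, coefs = coefs))
  }
  coefs <- piwls_run(state, theta, coefs)

  # final working solve for covariances
  eta <- drop(state$A %*% coefs$deltaA) + coefs$u[state$dist_idx]
  wr <- working_response(state$y, eta, control$clip)
  bl <- working_blocks(state$A, state$dist_idx, state$H, wr$w, wr$z)
  pvec <- ridge_precisions(state, theta)
  sol <- solve_working(bl, pvec, theta$sigma2_district)
  Sinv <- chol2inv(sol$chol)
  dimnames(Sinv) <- list(colnames(state$A), colnames(state$A))
  BS <- bl$B2 %*% Sinv
  u_var <- 1 / sol$d + rowSums(BS * bl$B2) / sol$d^2

  # complete-separation guard on the parametric block
  par_idx <- seq_len(state$n_fixed)
  se_A <- sqrt(diag(Sinv))
  big <- which(abs(coefs$deltaA[par_idx]) > 15 & se_A[par_idx] > 5)
  if (length(big)) {
    abort(paste0("Apparent complete separation for covariate column(s): ",
                 paste(colnames(state$A)[big], collapse = ", ")),
          class = "anaemiagamm_separation")
  }

  theta_rep <- unlist(theta)
  theta_rep[boundary] <- 0
  prob <- plogis(eta)
  dev <- -2 * sum(state$y * log(pmax(prob, 1e-12)) +
                    (1 - state$y) * log(pmax(1 - prob, 1e-12)))
  n_by_district <- tabulate(state$dist_idx, state$H)
  blups <- tibble::tibble(
    district_id = state$district_ids,
    blup = coefs$u,
    prediction_se = sqrt(u_var),
    n_children = n_by_district
  ) |>
    dplyr::left_join(state$design$country_by_district, by = "district_id") |>
    dplyr::relocate("district_id", "country")

  structure(
    list(
      coefficients = setNames(coefs$deltaA, colnames(state$A)),
      cov = Sinv,
      theta = as.list(theta_rep),
      theta_boundary = setNames(boundary, names(theta)),
      blups = blups,
      column_map = state$column_map,
      state = state,
      convergence = dplyr::bind_rows(conv_log),
      pdev_trace = coefs$pdev_trace,
      fitted = prob,
      deviance = dev,
      reml = reml_val,
      n = length(state$y),
      n_districts = state$H,
      spec = design$spec
    ),
    class = "anaemia_gamm"
  )
}

#' @export
print.anaemia_gamm <- function(x, ...) {
  cat(sprintf(
    paste0("<anaemia_gamm> n = %d children, %d districts\n",
           "  deviance %.1f; variance components: %s\n"),
    x$n, x$n_districts, x$deviance,
    paste(sprintf("%s = %.4g", names(x$theta), unlist(x$theta)),
          collapse = ", ")
  ))
  invisible(x)
}
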