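# Independent oracles used across tests: a direct Cox-de Boor recursion, a
# neighbour-loop spatial penalty, dense penalized solvers, and small
# dataset builders. These deliberately avoid the package's own code paths.

# --- Cox-de Boor recursion (direct, recursive, right-closed at the upper
#     boundary) ---------------------------------------------------------
bspline_oracle_one <- function(i, k, x, t) {
  if (k == 0) {
    tmax <- t[length(t)]
    inside <- x >= t[i] && x < t[i + 1]
    at_end <- x == tmax && t[i] < t[i + 1] && t[i + 1] == tmax
    return(as.numeric(inside || at_end))
  }
  a <- 0
  if (t[i + k] > t[i]) {
    a <- (x - t[i]) / (t[i + k] - t[i]) * bspline_oracle_one(i, k - 1, x, t)
  }
  b <- 0
  if (t[i + k + 1] > t[i + 1]) {
    b <- (t[i + k + 1] - x) / (t[i + k + 1] - t[i + 1]) *
      bspline_oracle_one(i + 1, k - 1, x, t)
  }
  a + b
}

bspline_oracle <- function(x, all_knots, degree) {
  n_basis <- length(all_knots) - degree - 1
  out <- matrix(0, length(x), n_basis)
  for (j in seq_len(n_basis)) {
    for (r in seq_along(x)) {
      out[r, j] <- bspline_oracle_one(j, degree, x[r], all_knots)
    }
  }
  out
}

# --- four-nearest-neighbour penalty by explicit pair enumeration --------
spatial_penalty_oracle <- function(M1, M2) {
  idx <- function(m1, m2) m1 + (m2 - 1) * M1
  K <- matrix(0, M1 * M2, M1 * M2)
  add_pair <- function(K, a, b) {
    K[a, a] <- K[a, a] + 1
    K[b, b] <- K[b, b] + 1
    K[a, b] <- K[a, b] - 1
    K[b, a] <- K[b, a] - 1
    K
  }
  for (m2 in seq_len(M2)) {
    for (m1 in seq_len(M1 - 1)) K <- add_pair(K, idx(m1, m2), idx(m1 + 1, m2))
  }
  for (m1 in seq_len(M1)) {
    for (m2 in seq_len(M2 - 1)) K <- add_pair(K, idx(m1, m2), idx(m1, m2 + 1))
  }
  K
}

# --- dense penalized-logistic machinery (no Schur shortcut) -------------
# One Newton/IWLS step on the full coefficient vector for the model
# eta = C beta with quadratic penalty 0.5 * beta' P beta.
dense_newton_step <- function(y, C, Pmat, beta) {
  eta <- drop(C %*% beta)
  prob <- plogis(eta)
  w <- prob * (1 - prob)
  z <- eta + (y - prob) / w
  solve(crossprod(C, C * w) + Pmat, crossprod(C, w * z))
}

# Generic numerical maximizer of the penalized Bernoulli log-likelihood.
penalized_logistic_bfgs <- function(y, C, Pmat, start = NULL) {
  if (is.null(start)) start <- numeric(ncol(C))
  fn <- function(b) {
    eta <- drop(C %*% b)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * drop(crossprod(b, Pmat %*% b))
  }
  gr <- function(b) {
    eta <- drop(C %*% b)
    -drop(crossprod(C, y - plogis(eta))) + drop(Pmat %*% b)
  }
  opt <- optim(start, fn, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  opt2 <- optim(opt$par, fn, gr, method = "BFGS",
                control = list(maxit = 5000, reltol = 1e-16))
  opt2$par
}

# Full dense coefficient vector (smooth/fixed block + district dummies)
# and matching penalty for a model_state at fixed theta.
dense_model_parts <- function(state, theta) {
  Z <- model.matrix(~ 0 + factor(state$dist_idx))
  C <- cbind(state$A, Z)
  pvec <- anaemiagamm:::ridge_precisions(state, theta)
  Pmat <- diag(c(pvec, rep(1 / theta[["sigma2_district"]], state$H)))
  list(C = C, Pmat = Pmat)
}

# --- small dataset builders --------------------------------------------
tiny_geography <- function(seed = 1, districts = 5L, clusters = 3L) {
  # urban_fraction 0.5 keeps every residence-by-country cell populated in
  # small samples so interaction columns stay well conditioned
  generate_geography(
    geography_config(districts_per_country = rep(districts, 4),
                     clusters_per_district = clusters,
                     urban_fraction = 0.5),
    seed = seed
  )
}

tiny_dataset <- function(n = 800, seed = 1, truth = true_model(),
                         districts = 5L) {
  geo <- tiny_geography(seed, districts = districts)
  cohort <- generate_cohort(geo, n, seed = seed + 1)
  simulate_outcomes(cohort, truth, seed = seed + 2)
}

# A small model specification that keeps fits fast in unit tests.
small_spec <- function(...) {
  model_spec(smooth_segments = 8, spatial_segments = 3, ...)
}
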