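#' Equally spaced P-spline knots
#'
#' Builds the knot vector for a degree-`degree` B-spline basis on
#' `[z_min, z_max]` with `n_segments` equal-width segments. The interior
#' knots are `n_segments + 1` equally spaced values including both
#' boundaries; the knot grid is then continued with the same spacing for
#' `degree` extra knots beyond each boundary (the classic P-spline
#' construction), so the basis spans the closed interval, sums to one
#' everywhere inside it, and an order-2 difference penalty leaves exactly
#' the linear functions of `z` unpenalized. The basis built on these knots
#' has exactly `n_segments + degree` functions.
#'
#' @param z_min,z_max Domain boundaries, `z_max > z_min`.
#' @param n_segments Number of equal-width segments (>= 1).
#' @param degree Spline degree `l` (>= 1); cubic by default.
#' @return An object of class `pspline_knots`: a list with `interior` (the
#'   equally spaced knots including boundaries), `all` (the extended knot
#'   vector), `degree`, `n_segments`, `z_min`, `z_max` and `n_basis`.
#' @examples
#' k <- make_knots(0, 10, 5)
#' k$interior
#' @export
make_knots <- function(z_min, z_max, n_segments, degree = 3) {
  if (!is_scalar_number(z_min) || !is_scalar_number(z_max) || z_max <= z_min) {
    abort("`z_max` must be strictly greater than `z_min`.")
  }
  if (!is_scalar_number(n_segments) || n_segments < 1) {
    abort("`n_segments` must be a positive integer.")
  }
  if (!is_scalar_number(degree) || degree < 1) {
    abort("`degree` must be an integer >= 1.")
  }
  n_segments <- as.integer(n_segments)
  degree <- as.integer(degree)
  h <- (z_max - z_min) / n_segments
  interior <- seq(z_min, z_max, length.out = n_segments + 1L)
  all_knots <- c(z_min - h * (degree:1), interior, z_max + h * (1:degree))
  structure(
    list(
      interior = interior, all = all_knots, degree = degree,
      n_segments = n_segments, z_min = z_min, z_max = z_max,
      n_basis = n_segments + degree
    ),
    class = "pspline_knots"
  )
}

#' Evaluate a B-spline basis
#'
#' Evaluates the `n_segments + degree` B-spline basis functions defined by a
#' [make_knots()] object at the points `z`. Rows are observations, columns
#' basis functions; every row is a partition of unity and has at most
#' `degree + 1` nonzero entries. Points outside the knot domain are an
#' error: the basis does not extrapolate.
#'
#' @param z Numeric vector of evaluation points inside the knot domain.
#' @param knots A `pspline_knots` object.
#' @return A numeric matrix with `length(z)` rows and `knots$n_basis`
#'   columns.
#' @export
bspline_basis <- function(z, knots) {
  if (!inherits(knots, "pspline_knots")) abort("`knots` must come from make_knots().")
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    abort("`z` must be finite and non-missing.")
  }
  out_of_domain <- z < knots$z_min | z > knots$z_max
  if (any(out_of_domain)) {
    abort(sprintf(
      "%d point(s) outside the spline domain [%g, %g] (first at index %d).",
      sum(out_of_domain), knots$z_min, knots$z_max, which(out_of_domain)[1]
    ))
  }
  B <- splines::splineDesign(knots$all, z, ord = knots$degree + 1L)
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}

#' Difference penalty matrix for adjacent B-spline coefficients
#'
#' Returns `K = t(D) %*% D` where `D` is the order-`order` differencing
#' operator on `n_basis` coefficients, so that `t(a) %*% K %*% a` equals the
#' sum of squared order-`order` differences of `a`. First-order differences
#' penalize jumps between successive coefficients; second-order differences
#' penalize departures from a linear trend. The null space has dimension
#' `order` (constants for order 1, constants and linear trends for order 2).
#'
#' @param n_basis Number of B-spline coefficients.
#' @param order Difference order, 1 or 2.
#' @return A symmetric positive semidefinite `n_basis` x `n_basis` matrix.
#' @export
difference_penalty <- function(n_basis, order = 2) {
  if (!is_scalar_number(n_basis) || !is_scalar_number(order)) {
    abort("`n_basis` and `order` must be single numbers.")
  }
  if (!order %in% c(1, 2)) abort("`order` must be 1 or 2.")
  if (n_basis <= order) abort("`n_basis` must exceed the difference order.")
  D <- diff(diag(as.integer(n_basis)), differences = as.integer(order))
  crossprod(D)
}

#' Penalty value of a P-spline coefficient vector
#'
#' The roughness penalty `lambda/2 * sum((diff(alpha, order))^2)` attached to
#' the penalized likelihood.
#'
#' @param alpha Coefficient vector.
#' @param lambda Smoothing parameter (>= 0).
#' @param order Difference order, 1 or 2.
#' @return A single number.
#' @export
penalty_value <- function(alpha, lambda, order = 2) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  K <- difference_penalty(length(alpha), order)
  0.5 * lambda * drop(crossprod(alpha, K %*% alpha))
}

#' Construct a one-dimensional P-spline term
#'
#' Bundles knots, basis matrix and difference penalty for one smooth
#' covariate.
#'
#' @param z Observed covariate values.
#' @param n_segments Number of equal knot segments (default 20, the
#'   moderately large knot count used for flexible P-splines).
#' @param degree Spline degree (default cubic).
#' @param order Difference-penalty order (default 2).
#' @param z_range Domain; defaults to the observed range.
#' @return An object of class `spline_term` with elements `knots`, `basis`,
#'   `penalty`, `order` and `z`.
#' @export
spline_term <- function(z, n_segments = 20, degree = 3, order = 2,
                        z_range = range(z)) {
  knots <- make_knots(z_range[1], z_range[2], n_segments, degree)
  B <- bspline_basis(z, knots)
  structure(
    list(
      knots = knots, basis = B,
      penalty = difference_penalty(knots$n_basis, order),
      order = as.integer(order), z = z
    ),
    class = "spline_term"
  )
}

#' Tensor-product basis of two marginal B-spline bases
#'
#' The row for a point `(lon, lat)` is the flattened outer product of the
#' longitude and latitude marginal basis rows: column `(m1, m2)` (with `m1`
#' varying fastest) holds `B_m1(lon) * B_m2(lat)`. Rows inherit the
#' partition-of-unity property from the marginals.
#'
#' @param lon,lat Coordinate vectors of equal length.
#' @param knots_lon,knots_lat Marginal `pspline_knots` objects.
#' @return A matrix with `length(lon)` rows and `M1 * M2` columns.
#' @export
tensor_basis <- function(lon, lat, knots_lon, knots_lat) {
  if (length(lon) != length(lat)) abort("`lon` and `lat` must have equal length.")
  B1 <- bspline_basis(lon, knots_lon)
  B2 <- bspline_basis(lat, knots_lat)
  M1 <- ncol(B1)
  M2 <- ncol(B2)
  out <- B1[, rep(seq_len(M1), times = M2), drop = FALSE] *
    B2[, rep(seq_len(M2), each = M1), drop = FALSE]
  colnames(out) <- paste0(
    "s", rep(seq_len(M1), times = M2), ".", rep(seq_len(M2), each = M1)
  )
  out
}

#' Four-nearest-neighbour penalty for a tensor-product coefficient grid
#'
#' Penalty matrix whose quadratic form sums, over the `M1 x M2` coefficient
#' grid, the squared deviations of each coefficient from its horizontal and
#' vertical neighbours, counted once per adjacent pair: the difference
#' penalty induced by the four nearest neighbours on the grid. Equivalently
#' the Kronecker sum of the two marginal first-order difference penalties.
#' The null space is the constant coefficient sheet.
#'
#' @param M1,M2 Grid dimensions (>= 2); `M1` indexes the longitude basis and
#'   varies fastest in the flattened coefficient vector.
#' @return A symmetric positive semidefinite `(M1*M2) x (M1*M2)` matrix.
#' @export
spatial_penalty <- function(M1, M2) {
  if (!is_scalar_number(M1) || !is_scalar_number(M2) || M1 < 2 || M2 < 2) {
    abort("`M1` and `M2` must both be at least 2.")
  }
  M1 <- as.integer(M1)
  M2 <- as.integer(M2)
  K1 <- difference_penalty(M1, 1)
  K2 <- difference_penalty(M2, 1)
  kronecker(diag(M2), K1) + kronecker(K2, diag(M1))
}

#' Construct the tensor-product spatial term
#'
#' Marginal B-spline bases over longitude and latitude with first-order
#' difference penalties combined into the four-nearest-neighbour grid
#' penalty.
#'
#' @param lon,lat Cluster coordinates.
#' @param n_segments Segments per marginal basis; a single number or a
#'   length-2 vector (lon, lat).
#' @param degree Marginal spline degree.
#' @param lon_range,lat_range Marginal domains; default observed ranges.
#' @return An object of class `tensor_term` with marginal knots, the tensor
#'   `basis`, the grid `penalty` and the grid dimensions `M1`, `M2`.
#' @export
tensor_term <- function(lon, lat, n_segments = 17, degree = 3,
                        lon_range = range(lon), lat_range = range(lat)) {
  n_segments <- rep(n_segments, length.out = 2)
  knots_lon <- make_knots(lon_range[1], lon_range[2], n_segments[1], degree)
  knots_lat <- make_knots(lat_range[1], lat_range[2], n_segments[2], degree)
  B <- tensor_basis(lon, lat, knots_lon, knots_lat)
  structure(
    list(
      knots_lon = knots_lon, knots_lat = knots_lat, basis = B,
      M1 = knots_lon$n_basis, M2 = knots_lat$n_basis,
      penalty = spatial_penalty(knots_lon$n_basis, knots_lat$n_basis),
      lon = lon, lat = lat
    ),
    class = "tensor_term"
  )
}

#' Mixed-model reparameterization of a penalized term
#'
#' Splits a penalized basis into an unpenalized null-space part and a
#' penalized part carrying an identity penalty, via the spectral
#' decomposition of the penalty matrix. Writing `K = U L U'`, the penalized
#' columns are `B U_+ L_+^{-1/2}` so their coefficients are exchangeable
#' random effects with variance `tau^2 = 1/lambda`; the null-space columns
#' `B U_0` are absorbed into the fixed effects. For difference penalties the
#' null space is spanned by known coefficient vectors (constant, and for
#' order 2 also linear), which are used directly so the null-space columns
#' are exactly the constant (absorbed by the model intercept) and, for
#' order-2 penalties, a linear function of the covariate.
#'
#' @param term A `spline_term` or `tensor_term`.
#' @return An object of class `reparam_term`: `X_pen` (penalized columns,
#'   identity penalty), `X_null` (null-space columns including the
#'   constant), `transform` (maps new basis rows to penalized columns),
#'   `null_coefs` (coefficient vectors spanning the null space),
#'   `null_dim`, and the originating `term`.
#' @export
reparameterize <- function(term) {
  if (!inherits(term, c("spline_term", "tensor_term"))) {
    abort("`term` must be a spline_term or tensor_term.")
  }
  K <- term$penalty
  M <- ncol(K)
  eg <- eigen(K, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  null_idx <- which(eg$values < tol)
  pen_idx <- which(eg$values >= tol)
  if (inherits(term, "spline_term")) {
    null_coefs <- switch(term$order, matrix(1, M, 1), cbind(1, seq_len(M)))
  } else {
    null_coefs <- matrix(1, M, 1)
  }
  if (length(null_idx) != ncol(null_coefs)) {
    abort("Penalty null-space dimension does not match the difference order.")
  }
  transform <- eg$vectors[, pen_idx, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pen_idx]), length(pen_idx))
  X_pen <- term$basis %*% transform
  X_null <- term$basis %*% null_coefs
  # the penalized block may be column-deficient when the data leave basis
  # regions empty (the identity penalty regularizes it); the unpenalized
  # null-space block must be identifiable on its own
  if (qr(X_null)$rank < ncol(X_null)) {
    abort("Rank-deficient basis after reparameterization (degenerate null space).")
  }
  structure(
    list(
      X_pen = X_pen, X_null = X_null, transform = transform,
      null_coefs = null_coefs, null_dim = ncol(null_coefs), term = term
    ),
    class = "reparam_term"
  )
}

# Evaluate the reparameterized columns of a term at new covariate values.
reparam_eval <- function(rep_term, ...) {
  term <- rep_term$term
  if (inherits(term, "spline_term")) {
    z <- list(...)$z
    B <- bspline_basis(z, term$knots)
  } else {
    pts <- list(...)
    B <- tensor_basis(pts$lon, pts$lat, term$knots_lon, term$knots_lat)
  }
  list(X_pen = B %*% rep_term$transform, X_null = B %*% rep_term$null_coefs)
}
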