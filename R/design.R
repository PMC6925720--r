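#' Model specification
#'
#' Declares which covariates enter the linear predictor and how: linear
#' fixed effects (categoricals are dummy-coded against fixed reference
#' levels: male, RDT negative, urban, no education, male household head, no
#' toilet facilities, Malawi), one optional P-spline smooth, an optional
#' tensor-product spatial surface, and two-way interactions formed as
#' products of non-reference dummies.
#'
#' @param linear Character vector of linear-term variables.
#' @param smooth Variable receiving the 1-D P-spline smooth (or `NULL`).
#' @param spatial Include the tensor-product spatial surface over
#'   `(lon, lat)`?
#' @param interactions List of length-2 character vectors naming variable
#'   pairs to interact.
#' @param smooth_segments,smooth_degree,smooth_order Knot segments, spline
#'   degree and penalty order of the 1-D smooth (defaults: 20 segments,
#'   cubic, second-order differences).
#' @param spatial_segments Knot segments per spatial marginal basis
#'   (default 17, i.e. 20 cubic basis functions per axis).
#' @param spatial_degree Spatial marginal spline degree.
#' @param alpha Significance level used by the screening helpers.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(linear = c("gender", "rdt_result", "household_size",
                                  "residence", "education", "head_gender",
                                  "toilet", "wealth_z", "country",
                                  "altitude", "evi", "lst"),
                       smooth = "age_months",
                       spatial = TRUE,
                       interactions = list(c("residence", "country")),
                       smooth_segments = 20, smooth_degree = 3,
                       smooth_order = 2,
                       spatial_segments = 17, spatial_degree = 3,
                       alpha = 0.10) {
  if (!is.null(smooth) && length(smooth) != 1) {
    abort("`smooth` must be a single variable name or NULL.")
  }
  if (!is.list(interactions) ||
      !all(vapply(interactions, length, integer(1)) == 2)) {
    abort("`interactions` must be a list of variable pairs.")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].")
  }
  structure(as.list(environment()), class = "model_spec")
}

# Continuous covariates entered on a rescaled reporting scale.
continuous_transforms <- function() {
  list(
    altitude = list(column = "altitude_100m", fn = function(x) x / 100),
    evi = list(column = "evi_1000", fn = function(x) x / 1000),
    lst = list(column = "lst", fn = identity),
    household_size = list(column = "household_size", fn = identity),
    wealth_z = list(column = "wealth_z", fn = identity),
    head_age = list(column = "head_age", fn = identity),
    age_months = list(column = "age_months", fn = identity)
  )
}

# Dummy columns (non-reference levels) for one categorical variable.
dummy_block <- function(data, var) {
  levels <- anaemia_levels()[[var]]
  vals <- data[[var]]
  bad <- which(!vals %in% levels)
  if (length(bad)) {
    abort(sprintf(
      "Row %d has level \"%s\" outside the closed set for column `%s`.",
      bad[1], vals[bad[1]], var
    ))
  }
  non_ref <- levels[-1]
  out <- vapply(non_ref, function(lv) as.numeric(vals == lv),
                numeric(nrow(data)))
  out <- matrix(out, nrow = nrow(data),
                dimnames = list(NULL, paste(var, non_ref, sep = "_")))
  out
}

# Columns for one linear term; continuous terms get their reporting scale.
linear_block <- function(data, var) {
  if (var %in% names(anaemia_levels())) return(dummy_block(data, var))
  tr <- continuous_transforms()[[var]]
  if (is.null(tr)) {
    if (!is.numeric(data[[var]])) {
      abort(sprintf("`%s` is neither a known categorical nor numeric.", var))
    }
    tr <- list(column = var, fn = identity)
  }
  matrix(tr$fn(data[[var]]), ncol = 1, dimnames = list(NULL, tr$column))
}

#' Encode the fixed-effect design
#'
#' Builds the fixed-effect design matrix with an intercept, dummy coding
#' against the fixed reference levels, interaction columns as products of
#' non-reference dummies, plus the district indicator information and the
#' raw inputs feeding the smooth terms.
#'
#' @param records Validated child records.
#' @param spec A [model_spec()].
#' @param require_outcome Passed to [validate_records()].
#' @return An object of class `design_matrices`: a list with `X` (fixed
#'   design with intercept), `district` (factor of district ids),
#'   `smooth_inputs` (tibble of raw smooth/spatial inputs), `y` (when
#'   present) and `column_map` (tibble: column, variable, level, reference,
#'   role).
#' @export
encode_design <- function(records, spec = model_spec(), require_outcome = TRUE) {
  records <- validate_records(records, require_outcome = require_outcome)
  levels <- anaemia_levels()
  blocks <- list(`(Intercept)` = matrix(1, nrow(records), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  map <- list(tibble::tibble(column = "(Intercept)", variable = "(Intercept)",
                             level = NA_character_, reference = NA_character_,
                             role = "parametric"))
  for (var in spec$linear) {
    blk <- linear_block(records, var)
    blocks[[var]] <- blk
    if (var %in% names(levels)) {
      map[[var]] <- tibble::tibble(
        column = colnames(blk), variable = var,
        level = levels[[var]][-1], reference = levels[[var]][1],
        role = "parametric"
      )
    } else {
      map[[var]] <- tibble::tibble(
        column = colnames(blk), variable = var, level = NA_character_,
        reference = NA_character_, role = "parametric"
      )
    }
  }
  for (pair in spec$interactions) {
    missing_terms <- setdiff(pair, spec$linear)
    if (length(missing_terms)) {
      abort(sprintf("Interaction term `%s` is not among the linear terms.",
                    missing_terms[1]))
    }
    b1 <- blocks[[pair[1]]]
    b2 <- blocks[[pair[2]]]
    cols <- matrix(0, nrow(records), ncol(b1) * ncol(b2))
    nm <- character(ncol(b1) * ncol(b2))
    k <- 0
    for (i in seq_len(ncol(b1))) {
      for (j in seq_len(ncol(b2))) {
        k <- k + 1
        cols[, k] <- b1[, i] * b2[, j]
        nm[k] <- paste(colnames(b1)[i], colnames(b2)[j], sep = ":")
      }
    }
    colnames(cols) <- nm
    blocks[[paste(pair, collapse = ":")]] <- cols
    map[[paste(pair, collapse = ":")]] <- tibble::tibble(
      column = nm, variable = paste(pair, collapse = ":"),
      level = sub("^[^_]*_", "", nm), reference = NA_character_,
      role = "interaction"
    )
  }
  X <- do.call(cbind, blocks)
  smooth_vars <- c(spec$smooth, if (isTRUE(spec$spatial)) c("lon", "lat"))
  smooth_inputs <- tibble::as_tibble(records[, intersect(smooth_vars, names(records))])
  structure(
    list(
      X = X,
      district = factor(records$district_id),
      country_by_district = records |>
        dplyr::distinct(.data$district_id, .data$country),
      smooth_inputs = smooth_inputs,
      y = if ("y" %in% names(records)) as.numeric(records$y),
      column_map = dplyr::bind_rows(map),
      spec = spec,
      records = records
    ),
    class = "design_matrices"
  )
}
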