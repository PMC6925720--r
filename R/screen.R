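# Prepare a data frame of properly releveled factors for glm-based
# screening models.
screening_frame <- function(records, vars) {
  levels <- anaemia_levels()
  cols <- lapply(vars, function(v) {
    if (v %in% names(levels)) {
      factor(records[[v]], levels = levels[[v]])
    } else {
      tr <- continuous_transforms()[[v]]
      if (is.null(tr)) records[[v]] else tr$fn(records[[v]])
    }
  })
  names(cols) <- vars
  out <- tibble::as_tibble(cols)
  out$y <- records$y
  out
}

#' Univariate screening of one candidate covariate
#'
#' Fits the single-covariate logistic model `y ~ x` and reports the
#' covariate's p-value: a likelihood-ratio test against the null model by
#' default (always used for multi-level categoricals), or a Wald test for a
#' single-column covariate. The covariate is kept when `p < alpha`
#' (default 10% level).
#'
#' @param records Validated child records with a `y` outcome.
#' @param variable Candidate covariate name.
#' @param alpha Screening level in (0, 1]; default 0.10.
#' @param test `"lr"` or `"wald"` (Wald falls back to LR for multi-level
#'   categoricals).
#' @return A one-row tibble: `variable`, `df`, `p_value`, `keep`, `test`.
#' @export
univariate_screen <- function(records, variable, alpha = 0.10,
                              test = c("lr", "wald")) {
  test <- match.arg(test)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].")
  }
  records <- validate_records(records)
  if (length(unique(records$y)) < 2) {
    abort("Outcome is constant; the screening model is inestimable.")
  }
  df <- screening_frame(records, variable)
  fit <- glm(y ~ ., data = df, family = binomial())
  k <- length(coef(fit)) - 1L
  if (test == "wald" && k == 1L) {
    z <- coef(fit)[2] / sqrt(diag(vcov(fit)))[2]
    p <- 2 * pnorm(-abs(z))
    used <- "wald"
  } else {
    p <- pchisq(fit$null.deviance - fit$deviance, df = k, lower.tail = FALSE)
    used <- "lr"
  }
  tibble::tibble(variable = variable, df = k, p_value = unname(p),
                 keep = unname(p) < alpha, test = used)
}

#' Screen several candidate covariates
#'
#' Applies [univariate_screen()] to each candidate and binds the rows.
#'
#' @inheritParams univariate_screen
#' @param candidates Character vector of covariate names.
#' @return A tibble with one row per candidate.
#' @export
screen_covariates <- function(records, candidates, alpha = 0.10,
                              test = c("lr", "wald")) {
  test <- match.arg(test)
  purrr::map_dfr(candidates, function(v) {
    univariate_screen(records, v, alpha = alpha, test = test)
  })
}

#' Screen all two-way interactions of the fixed effects
#'
#' For every pair of fixed-effect terms, compares the main-effects logistic
#' model with the model augmented by that pair's interaction using a
#' likelihood-ratio test. Pairs whose augmented model cannot be estimated
#' (separation, non-convergence) are skipped with a warning.
#'
#' @param records Validated child records with a `y` outcome.
#' @param fixed_terms Character vector (>= 2) of fixed-effect variables.
#' @param alpha Significance level for flagging a pair.
#' @return A tibble: `term1`, `term2`, `df`, `p_value`, `significant`,
#'   sorted by p-value.
#' @export
screen_interactions <- function(records, fixed_terms, alpha = 0.10) {
  if (length(fixed_terms) < 2) {
    return(tibble::tibble(term1 = character(), term2 = character(),
                          df = integer(), p_value = numeric(),
                          significant = logical()))
  }
  records <- validate_records(records)
  df <- screening_frame(records, fixed_terms)
  main <- glm(y ~ ., data = df, family = binomial())
  pairs <- utils::combn(fixed_terms, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    fml <- stats::as.formula(
      paste0("y ~ . + `", pr[1], "`:`", pr[2], "`")
    )
    aug <- tryCatch(
      suppressWarnings(stats::update(main, fml)),
      error = function(e) NULL
    )
    if (is.null(aug) || !aug$converged ||
        aug$df.residual >= main$df.residual) {
      warn(sprintf("Interaction %s:%s skipped (model inestimable).",
                   pr[1], pr[2]))
      return(NULL)
    }
    k <- main$df.residual - aug$df.residual
    p <- pchisq(main$deviance - aug$deviance, df = k, lower.tail = FALSE)
    tibble::tibble(term1 = pr[1], term2 = pr[2], df = k,
                   p_value = unname(p), significant = unname(p) < alpha)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$p_value)
}
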