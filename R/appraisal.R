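#' Extract district BLUPs from a fit
#'
#' The best linear unbiased predictions of the district random effects
#' (realised district-level deviations on the log-odds scale) with their
#' prediction standard errors. Districts with more sampled children shrink
#' less toward zero. A negative BLUP marks a district associated with
#' decreased odds of anaemia. If the district variance was estimated at the
#' boundary (reported 0), all BLUPs are exactly 0 and a warning is issued.
#'
#' @param fit An `anaemia_gamm` fit.
#' @return A tibble: `district_id`, `country`, `n_children`, `blup`,
#'   `prediction_se`.
#' @export
extract_blups <- function(fit) {
  stopifnot(inherits(fit, "anaemia_gamm"))
  out <- fit$blups |>
    dplyr::select("district_id", "country", "n_children", "blup",
                  "prediction_se")
  if (isTRUE(fit$theta_boundary[["sigma2_district"]])) {
    warn(paste0("District variance was estimated at the zero boundary; ",
                "all BLUPs are 0."))
    out$blup <- 0
  }
  out
}

#' Standardize district BLUPs
#'
#' Default (`method = "se"`): each BLUP divided by its own prediction
#' standard error, a conditional z-like score that accounts for unequal
#' district sample sizes. Alternative (`method = "zscore"`): the BLUPs
#' z-scored across districts (mean 0, SD 1). Signs are preserved either
#' way.
#'
#' @param blups Tibble from [extract_blups()].
#' @param method `"se"` or `"zscore"`.
#' @return `blups` with a `standardized` column added.
#' @export
standardize_blups <- function(blups, method = c("se", "zscore")) {
  method <- match.arg(method)
  stop_not_df(blups, "blups")
  if (nrow(blups) < 2) abort("Need at least 2 districts to standardize.")
  if (method == "se") {
    if (any(blups$prediction_se <= 0)) {
      abort("Zero prediction SE; cannot standardize by SE.")
    }
    std <- blups$blup / blups$prediction_se
  } else {
    s <- sd(blups$blup)
    if (s == 0) abort("All BLUPs are equal; the z-score variant is undefined.")
    std <- (blups$blup - mean(blups$blup)) / s
  }
  dplyr::mutate(blups, standardized = std)
}

#' Rank districts and flag the best and worst performers
#'
#' Sorts standardized BLUPs in ascending order (within country by default)
#' and flags the first `k` as best-performing (lowest standardized BLUP,
#' decreased odds of anaemia) and the last `k` as worst-performing. Ties
#' are broken deterministically by district identifier.
#'
#' @param appraisal Tibble from [standardize_blups()].
#' @param k Number of districts to flag at each end (default 3).
#' @param within `"country"` (rank within each country) or `"global"`.
#' @return The tibble with `rank` (1 = lowest standardized BLUP within the
#'   ranking group) and `flag` (`"best"`, `"worst"` or `NA`) added, sorted
#'   by group and rank.
#' @export
rank_districts <- function(appraisal, k = 3, within = c("country", "global")) {
  within <- match.arg(within)
  stop_not_df(appraisal, "appraisal")
  if (!is_scalar_number(k) || k < 1) abort("`k` must be a positive integer.")
  if (!"standardized" %in% names(appraisal)) {
    abort("`appraisal` must carry a `standardized` column; see standardize_blups().")
  }
  grouped <- if (within == "country") {
    dplyr::group_by(appraisal, .data$country)
  } else {
    dplyr::group_by(appraisal, group = 1)
  }
  sizes <- dplyr::summarise(grouped, n = dplyr::n())
  if (any(sizes$n < k)) {
    abort(sprintf("`k` = %d exceeds the %d district(s) in some ranking group.",
                  as.integer(k), min(sizes$n)))
  }
  out <- grouped |>
    dplyr::arrange(.data$standardized, .data$district_id, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      flag = dplyr::case_when(
        rank <= k ~ "best",
        rank > dplyr::n() - k ~ "worst",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::ungroup()
  if (within == "global") out$group <- NULL
  out
}

#' District performance appraisal
#'
#' Convenience wrapper: [extract_blups()], [standardize_blups()] and
#' [rank_districts()] in one call.
#'
#' @param fit An `anaemia_gamm` fit.
#' @param k Number of best/worst districts to flag per ranking group.
#' @param method Standardization method, see [standardize_blups()].
#' @param within Ranking scope, see [rank_districts()].
#' @return The ranked appraisal tibble.
#' @export
appraise_districts <- function(fit, k = 3, method = c("se", "zscore"),
                               within = c("country", "global")) {
  rank_districts(
    standardize_blups(extract_blups(fit), method = method),
    k = k, within = within
  )
}
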