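#' Altitude correction for haemoglobin
#'
#' The CDC/DHS altitude adjustment for haemoglobin measurements: with `A`
#' the altitude in thousands of feet, the correction in g/dl is
#' `max(0, -0.032 * A + 0.022 * A^2)`. The quadratic is negative (so the
#' correction is zero) below about 443 m and is nondecreasing above that.
#'
#' @param altitude Altitude in metres.
#' @return Nonnegative correction in g/dl, to be subtracted from measured Hb.
#' @export
hb_altitude_correction <- function(altitude) {
  if (!is.numeric(altitude) || any(!is.finite(altitude))) {
    abort("`altitude` must be finite.")
  }
  A <- altitude * 3.28084 / 1000
  pmax(0, -0.032 * A + 0.022 * A^2)
}

#' Adjust measured haemoglobin for cluster altitude
#'
#' Subtracts a nonnegative altitude correction from the measured Hb so that
#' sea-level WHO thresholds apply. The correction function is swappable;
#' the default is the CDC/DHS quadratic of [hb_altitude_correction()].
#'
#' @param hb Measured haemoglobin, g/dl (> 0).
#' @param altitude Altitude in metres.
#' @param correction Function mapping altitude (m) to a nonnegative g/dl
#'   correction.
#' @return Adjusted haemoglobin, g/dl.
#' @export
adjust_hb_for_altitude <- function(hb, altitude,
                                   correction = hb_altitude_correction) {
  if (!is.numeric(hb) || any(!is.finite(hb))) abort("`hb` must be finite.")
  if (any(hb <= 0)) abort("`hb` must be positive (g/dl).")
  hb - correction(altitude)
}

#' Classify anaemia from adjusted haemoglobin
#'
#' WHO definition for children aged 6-59 months: anaemic if the
#' altitude-adjusted Hb is strictly below 11 g/dl.
#'
#' @param adjusted_hb Altitude-adjusted haemoglobin, g/dl.
#' @param threshold Threshold in g/dl (default 11).
#' @return Integer vector of 0/1 outcomes (1 = anaemic).
#' @export
classify_anaemia <- function(adjusted_hb, threshold = 11) {
  if (!is.numeric(adjusted_hb) || any(!is.finite(adjusted_hb))) {
    abort("`adjusted_hb` must be finite.")
  }
  as.integer(adjusted_hb < threshold)
}

# Closed categorical level sets (first level = reference, matching the
# model's reporting conventions: male, RDT negative, urban, no education,
# male household head, no toilet facilities, Malawi).
anaemia_levels <- function() {
  list(
    gender = c("male", "female"),
    rdt_result = c("negative", "positive"),
    residence = c("urban", "rural"),
    education = c("none", "primary", "secondary_higher", "unknown"),
    toilet = c("none", "pit", "flush", "other"),
    head_gender = c("male", "female"),
    country = c("Malawi", "Kenya", "Tanzania", "Uganda")
  )
}

#' Validate child records
#'
#' Checks the closed categorical level sets, the age range (6-59 months),
#' household size >= 1 and, when present, a binary outcome. With
#' `action = "error"` (default) the first violation is an error naming the
#' row and column; with `action = "drop"` offending rows are removed and a
#' validation report is returned.
#'
#' @param data Child records.
#' @param action `"error"` or `"drop"`.
#' @param require_outcome Require a 0/1 `y` column (or `hb` + `altitude`
#'   from which it can be derived)?
#' @return For `"error"`, the validated tibble. For `"drop"`, a list with
#'   `records` and a `report` tibble (`reason`, `n`).
#' @export
validate_records <- function(data, action = c("error", "drop"),
                             require_outcome = TRUE) {
  stop_not_df(data)
  action <- match.arg(action)
  data <- tibble::as_tibble(data)
  levels <- anaemia_levels()
  bad <- list()
  for (col in intersect(names(levels), names(data))) {
    ok <- data[[col]] %in% levels[[col]]
    if (!all(ok)) {
      bad[[paste0("invalid level in `", col, "`")]] <- which(!ok)
      if (action == "error") {
        abort(sprintf(
          "Row %d has level \"%s\" outside the closed set for column `%s`.",
          which(!ok)[1], data[[col]][which(!ok)[1]], col
        ))
      }
    }
  }
  if ("age_months" %in% names(data)) {
    ok <- is.finite(data$age_months) & data$age_months >= 6 & data$age_months <= 59
    if (!all(ok)) {
      bad[["age_months outside 6-59"]] <- which(!ok)
      if (action == "error") abort(sprintf("Row %d: age_months outside 6-59.", which(!ok)[1]))
    }
  }
  if ("household_size" %in% names(data)) {
    ok <- is.finite(data$household_size) & data$household_size >= 1
    if (!all(ok)) {
      bad[["household_size < 1"]] <- which(!ok)
      if (action == "error") abort(sprintf("Row %d: household_size < 1.", which(!ok)[1]))
    }
  }
  if (require_outcome) {
    if (!"y" %in% names(data) && all(c("hb", "altitude") %in% names(data))) {
      data$y <- classify_anaemia(adjust_hb_for_altitude(data$hb, data$altitude))
    }
    if (!"y" %in% names(data)) {
      abort("Records need a binary `y` outcome, or `hb` and `altitude` to derive it.")
    }
    ok <- data$y %in% c(0L, 1L)
    if (!all(ok)) {
      bad[["y not in {0, 1}"]] <- which(!ok)
      if (action == "error") abort(sprintf("Row %d: `y` must be 0 or 1.", which(!ok)[1]))
    }
  }
  if (action == "error") return(data)
  drop_rows <- sort(unique(unlist(bad)))
  report <- tibble::tibble(
    reason = names(bad),
    n = unname(vapply(bad, length, integer(1)))
  )
  list(records = if (length(drop_rows)) data[-drop_rows, ] else data,
       report = report)
}

#' Read child records from CSV
#'
#' Reads a one-row-per-child table (the column dictionary of
#' [generate_cohort()] / [simulate_outcomes()]) and validates it.
#'
#' @param path CSV path.
#' @param ... Passed to [validate_records()].
#' @return A validated tibble.
#' @export
read_children_csv <- function(path, ...) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_records(data, ...)
}
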