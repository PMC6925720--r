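#' Geography configuration for the synthetic survey generator
#'
#' Describes the nested country / district / cluster structure to simulate:
#' how many districts each country has, how clusters are allocated to
#' districts, each country's bounding box (degrees), and the fraction of
#' clusters labelled urban. The default is a scaled-down four-country
#' geography (10 districts per country, 4 clusters per district) with
#' bounding boxes loosely shaped like Kenya, Malawi, Tanzania and Uganda;
#' [geography_config_full()] mirrors the full survey shape of 370 districts
#' and 1595 clusters.
#'
#' @param countries Character vector of country labels.
#' @param districts_per_country Positive integer(s), one per country.
#' @param clusters_per_district A single positive integer, or a length-2
#'   range `c(lo, hi)` from which per-district cluster counts are drawn.
#' @param total_clusters Optional total cluster count; when given, clusters
#'   are allocated deterministically (floor share per district, remainder to
#'   the first districts in order) and `clusters_per_district` is ignored.
#' @param bounding_boxes Named list (one per country) of
#'   `c(lon_min, lon_max, lat_min, lat_max)` rectangles.
#' @param urban_fraction Probability a cluster is labelled urban, in [0, 1].
#' @return An object of class `geography_config`.
#' @export
geography_config <- function(countries = c("Kenya", "Malawi", "Tanzania", "Uganda"),
                             districts_per_country = rep(10L, length(countries)),
                             clusters_per_district = 4L,
                             total_clusters = NULL,
                             bounding_boxes = default_bounding_boxes(countries),
                             urban_fraction = 0.25) {
  if (length(countries) == 0) abort("`countries` must be a nonempty character vector.")
  if (anyDuplicated(countries)) abort("`countries` must be unique.")
  districts_per_country <- rep(as.integer(districts_per_country),
                               length.out = length(countries))
  if (any(districts_per_country < 1)) abort("Each country needs at least one district.")
  if (!all(countries %in% names(bounding_boxes))) {
    abort("`bounding_boxes` must contain an entry for every country.")
  }
  for (cn in countries) {
    bb <- bounding_boxes[[cn]]
    if (length(bb) != 4 || bb[2] <= bb[1] || bb[4] <= bb[3]) {
      abort(sprintf("Degenerate bounding box for %s (zero area).", cn))
    }
  }
  if (!is_scalar_number(urban_fraction) || urban_fraction < 0 || urban_fraction > 1) {
    abort("`urban_fraction` must lie in [0, 1].")
  }
  if (is.null(total_clusters)) {
    if (!length(clusters_per_district) %in% 1:2 || any(clusters_per_district < 1)) {
      abort("`clusters_per_district` must be a positive integer or range.")
    }
  } else if (!is_scalar_number(total_clusters) ||
             total_clusters < sum(districts_per_country)) {
    abort("`total_clusters` must be at least one cluster per district.")
  }
  structure(
    list(
      countries = countries,
      districts_per_country = setNames(districts_per_country, countries),
      clusters_per_district = as.integer(clusters_per_district),
      total_clusters = if (!is.null(total_clusters)) as.integer(total_clusters),
      bounding_boxes = bounding_boxes,
      urban_fraction = urban_fraction
    ),
    class = "geography_config"
  )
}

# Rectangles roughly shaped like the four study countries (degrees).
default_bounding_boxes <- function(countries) {
  boxes <- list(
    Kenya    = c(34.0, 41.9, -4.7, 5.0),
    Malawi   = c(32.7, 35.9, -17.1, -9.4),
    Tanzania = c(29.3, 40.4, -11.7, -1.0),
    Uganda   = c(29.6, 35.0, -1.5, 4.2)
  )
  extra <- setdiff(countries, names(boxes))
  for (i in seq_along(extra)) {
    boxes[[extra[i]]] <- c(0, 5, 10 * (i - 1), 10 * (i - 1) + 5)
  }
  boxes
}

#' Full-scale geography configuration
#'
#' The survey-scale shape: 47 Kenyan counties, 26 Malawian districts, 176
#' mainland-Tanzanian districts and 121 Ugandan districts (370 in total)
#' with 1595 clusters allocated across them.
#'
#' @param ... Passed on to [geography_config()] to override defaults.
#' @export
geography_config_full <- function(...) {
  geography_config(
    districts_per_country = c(Kenya = 47L, Malawi = 26L, Tanzania = 176L,
                              Uganda = 121L),
    total_clusters = 1595L,
    ...
  )
}

#' Generate a nested synthetic geography
#'
#' Draws the country / district / cluster skeleton described by a
#' [geography_config()]: unique district and cluster identifiers, cluster
#' coordinates uniform within the owning country's bounding box, and an
#' urban/rural label per cluster.
#'
#' @param config A `geography_config`.
#' @param seed Integer seed; the same `(config, seed)` pair regenerates the
#'   identical geography.
#' @return An object of class `geography`: a list with tibbles `districts`
#'   (`country`, `district_id`) and `clusters` (`country`, `district_id`,
#'   `cluster_id`, `lon`, `lat`, `residence`).
#' @export
generate_geography <- function(config = geography_config(), seed = 1L) {
  if (!inherits(config, "geography_config")) {
    abort("`config` must come from geography_config().")
  }
  local_seed(seed, {
    districts <- purrr::map_dfr(config$countries, function(cn) {
      nd <- config$districts_per_country[[cn]]
      tibble::tibble(
        country = cn,
        district_id = sprintf("%s_d%03d", cn, seq_len(nd))
      )
    })
    n_district <- nrow(districts)
    if (!is.null(config$total_clusters)) {
      base <- config$total_clusters %/% n_district
      n_clusters <- rep(base, n_district)
      extra <- config$total_clusters - base * n_district
      if (extra > 0) n_clusters[seq_len(extra)] <- base + 1L
    } else if (length(config$clusters_per_district) == 2L) {
      n_clusters <- sample(
        config$clusters_per_district[1]:config$clusters_per_district[2],
        n_district, replace = TRUE
      )
    } else {
      n_clusters <- rep(config$clusters_per_district, n_district)
    }
    clusters <- districts |>
      dplyr::mutate(.n_clusters = n_clusters) |>
      tidyr::uncount(.data$.n_clusters, .id = "cluster_num") |>
      dplyr::mutate(
        cluster_id = sprintf("%s_c%02d", .data$district_id, .data$cluster_num)
      ) |>
      dplyr::select(-"cluster_num")
    coords <- purrr::map_dfr(split(clusters, clusters$country)[unique(clusters$country)],
      function(cl) {
        bb <- config$bounding_boxes[[cl$country[1]]]
        tibble::tibble(
          cluster_id = cl$cluster_id,
          lon = runif(nrow(cl), bb[1], bb[2]),
          lat = runif(nrow(cl), bb[3], bb[4])
        )
      })
    clusters <- clusters |>
      dplyr::left_join(coords, by = "cluster_id") |>
      dplyr::mutate(
        residence = ifelse(runif(dplyr::n()) < config$urban_fraction,
                           "urban", "rural")
      ) |>
      tibble::as_tibble()
    structure(
      list(districts = tibble::as_tibble(districts), clusters = clusters,
           config = config, seed = as.integer(seed)),
      class = "geography"
    )
  })
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf(
    "<geography> %d countries, %d districts, %d clusters\n",
    length(unique(x$districts$country)), nrow(x$districts), nrow(x$clusters)
  ))
  invisible(x)
}
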