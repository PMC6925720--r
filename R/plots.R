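#' Plot the estimated nonlinear age effect
#'
#' Line with pointwise confidence ribbon for the centered smooth of age in
#' months on the log-odds of anaemia.
#'
#' @param fit An `anaemia_gamm` fit.
#' @param grid,conf.level Passed to [smooth_curve()].
#' @return A ggplot object.
#' @export
plot_age_effect <- function(fit, grid = NULL, conf.level = 0.95) {
  curve <- smooth_curve(fit, grid = grid, conf.level = conf.level)
  xvar <- names(curve)[1]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data[[xvar]], y = .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Age (months)", y = "Effect on log-odds of anaemia")
}

#' Map the estimated cluster-level spatial effect
#'
#' Cluster points colored by the centered spatial effect on the log-odds
#' scale (blue = decreased risk, red = increased risk).
#'
#' @param fit An `anaemia_gamm` fit.
#' @param points Passed to [spatial_surface()].
#' @return A ggplot object.
#' @export
plot_spatial_effect <- function(fit, points = NULL) {
  surf <- spatial_surface(fit, points = points)
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$lon, y = .data$lat,
                                     colour = .data$estimate)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "lightyellow",
                                    high = "red", midpoint = 0) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  colour = "Spatial effect\n(log-odds)")
}

#' Plot the district appraisal
#'
#' Standardized district BLUPs ordered within country, best/worst flags
#' highlighted.
#'
#' @param appraisal Output of [appraise_districts()] / [rank_districts()].
#' @return A ggplot object.
#' @export
plot_district_blups <- function(appraisal) {
  stop_not_df(appraisal, "appraisal")
  ggplot2::ggplot(
    appraisal,
    ggplot2::aes(x = .data$rank, y = .data$standardized,
                 colour = .data$flag %||% NA)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~country, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(best = "blue", worst = "black"), na.value = "grey60"
    ) +
    ggplot2::labs(x = "Rank (1 = lowest standardized BLUP)",
                  y = "Standardized BLUP", colour = NULL)
}

#' Plot total residence-by-country effects
#'
#' Point-and-interval display of the total log-odds contribution of each
#' residence-by-country cell relative to urban Malawi.
#'
#' @param fit An `anaemia_gamm` fit.
#' @return A ggplot object.
#' @export
plot_total_effects <- function(fit) {
  cells <- total_residence_country_effects(fit)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$country,
                                      y = .data$total_log_odds,
                                      colour = .data$residence)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Total effect on log-odds of anaemia",
                  colour = "Residence")
}

#' @exportS3Method ggplot2::autoplot
#' @importFrom ggplot2 autoplot
#' @rdname plot_age_effect
#' @param object An `anaemia_gamm` fit.
#' @param type One of `"age"`, `"spatial"`, `"total_effects"`.
#' @param ... Unused.
autoplot.anaemia_gamm <- function(object, type = c("age", "spatial",
                                                   "total_effects"), ...) {
  type <- match.arg(type)
  switch(type,
    age = plot_age_effect(object),
    spatial = plot_spatial_effect(object),
    total_effects = plot_total_effects(object)
  )
}
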