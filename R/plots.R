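#' @importFrom ggplot2 ggplot aes geom_density geom_histogram geom_vline
#'   geom_pointrange geom_col facet_wrap labs theme_minimal after_stat
NULL

# Long format of a fit's top-level draws.
top_draws_long <- function(draws) {
  draws %>%
    select(-".chain", -".iteration", -".draw") %>%
    tidyr::pivot_longer(everything(), names_to = "parameter")
}

#' Posterior densities of the area-model parameters
#'
#' @param object An `area_fit`.
#' @param ... Unused.
#' @return A ggplot: one density panel per top-level parameter.
#' @method autoplot area_fit
#' @export
autoplot.area_fit <- function(object, ...) {
  ggplot(top_draws_long(object$draws), aes(x = .data$value)) +
    geom_density(fill = "grey70", colour = NA) +
    facet_wrap(~parameter, scales = "free") +
    labs(x = NULL, y = "posterior density",
         title = "Hunting-area model posterior") +
    theme_minimal()
}

#' Posterior densities of a harvest model's parameters
#'
#' @param object A `harvest_fit`.
#' @param ... Unused.
#' @return A ggplot: one density panel per top-level parameter.
#' @method autoplot harvest_fit
#' @export
autoplot.harvest_fit <- function(object, ...) {
  ggplot(top_draws_long(object$draws), aes(x = .data$value)) +
    geom_density(fill = "grey70", colour = NA) +
    facet_wrap(~parameter, scales = "free") +
    labs(x = NULL, y = "posterior density",
         title = paste("Harvest model", object$spec$name, "posterior")) +
    theme_minimal()
}

#' Posterior predictive distribution of a total harvest
#'
#' Histogram of the predicted total (reported + unreported) harvest at the
#' chosen level, with the reported harvest marked.
#'
#' @param object A `harvest_prediction`.
#' @param data The `harvest_data` predicted for.
#' @param level,unit_id Aggregation level and optional unit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot harvest_prediction
#' @export
autoplot.harvest_prediction <- function(object, data,
                                        level = "nation", unit_id = NULL,
                                        ...) {
  totals <- prediction_totals(object, level, unit_id)
  rep_tab <- reported_totals(data, level, unit_id)
  totals <- totals %>%
    left_join(rep_tab, by = "unit_id") %>%
    mutate(total = .data$kappa + .data$reported)
  ggplot(totals, aes(x = .data$total)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 40,
                   fill = "grey70") +
    geom_vline(aes(xintercept = .data$reported), linetype = 2) +
    labs(x = "total harvest (animals)", y = "predictive density",
         title = paste0("Predicted ", level, " harvest (",
                        attr(object, "model"), ")"),
         subtitle = "dashed: reported harvest") +
    theme_minimal()
}

#' Model comparison by ELPD difference
#'
#' @param object A comparison tibble from [compare_elpd()].
#' @param ... Unused.
#' @return A ggplot of ELPD differences with 2-SE error bars.
#' @export
plot_elpd_comparison <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$model, .data$elpd_diff),
                     y = .data$elpd_diff)) +
    geom_pointrange(aes(ymin = .data$elpd_diff - 2 * .data$se_diff,
                        ymax = .data$elpd_diff + 2 * .data$se_diff)) +
    labs(x = NULL, y = "ELPD difference vs best model",
         subtitle = "bars: 2 SE of pointwise differences") +
    theme_minimal()
}
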