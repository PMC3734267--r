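#' Plot module scores by listing status
#'
#' Mean module score per status group with across-taxon standard-error
#' bars, in the style of a grouped bar chart with one panel position per
#' module.
#'
#' @param ci Tibble from [mc_uncertainty_ci()] including a `status` column.
#' @return A ggplot object.
#' @export
plot_module_scores <- function(ci) {
  stopifnot(all(c("module", "status", "point") %in% names(ci)))
  smry <- ci |>
    dplyr::group_by(.data$module, .data$status) |>
    dplyr::summarise(
      mean = mean(.data$point),
      se = sd(.data$point) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(module = factor(.data$module, levels = SIVVA_MODULES))
  ggplot2::ggplot(smry, ggplot2::aes(
    x = .data$module, y = .data$mean, fill = .data$status
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7,
                      colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::scale_fill_manual(values = c(listed = "grey40", nonlisted = "white")) +
    ggplot2::labs(x = NULL, y = "Module score", fill = "Status") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
}

#' Plot normalised trait values by status
#'
#' Boxplots of proportion-of-maximum trait values per trait and listing
#' status.
#'
#' @param trait_norm Tibble from [proportion_of_max()].
#' @return A ggplot object.
#' @export
plot_trait_values <- function(trait_norm) {
  stopifnot(all(c("trait", "status", "prop_max") %in% names(trait_norm)))
  ggplot2::ggplot(trait_norm, ggplot2::aes(
    x = .data$trait, y = .data$prop_max, fill = .data$status
  )) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8)) +
    ggplot2::scale_fill_manual(values = c(listed = "grey40", nonlisted = "white")) +
    ggplot2::labs(x = NULL, y = "Proportion of pair maximum", fill = "Status") +
    ggplot2::theme_classic()
}

#' Plot a weight-permutation distribution
#'
#' Histogram of permuted module scores with the observed score marked.
#'
#' @param wp A `sivva_weight_perm` from [permute_weights()].
#' @return A ggplot object.
#' @export
plot_weight_permutation <- function(wp) {
  stopifnot(inherits(wp, "sivva_weight_perm"))
  df <- tibble::tibble(score = wp$permuted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "black") +
    ggplot2::geom_vline(xintercept = wp$observed, linetype = 2) +
    ggplot2::labs(
      x = "Permuted module score", y = "Count",
      title = sprintf("%s / %s: observed %.3f", wp$taxon_id, wp$module,
                      wp$observed)
    ) +
    ggplot2::theme_classic()
}
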