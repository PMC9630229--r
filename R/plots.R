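#' Plot standardised centroid profiles of a cluster model
#'
#' Bars of the standardised centroid coordinate per classifier and cluster,
#' the usual way to read the clinical phenotype of each subgroup.
#'
#' @param object A `cluster_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_model <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(object$classifiers),
                        names_to = "classifier", values_to = "centroid")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$centroid,
                                   fill = .data$subgroup)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Standardised centroid", fill = "Subgroup") +
    ggplot2::theme_minimal()
}

#' Plot the majority-vote distribution over candidate k
#'
#' @param object A `k_vote` from [select_k_majority_vote()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_vote <- function(object, ...) {
  ggplot2::ggplot(object$votes, ggplot2::aes(x = factor(.data$k), y = .data$votes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Number of clusters", y = "Votes") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster bootstrap Jaccard distributions
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  df <- tibble::as_tibble(object$per_bootstrap, .name_repair = ~ paste0("cluster", seq_along(.x))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "cluster",
                        values_to = "jaccard")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$jaccard)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0.86, linetype = 2, colour = "red") +
    ggplot2::labs(x = NULL, y = "Bootstrap Jaccard index") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param km Tibble from [km_estimate()] (optionally with a `group`
#'   column).
#' @param cumulative Plot cumulative incidence `1 - S(t)` (default) rather
#'   than survival.
#' @return A ggplot object.
#' @export
plot_km <- function(km, cumulative = TRUE) {
  km$y <- if (cumulative) 1 - km$survival else km$survival
  aes <- if ("group" %in% names(km)) {
    ggplot2::aes(x = .data$time, y = .data$y, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$y)
  }
  ggplot2::ggplot(km, aes) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years of follow-up",
                  y = if (cumulative) "Cumulative incidence" else "Survival",
                  colour = "Subgroup") +
    ggplot2::theme_minimal()
}

#' Heatmap of row-standardised subgroup means of significant lipids
#'
#' @param z Matrix from [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_lipid_heatmap <- function(z) {
  df <- tibble::as_tibble(z, rownames = "species_id") |>
    tidyr::pivot_longer(-"species_id", names_to = "subgroup",
                        values_to = "z")
  df$species_id <- factor(df$species_id, levels = rev(rownames(z)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subgroup, y = .data$species_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Row z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
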