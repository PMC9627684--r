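#' Bar chart of skeleton voxel-class distribution
#'
#' Proportions of endpoints, vessel, bifurcation and crossing points among
#' the included skeleton voxels — the at-a-glance summary of vascular
#' morphology. In cohort form (a data frame with the count columns and a
#' grouping column such as `scheduled_week`) the proportions are shown per
#' group.
#'
#' @param x an `upvs_classification`, `upvs_morphology`, or a data frame
#'   with `n_end`, `n_vessel`, `n_bif`, `n_cross` columns.
#' @param by optional grouping column for the data-frame form.
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(x, by = NULL) {
  if (inherits(x, "upvs_morphology")) x <- x$classification
  if (inherits(x, "upvs_classification")) {
    d <- tibble(class = c("endpoint", "vessel", "bifurcation", "crossing"),
                n = unname(x$counts[c("n_end", "n_vessel", "n_bif", "n_cross")]),
                group = "all")
  } else {
    stopifnot(all(c("n_end", "n_vessel", "n_bif", "n_cross") %in% names(x)))
    g <- if (is.null(by)) rep("all", nrow(x)) else x[[by]]
    d <- tidyr::pivot_longer(
      dplyr::summarise(dplyr::group_by(tibble(group = as.factor(g),
                                              endpoint = x$n_end, vessel = x$n_vessel,
                                              bifurcation = x$n_bif, crossing = x$n_cross),
                                       .data$group),
                       dplyr::across(dplyr::everything(), sum)),
      -"group", names_to = "class", values_to = "n")
  }
  d$class <- factor(d$class, c("endpoint", "vessel", "bifurcation", "crossing"))
  d <- dplyr::mutate(dplyr::group_by(d, .data$group),
                     prop = .data$n / sum(.data$n))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$prop,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "stack", colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(endpoint = "#c0392b", vessel = "grey95",
                                          bifurcation = "#27ae60", crossing = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "proportion of skeleton voxels", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.upvs_classification <- function(object, ...) plot_class_distribution(object)

#' @export
autoplot.upvs_morphology <- function(object, ...) plot_class_distribution(object)

#' Scatter of observations on the first two principal components
#'
#' @param object an `upvs_pca` from [pca_characteristics()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.upvs_pca <- function(object, ...) {
  d <- tibble(PC1 = object$scores[, 1], PC2 = object$scores[, 2])
  ev <- round(100 * object$explained_variance[1:2], 1)
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(colour = "#2980b9", alpha = 0.7) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Longitudinal trajectories of a characteristic over gestational age
#'
#' Spaghetti plot of per-subject trajectories with the cohort median per
#' scheduled week; optionally coloured by a binary stratum.
#'
#' @param cohort data frame with `id`, `ga_weeks` and the variable.
#' @param variable column to plot.
#' @param by optional stratifier column (e.g. `"complication"`).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cohort, variable, by = NULL) {
  stopifnot(all(c("id", "ga_weeks", variable) %in% names(cohort)))
  d <- tibble(id = cohort$id, ga = cohort$ga_weeks, y = cohort[[variable]],
              g = if (is.null(by)) "all" else as.factor(cohort[[by]]))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$ga, .data$y, group = .data$id,
                                       colour = .data$g)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_point(size = 0.6, alpha = 0.4) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$g), fun = median,
                          geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "gestational age (weeks)", y = variable,
                  colour = by %||% NULL) +
    ggplot2::theme_minimal()
  if (is.null(by)) p + ggplot2::guides(colour = "none") else p
}
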