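#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot intra- versus inter-individual similarity distributions
#'
#' Violin plot of the per-subject intra- and inter-individual similarities
#' underlying an identifiability test, the standard visual for whether
#' predictions favour their own subject.
#'
#' @param object An `fc_identifiability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_identifiability <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("r_intra", "r_inter"),
                        names_to = "kind", values_to = "similarity") |>
    dplyr::mutate(kind = factor(.data$kind, c("r_intra", "r_inter"),
                                c("intra", "inter")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kind, y = .data$similarity,
                                     fill = .data$kind)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA,
                          show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "similarity",
      subtitle = sprintf("t = %.3g, df = %d, p = %.3g (%s)",
                         object$t_statistic, object$df, object$p_value,
                         object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a matching-accuracy curve
#'
#' Matching accuracy versus subset size for the model and chance conditions,
#' with the analytic `100/n` chance level and asterisks marking sizes that
#' stay significant after FDR adjustment.
#'
#' @param object An `fc_matching_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_matching_curve <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("accuracy_model", "accuracy_null"),
                        names_to = "condition", values_to = "accuracy") |>
    dplyr::mutate(condition = factor(.data$condition,
                                     c("accuracy_model", "accuracy_null"),
                                     c("model", "chance")))
  stars <- tibble::as_tibble(object) |> dplyr::filter(.data$significant)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$accuracy,
                                           colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::stat_function(fun = function(n) 100 / n, colour = "grey60",
                           linetype = "dashed") +
    ggplot2::labs(x = "subset size n", y = "% correctly matched",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(stars) > 0) {
    gg <- gg + ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$n, y = .data$accuracy_model, label = "*"),
      inherit.aes = FALSE, vjust = -0.4
    )
  }
  gg
}

#' Heatmap of a cross-subject similarity matrix
#'
#' @param similarity An `fc_similarity`.
#' @return A ggplot object; rows are predictions, columns empirical
#'   references, so a visible diagonal indicates identifiable subjects.
#' @export
plot_similarity <- function(similarity) {
  stopifnot(inherits(similarity, "fc_similarity"))
  df <- tibble::as_tibble(as.table(similarity$values), .name_repair = "minimal")
  names(df) <- c("prediction", "reference", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$prediction,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(name = similarity$measure) +
    ggplot2::labs(x = "empirical reference", y = "prediction",
                  subtitle = similarity$direction) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
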