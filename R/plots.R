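#' Heatmap of a phenotype similarity network
#'
#' @param object a [phenotype_net()].
#' @param ... ignored.
#' @return a ggplot object: a disease-by-disease tile heatmap.
#' @exportS3Method ggplot2::autoplot
autoplot.phenotype_net <- function(object, ...) {
  df <- tibble(
    from = rep(object$disease_ids, times = length(object$disease_ids)),
    to = rep(object$disease_ids, each = length(object$disease_ids)),
    similarity = as.vector(object$scores)
  )
  df$from <- factor(df$from, levels = object$disease_ids)
  df$to <- factor(df$to, levels = rev(object$disease_ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(0, min(df$similarity)),
                                             max(1, max(df$similarity)))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Cumulative recovery curve of a cross-validation run
#'
#' Plots the percentage of held-out target genes recovered within the top k
#' ranks as k grows — the curve whose values at k = 5, 10, 30 are the TPR@k
#' statistics.
#'
#' @param object a `phenoprio_loocv` object.
#' @param max_rank largest rank cutoff shown (default 30).
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phenoprio_loocv <- function(object, max_rank = 30L, ...) {
  ks <- seq_len(max_rank)
  df <- tibble(
    k = ks,
    tpr = vapply(ks, function(k) 100 * mean(object$records$rank <= k),
                 numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank cutoff k", y = "targets recovered (%)") +
    ggplot2::theme_minimal()
}

#' Steepness-sweep performance curve
#'
#' Plots the number of top-ranking genes against the logistic steepness `c`,
#' with the selected optimum highlighted — the curve used to pick `c`.
#'
#' @param object a `phenoprio_sweep` object.
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phenoprio_sweep <- function(object, ...) {
  df <- object$reports
  best <- df[df$c == object$best_c, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$top_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = best, colour = "red", size = 3) +
    ggplot2::labs(x = "logistic steepness c", y = "top-ranking genes") +
    ggplot2::theme_minimal()
}
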