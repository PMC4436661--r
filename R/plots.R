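# autoplot() methods for result objects

#' Plot a Deformation Profile as a heatmap
#'
#' @param object An `rna_dp`.
#' @param ... Unused.
#' @return A ggplot object (anchor residues on y, measured on x).
#' @method autoplot rna_dp
#' @export
autoplot.rna_dp <- function(object, ...) {
  df <- tidy(object)
  df$anchor <- factor(df$anchor, levels = rownames(object$values))
  df$measured <- factor(df$measured, levels = colnames(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$anchor,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mean\ndistance (Å)",
                                  na.value = "grey85") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$values))) +
    ggplot2::labs(x = "measured residue", y = "anchor residue") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5))
}

#' Plot an assessment report
#'
#' One panel per metric, models ordered by rank.
#'
#' @param object An `rna_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rna_report
#' @export
autoplot.rna_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  df$model <- factor(df$model, levels = rev(object$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$model)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw(base_size = 9)
}

#' Plot MCQ-local differences along the sequence
#'
#' @param object An `rna_mcq`.
#' @param ... Unused.
#' @return A ggplot object of per-slot circular differences.
#' @method autoplot rna_mcq
#' @export
autoplot.rna_mcq <- function(object, ...) {
  df <- object$per_slot
  df$pos <- match(df$key, unique(df$key))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$diff,
                                   colour = .data$angle)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue (paired order)",
                  y = "circular difference (deg)", colour = "angle") +
    ggplot2::theme_bw(base_size = 9)
}
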