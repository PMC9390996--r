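# ggplot2 views of the result objects; untested display surface

#' @export
autoplot.rb_oncoprint <- function(object, ...) {
  df <- as_tibble(object$matrix, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "alteration") |>
    mutate(
      gene = factor(.data$gene, levels = rev(rownames(object$matrix))),
      sample_id = factor(.data$sample_id, levels = colnames(object$matrix)),
      alteration = if_else(.data$alteration == "none", NA_character_, .data$alteration)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$gene)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$alteration), color = "grey90") +
    ggplot2::scale_fill_brewer(palette = "Set1", na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Alteration") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.rb_recurrence <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    stats::reorder(.data$arm, .data$z), .data$z,
    fill = .data$direction
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = attr(object, "z_cut"), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Arm", y = "Permutation z score", fill = "Direction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rb_integration <- function(object, ...) {
  df <- object$summary$bin_counts
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$n_peaks)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Distance to TSS", y = "Peaks on DE genes",
      title = "TSS-distance bins of DE-linked peaks"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rb_sc_qc <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(
    .data$total_umi, .data$n_genes_detected,
    color = .data$pass
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Total UMIs (log scale)", y = "Genes detected", color = "Pass QC"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of motif subset co-occurrence counts
#'
#' @param counts Tibble from [cooccurrence_counts()].
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(counts) {
  ggplot2::ggplot(
    filter(counts, .data$n > 0),
    ggplot2::aes(stats::reorder(.data$subset, -.data$n), .data$n)
  ) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Motif subset (exact)", y = "Regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
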