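# ggplot2 views of the main result types.

#' Volcano plot of a contrast table
#'
#' @param contrasts Contrast tibble (optionally with an `isoform` column,
#'   which facets the plot).
#' @param delta_min,alpha Gates drawn as reference lines and used to color
#'   passing proteins.
#' @param p_mode `"raw"` or `"bh"`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(contrasts, delta_min = 1, alpha = 0.05,
                         p_mode = "raw") {
  pc <- p_column(p_mode)
  df <- contrasts |>
    mutate(
      neglog10p = -log10(pmax(.data[[pc]], 1e-300)),
      hit = .data$delta > delta_min & .data[[pc]] < alpha
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                        y = .data$neglog10p,
                                        color = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-delta_min, delta_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "#c0392b"),
                                guide = "none") +
    ggplot2::labs(x = "log2 fold change",
                  y = sprintf("-log10 %s", if (pc == "p") "p" else "q"))
  if ("isoform" %in% names(contrasts)) {
    p <- p + ggplot2::facet_wrap(~isoform)
  }
  p
}

#' @describeIn randomize_labels_fdr Histogram of pooled randomized |delta|
#'   with the calibrated threshold and the real |delta| distribution.
#' @param object A `prx_calibration`.
#' @param ... Unused.
#' @export
autoplot.prx_calibration <- function(object, ...) {
  df <- bind_rows(
    tibble(abs_delta = object$perm_deltas, which = "randomized"),
    tibble(abs_delta = object$real_deltas, which = "real")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_delta,
                                   fill = .data$which)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, position = "identity", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$tau, linetype = "dashed") +
    ggplot2::annotate("text", x = object$tau, y = Inf,
                      label = sprintf("tau = %.3f", object$tau),
                      hjust = -0.1, vjust = 1.5, size = 3) +
    ggplot2::labs(x = "|log2 fold change|", y = "density", fill = NULL)
}

#' Bar chart of amino-acid enrichment around cysteines
#'
#' @param enrichment Output of [aa_composition_enrichment()] (optionally
#'   with an `isoform` column for faceting).
#' @param alpha Significance level marked on the bars.
#' @return A ggplot object.
#' @export
plot_aa_enrichment <- function(enrichment, alpha = 0.05) {
  df <- enrichment |>
    mutate(log2_fold = log2(.data$fold), sig = .data$q < alpha)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                        y = .data$log2_fold,
                                        fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2980b9"),
                               labels = c("n.s.", sprintf("q < %.2f", alpha)),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "log2 fold enrichment (flanking residues)")
  if ("isoform" %in% names(enrichment)) {
    p <- p + ggplot2::facet_wrap(~isoform)
  }
  p
}

#' UpSet-style bar chart of exclusive set intersections
#'
#' @param intersections Output of [set_intersections()].
#' @param top_n Show at most this many patterns (largest first).
#' @return A ggplot object.
#' @export
plot_set_intersections <- function(intersections, top_n = 20) {
  df <- intersections |>
    arrange(desc(.data$n)) |>
    head(top_n) |>
    mutate(pattern = factor(.data$pattern, levels = .data$pattern))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "exclusive intersection size") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
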