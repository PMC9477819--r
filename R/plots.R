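# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_abline
#'   geom_col scale_fill_gradient labs theme_minimal facet_wrap
#'   geom_hline scale_colour_manual
NULL

#' @export
ggplot2::autoplot

#' Heatmap of CDS coverage across samples and genes
#'
#' Distributed genes only by default, mirroring the usual PAV landscape
#' view.
#'
#' @param object a `pav_matrix`.
#' @param distributed_only plot distributed genes only.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pav_matrix <- function(object, distributed_only = TRUE, ...) {
  d <- tidy(object)
  if (distributed_only && any(d$label == "DISTRIBUTED"))
    d <- d |> filter(.data$label == "DISTRIBUTED")
  ggplot(d, aes(x = .data$gene_id, y = .data$sample,
                fill = .data$coverage)) +
    geom_tile() +
    scale_fill_gradient(low = "grey15", high = "gold", limits = c(0, 1)) +
    labs(x = "gene", y = "sample", fill = "CDS coverage") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Case-versus-control absence-frequency scatter
#'
#' Each dot is a gene; colour marks FDR-flagged genes.
#'
#' @param object a `pav_comparison`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pav_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$freq_case, y = .data$freq_control,
                colour = .data$flagged)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.8) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    labs(x = "absence frequency (case)", y = "absence frequency (control)",
         colour = "FDR flagged") +
    theme_minimal()
}

#' Per-sample mapping-rate comparison plot
#'
#' @param rates tibble with columns `sample`, `reference`, `pangenome`
#'   (mapping rates), e.g. assembled from [mapping_rate()] calls.
#' @return A ggplot.
#' @export
plot_mapping_rates <- function(rates) {
  d <- rates |>
    tidyr::pivot_longer(c("reference", "pangenome"), names_to = "target",
                        values_to = "rate")
  ggplot(d, aes(x = .data$target, y = .data$rate)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    labs(x = NULL, y = "read mapping rate") +
    theme_minimal()
}

#' Caller-support distribution of merged SVs
#'
#' @param merged a `merged_svs` tibble.
#' @return A ggplot.
#' @export
plot_sv_support <- function(merged) {
  d <- merged |> count(.data$type, .data$support)
  ggplot(d, aes(x = factor(.data$support), y = .data$n, fill = .data$type)) +
    geom_col(position = "dodge") +
    labs(x = "supporting callers", y = "merged SVs", fill = "type") +
    theme_minimal()
}
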