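# broom-style tidiers for the package's result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PAV matrix into its long call table
#'
#' @param x a `pav_matrix`.
#' @param ... unused.
#' @return Tibble: `sample`, `gene_id`, `coverage`, `present`, plus the
#'   gene's core/distributed label.
#' @export
tidy.pav_matrix <- function(x, ...) {
  x$calls |> left_join(x$labels, by = "gene_id")
}

#' One-row summary of a PAV matrix
#'
#' @param x a `pav_matrix`.
#' @param ... unused.
#' @return Tibble: sample and gene counts, core/distributed/unevaluable
#'   counts, mean genes present per sample.
#' @export
glance.pav_matrix <- function(x, ...) {
  gps <- genes_per_sample(x)
  tibble(
    n_samples = length(unique(x$calls$sample)),
    n_genes = nrow(x$labels),
    n_core = sum(x$labels$label == "CORE"),
    n_distributed = sum(x$labels$label == "DISTRIBUTED"),
    n_unevaluable = sum(x$labels$label == "UNEVALUABLE"),
    mean_genes_present = mean(gps$n_ref_present + gps$n_novel_present))
}

#' Tidy a cohort comparison
#'
#' @param x a `pav_comparison`.
#' @param ... unused.
#' @return The comparison as a plain tibble.
#' @export
tidy.pav_comparison <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a cohort comparison
#'
#' @param x a `pav_comparison`.
#' @param ... unused.
#' @return Tibble: genes tested, FDR-flagged and OR-flagged counts.
#' @export
glance.pav_comparison <- function(x, ...) {
  tibble(n_genes = nrow(x), n_flagged = sum(x$flagged),
         n_or_flagged = sum(x$or_flagged),
         min_q = if (nrow(x)) min(x$q) else NA_real_)
}
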