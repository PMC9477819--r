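# Per-gene cohort comparison of absence frequencies: Fisher's exact test
# (probability-ordering two-sided), Benjamini-Hochberg FDR, odds ratios with
# Haldane-Anscombe correction for zero cells, the OR > 1.5 flag, the
# HAG/LAG split of top-ranked distributed genes, and generic phenotype
# association through the same machinery.

#' 2x2 absence table for one gene across two cohorts
#'
#' Returns (a, b, c, d) = (absent-in-case, present-in-case,
#' absent-in-control, present-in-control). chrY genes are counted over male
#' samples only.
#'
#' @param matrix_case,matrix_control `pav_matrix` objects.
#' @param gene gene id.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
absence_table <- function(matrix_case, matrix_control, gene) {
  counts <- function(m) {
    calls <- m$calls[m$calls$gene_id == gene, , drop = FALSE]
    if (nrow(calls) == 0L)
      abort(paste0("gene '", gene, "' missing from a PAV matrix"))
    chry <- unique(m$genes$gene_id[m$genes$seqnames == "chrY"])
    if (gene %in% chry) {
      males <- m$meta$sample[m$meta$sex == "male"]
      calls <- calls[calls$sample %in% males, , drop = FALSE]
    }
    c(absent = sum(!calls$present), present = sum(calls$present))
  }
  k1 <- counts(matrix_case); k2 <- counts(matrix_control)
  c(a = unname(k1["absent"]), b = unname(k1["present"]),
    c = unname(k2["absent"]), d = unname(k2["present"]))
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (probability-ordering convention, with the customary 1 + 1e-7 relative
#' tolerance on the comparison).
#'
#' @param a,b,c,d integer cell counts (rows = cohorts, columns =
#'   absent/present).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  row1 <- a + b; col1 <- a + c; col2 <- b + d
  lo <- max(0L, col1 - (c + d)); hi <- min(row1, col1)
  k <- lo:hi
  pk <- dhyper(k, col1, col2, row1)
  pobs <- dhyper(a, col1, col2, row1)
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment with monotone enforcement; output in input order.
#'
#' @param pvals numeric vector of p-values.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  p.adjust(pvals, method = "BH")
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe correction
#' (+0.5 to every cell) is applied.
#'
#' @inheritParams fisher_exact_two_sided
#' @return Odds ratio (finite, positive).
#' @export
odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

# shared core for cohort and phenotype comparisons
.compare_tables <- function(tables, t) {
  if (nrow(tables) == 0L) {
    return(structure(
      tibble(gene_id = character(), a = integer(), b = integer(),
             c = integer(), d = integer(), freq_case = numeric(),
             freq_control = numeric(), p = numeric(), q = numeric(),
             or_value = numeric(), flagged = logical(),
             or_flagged = logical()),
      class = c("pav_comparison", "tbl_df", "tbl", "data.frame")))
  }
  res <- tables |>
    mutate(freq_case = .data$a / (.data$a + .data$b),
           freq_control = .data$c / (.data$c + .data$d),
           p = purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                               fisher_exact_two_sided),
           or_value = purrr::pmap_dbl(list(.data$a, .data$b, .data$c, .data$d),
                                      odds_ratio))
  res$q <- bh_fdr(res$p)
  res <- res |>
    mutate(flagged = .data$q < t$fdr_alpha,
           or_flagged = .data$or_value > t$or_flag_threshold) |>
    arrange(.data$q, .data$gene_id)
  structure(res, class = c("pav_comparison", class(tibble())))
}

#' Compare gene absence frequencies between two cohorts
#'
#' One Fisher's exact test per gene evaluated in both matrices; q-values are
#' BH-adjusted over exactly this gene family; `flagged` marks q below
#' `fdr_alpha`, `or_flagged` odds ratios above `or_flag_threshold`.
#'
#' @param matrix_case,matrix_control `pav_matrix` objects.
#' @param t a [pav_thresholds()] object.
#' @param genes optional gene ids to test (default: genes present in both
#'   matrices).
#' @return A `pav_comparison` tibble: `gene_id`, `a`, `b`, `c`, `d`,
#'   `freq_case`, `freq_control`, `p`, `q`, `or_value`, `flagged`,
#'   `or_flagged`, sorted by (`q`, `gene_id`).
#' @export
compare_cohorts <- function(matrix_case, matrix_control, t = pav_thresholds(),
                            genes = NULL) {
  shared <- intersect(unique(matrix_case$calls$gene_id),
                      unique(matrix_control$calls$gene_id))
  genes <- genes %||% shared
  tables <- lapply(genes, function(g) {
    k <- absence_table(matrix_case, matrix_control, g)
    tibble(gene_id = g, a = k[["a"]], b = k[["b"]], c = k[["c"]], d = k[["d"]])
  })
  tables <- if (length(tables)) bind_rows(tables) else
    tibble(gene_id = character(), a = integer(), b = integer(),
           c = integer(), d = integer())
  # drop genes with an empty evaluation set on either side (e.g. chrY with
  # no males)
  tables <- tables |> filter(.data$a + .data$b > 0, .data$c + .data$d > 0)
  .compare_tables(tables, t)
}

#' Split top-ranked distributed genes into highly / lowly absent
#'
#' Distributed genes are ranked by absence frequency (descending); among the
#' top `top_n`, a gene is HAG when the median CDS coverage over its
#' absence-called samples is below `hag_cds_coverage` (50%), else LAG.
#'
#' @param matrix a `pav_matrix` (the case cohort).
#' @param t a [pav_thresholds()] object.
#' @param top_n number of top genes to categorize (default 20; fewer
#'   distributed genes than `top_n` are all ranked, none invented).
#' @return Tibble: `gene_id`, `rank`, `absence_freq`,
#'   `median_absent_coverage`, `category` (HAG/LAG).
#' @export
hag_lag <- function(matrix, t = pav_thresholds(), top_n = 20L) {
  distributed <- matrix$labels$gene_id[matrix$labels$label == "DISTRIBUTED"]
  stats <- matrix$calls |>
    filter(.data$gene_id %in% distributed) |>
    group_by(.data$gene_id) |>
    summarise(absence_freq = mean(!.data$present),
              median_absent_coverage =
                if (any(!.data$present)) median(.data$coverage[!.data$present])
                else NA_real_,
              .groups = "drop") |>
    arrange(dplyr::desc(.data$absence_freq), .data$gene_id) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= top_n) |>
    mutate(category = if_else(.data$median_absent_coverage < t$hag_cds_coverage,
                              "HAG", "LAG"))
  stats |> select("gene_id", "rank", "absence_freq",
                  "median_absent_coverage", "category")
}

#' Associate gene PAVs with a binary phenotype
#'
#' Splits the samples of one PAV matrix by a metadata column and runs the
#' cohort-comparison machinery; `case_level` defines which level is the
#' case. With the `sex` phenotype chrY genes are excluded (confounded by
#' design).
#'
#' @param matrix a `pav_matrix`.
#' @param phenotype name of a column of `matrix$meta`.
#' @param t a [pav_thresholds()] object.
#' @param case_level optional level treated as case (default: first sorted
#'   level).
#' @return A `pav_comparison` tibble.
#' @export
phenotype_association <- function(matrix, phenotype, t = pav_thresholds(),
                                  case_level = NULL) {
  if (!phenotype %in% names(matrix$meta))
    abort(paste0("phenotype '", phenotype, "' not in sample metadata"))
  ph <- matrix$meta[[phenotype]]
  lv <- sort(unique(ph[!is.na(ph)]))
  if (length(lv) < 2L)
    abort(paste0("phenotype '", phenotype,
                 "' has fewer than two levels: no contrast"))
  if (length(lv) > 2L)
    abort(paste0("phenotype '", phenotype,
                 "' has more than two levels: binarize it first"))
  case_level <- case_level %||% lv[1]
  split_matrix <- function(samples) {
    m <- matrix
    m$calls <- m$calls[m$calls$sample %in% samples, , drop = FALSE]
    m$meta <- m$meta[m$meta$sample %in% samples, , drop = FALSE]
    m
  }
  case_samples <- matrix$meta$sample[!is.na(ph) & ph == case_level]
  ctrl_samples <- matrix$meta$sample[!is.na(ph) & ph != case_level]
  genes <- unique(matrix$calls$gene_id)
  if (identical(phenotype, "sex")) {
    chry <- unique(matrix$genes$gene_id[matrix$genes$seqnames == "chrY"])
    genes <- setdiff(genes, chry)
  }
  compare_cohorts(split_matrix(case_samples), split_matrix(ctrl_samples),
                  t, genes = genes)
}
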