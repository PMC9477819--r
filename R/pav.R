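# Gene presence-absence calling from CDS depth coverage.
#
# For each gene only the transcript with the longest total CDS (the
# longest-ORF representative) is evaluated. A gene is present in a sample
# when strictly more than 80% of its representative CDS bases are covered by
# mapped reads; genes present in every evaluable sample are core, the rest
# distributed. chrY genes are evaluated over male samples only, since
# females carry no chrY.

#' Representative (longest-ORF) transcript per gene
#'
#' Picks, per gene, the transcript with maximal total CDS length; ties go to
#' the first listed transcript.
#'
#' @param genes gene-model tibble (one row per CDS exon).
#' @return The input rows restricted to each gene's representative
#'   transcript.
#' @export
representative_transcript <- function(genes) {
  if (nrow(genes) == 0L) return(genes)
  ord <- genes |>
    mutate(.row = row_number()) |>
    group_by(.data$gene_id, .data$transcript) |>
    summarise(cds_len = sum(.data$end - .data$start),
              first_row = min(.data$.row), .groups = "drop_last") |>
    arrange(dplyr::desc(.data$cds_len), .data$first_row, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  genes |>
    inner_join(ord |> select("gene_id", "transcript"),
               by = c("gene_id", "transcript"))
}

# covered intervals (depth >= min) per target as a list of IRanges
.covered_by_target <- function(track, min_depth) {
  tr <- track[track$depth >= min_depth, , drop = FALSE]
  if (nrow(tr) == 0L) return(list())
  lapply(split(tr, tr$target), function(d)
    IRanges::reduce(iranges0(d$start, d$end)))
}

#' CDS coverage of genes under a depth track
#'
#' Fraction of representative-transcript CDS bases with depth at or above
#' `depth_presence_min`. A gene whose host sequence is absent from the track
#' has coverage 0.
#'
#' @param genes gene-model tibble.
#' @param track depth-track tibble (`target`, `start`, `end`, `depth`).
#' @param t a [pav_thresholds()] object.
#' @return Tibble: `gene_id`, `coverage`.
#' @export
cds_coverage <- function(genes, track, t = pav_thresholds()) {
  if (nrow(genes) == 0L)
    return(tibble(gene_id = character(), coverage = numeric()))
  rep_genes <- representative_transcript(genes)
  covered <- .covered_by_target(track, t$depth_presence_min)
  by_gene <- split(rep_genes, rep_genes$gene_id)
  out <- lapply(by_gene, function(g) {
    cds <- IRanges::reduce(iranges0(g$start, g$end))
    host <- g$seqnames[1]
    cv <- covered[[host]]
    num <- if (is.null(cv)) 0 else
      sum(IRanges::width(IRanges::intersect(cds, cv)))
    tibble(gene_id = g$gene_id[1], coverage = num / sum(IRanges::width(cds)))
  })
  bind_rows(out)[order(match(names(by_gene), unique(rep_genes$gene_id))), ] |>
    as_tibble()
}

#' Call gene presence from CDS coverage
#'
#' Present iff coverage is strictly greater than `presence_cds_coverage`
#' (more than 80% by default); exactly 80% is an absence.
#'
#' @param coverage numeric vector of CDS-coverage fractions.
#' @param t a [pav_thresholds()] object.
#' @return Logical vector.
#' @export
call_presence <- function(coverage, t = pav_thresholds()) {
  coverage > t$presence_cds_coverage
}

#' Build the sample-by-gene PAV matrix
#'
#' Computes CDS coverage for every (sample, gene), derives presence calls,
#' and labels genes core/distributed (chrY genes over males only). Genes are
#' ordered by host and position, samples by id.
#'
#' @param genes gene-model tibble (reference and/or novel genes).
#' @param tracks named list of depth-track tibbles, one per sample.
#' @param meta sample metadata tibble (`sample`, `cohort`, `sex`, optional
#'   phenotype columns).
#' @param t a [pav_thresholds()] object.
#' @return A `pav_matrix` object: list with `calls` (long tibble `sample`,
#'   `gene_id`, `coverage`, `present`), `genes` (representative-transcript
#'   models), `meta`, and `labels` (`gene_id`, `label` in CORE/DISTRIBUTED/
#'   UNEVALUABLE).
#' @export
build_pav_matrix <- function(genes, tracks, meta, t = pav_thresholds()) {
  missing_meta <- setdiff(names(tracks), meta$sample)
  if (length(missing_meta))
    abort(paste0("metadata error: sample(s) missing from meta: ",
                 paste(missing_meta, collapse = ", ")))
  if (anyDuplicated(meta$sample)) abort("duplicate sample ids in meta")
  rep_genes <- representative_transcript(genes)
  gene_order <- if (nrow(rep_genes) == 0L) character(0) else rep_genes |>
    group_by(.data$gene_id) |>
    summarise(seqnames = .data$seqnames[1], pos = min(.data$start),
              .groups = "drop") |>
    arrange(.data$seqnames, .data$pos) |>
    pull("gene_id")
  samples <- sort(names(tracks))
  calls <- lapply(samples, function(sid) {
    cds_coverage(rep_genes, tracks[[sid]], t) |>
      mutate(sample = sid, .before = 1L)
  })
  calls <- bind_rows(calls)
  if (nrow(calls) == 0L) {
    calls <- tibble(sample = character(), gene_id = character(),
                    coverage = numeric(), present = logical())
  } else {
    calls <- calls |>
      mutate(gene_id = factor(.data$gene_id, levels = gene_order)) |>
      arrange(.data$sample, .data$gene_id) |>
      mutate(gene_id = as.character(.data$gene_id),
             present = call_presence(.data$coverage, t))
  }
  m <- structure(list(calls = calls, genes = rep_genes,
                      meta = meta[match(samples, meta$sample), , drop = FALSE],
                      labels = NULL),
                 class = "pav_matrix")
  m$labels <- classify_core_distributed(m)
  m
}

#' Label genes core / distributed
#'
#' A non-chrY gene is CORE iff present in every sample; a chrY gene is CORE
#' iff present in every male sample (females are excluded from evaluation).
#' chrY genes in a cohort with no males are UNEVALUABLE. Everything else is
#' DISTRIBUTED.
#'
#' @param matrix a `pav_matrix`.
#' @param meta sample metadata (defaults to the matrix's own).
#' @return Tibble: `gene_id`, `label`.
#' @export
classify_core_distributed <- function(matrix, meta = NULL) {
  meta <- meta %||% matrix$meta
  chry <- matrix$genes |>
    filter(.data$seqnames == "chrY") |> pull("gene_id") |> unique()
  males <- meta$sample[meta$sex == "male"]
  matrix$calls |>
    group_by(.data$gene_id) |>
    summarise(label = {
      on_y <- .data$gene_id[1] %in% chry
      ev <- if (on_y) .data$present[.data$sample %in% males] else .data$present
      if (length(ev) == 0L) "UNEVALUABLE"
      else if (all(ev)) "CORE" else "DISTRIBUTED"
    }, .groups = "drop")
}

#' Per-sample counts of present genes, split reference vs novel
#'
#' @param matrix a `pav_matrix`.
#' @return Tibble: `sample`, `n_ref_present`, `n_novel_present`.
#' @export
genes_per_sample <- function(matrix) {
  novel_ids <- matrix$genes |> filter(.data$novel) |> pull("gene_id") |> unique()
  matrix$calls |>
    group_by(.data$sample) |>
    summarise(
      n_ref_present = sum(.data$present & !(.data$gene_id %in% novel_ids)),
      n_novel_present = sum(.data$present & .data$gene_id %in% novel_ids),
      .groups = "drop")
}

#' Presence matrix in wide form
#'
#' @param matrix a `pav_matrix`.
#' @param value `"present"` or `"coverage"`.
#' @return Tibble, one row per sample, one column per gene.
#' @export
pav_wide <- function(matrix, value = c("present", "coverage")) {
  value <- match.arg(value)
  matrix$calls |>
    select("sample", "gene_id", dplyr::all_of(value)) |>
    pivot_wider(names_from = "gene_id", values_from = dplyr::all_of(value))
}

#' @export
print.pav_matrix <- function(x, ...) {
  lab <- table(x$labels$label)
  cat(sprintf("<pav_matrix> %d samples x %d genes (%s)\n",
              length(unique(x$calls$sample)), nrow(x$labels),
              paste(sprintf("%s %d", names(lab), lab), collapse = ", ")))
  invisible(x)
}
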