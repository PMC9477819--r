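# Anchor-based chromosomal placement of non-reference genes.
#
# A gene is matched to a long-read contig when the matching columns of its
# coding sequence exceed 80% of the coding length; the 3000 bp of contig
# immediately flanking the hit become anchor sequences; an anchor placement
# is accepted when its best reference alignment is longer than 1500 bp at
# identity above 80%; and the inter-anchor reference gap becomes the gene's
# locus when it is shorter than twice the gene length. Loci accepted across
# contigs are clustered by overlap (single linkage) and the best-supported
# cluster is reported.

#' Match a gene's coding sequence to a long-read contig
#'
#' @param gene_seq gene coding/cassette sequence (character).
#' @param contig contig sequence (character) or a prebuilt [seed_index()]
#'   over it.
#' @param t a [pav_thresholds()] object.
#' @return `NULL` when unmatched, else a list with `t_start`, `t_end` (hit
#'   interval on the contig, 0-based half-open), `identity` (matching
#'   columns / coding length) and `strand`.
#' @export
match_gene_to_contig <- function(gene_seq, contig, t = pav_thresholds()) {
  idx <- if (inherits(contig, "seed_index")) contig else
    seed_index(c(contig_ = unname(contig)))
  glen <- nchar(gene_seq)
  # generous same-diagonal gap budget: the rule is a global identity over
  # the coding region, so seedless stretches (error clusters at ~10-20%
  # divergence) must be bridged, not split
  b <- align(c(gene = unname(gene_seq)), idx,
             min_block_len = min(50L, glen), gap_budget = 250L)
  if (nrow(b) == 0L) return(NULL)
  # best non-overlapping chain on the gene; matching columns summed over it
  sel <- .best_chain(b)
  ident <- sum(sel$n_match) / glen
  if (ident <= t$gene_contig_min_identity) return(NULL)
  strand <- sel$strand[which.max(sel$block_len)]
  sel <- sel[sel$strand == strand, , drop = FALSE]
  list(t_start = min(sel$t_start), t_end = max(sel$t_end),
       identity = ident, strand = strand)
}

# weighted-interval-scheduling selection of a non-overlapping block subset
# maximizing total aligned length (ties -> more matching columns)
.best_chain <- function(b) {
  o <- order(b$q_end, b$q_start)
  b <- b[o, , drop = FALSE]
  nb <- nrow(b)
  pred <- findInterval(b$q_start, b$q_end)
  len_dp <- numeric(nb + 1L); idm_dp <- numeric(nb + 1L)
  for (i in seq_len(nb)) {
    take_len <- len_dp[pred[i] + 1L] + b$block_len[i]
    take_idm <- idm_dp[pred[i] + 1L] + b$n_match[i]
    if (take_len > len_dp[i] ||
        (take_len == len_dp[i] && take_idm > idm_dp[i])) {
      len_dp[i + 1L] <- take_len; idm_dp[i + 1L] <- take_idm
    } else {
      len_dp[i + 1L] <- len_dp[i]; idm_dp[i + 1L] <- idm_dp[i]
    }
  }
  sel <- integer(0); i <- nb
  while (i > 0L) {
    if (len_dp[i + 1L] == len_dp[i] && idm_dp[i + 1L] == idm_dp[i]) {
      i <- i - 1L
    } else {
      sel <- c(sel, i); i <- pred[i]
    }
  }
  b[rev(sel), , drop = FALSE]
}

#' Extract anchor sequences flanking a contig hit
#'
#' The `anchor_flank_len` (3000 bp) immediately left and right of the hit;
#' a side with insufficient flank yields `NULL` for that side rather than a
#' shortened anchor.
#'
#' @param contig_seq contig sequence.
#' @param hit list with `t_start`, `t_end` (as from
#'   [match_gene_to_contig()]).
#' @param t a [pav_thresholds()] object.
#' @return `list(left = , right = )` of sequences or `NULL`s.
#' @export
extract_anchors <- function(contig_seq, hit, t = pav_thresholds()) {
  fl <- t$anchor_flank_len
  n <- nchar(contig_seq)
  left <- if (hit$t_start >= fl)
    substring(contig_seq, hit$t_start - fl + 1L, hit$t_start) else NULL
  right <- if (n - hit$t_end >= fl)
    substring(contig_seq, hit$t_end + 1L, hit$t_end + fl) else NULL
  list(left = left, right = right)
}

#' Place one anchor sequence on the reference
#'
#' The best alignment block by (length, identity) lexicographic order,
#' accepted iff longer than `anchor_min_aln_len` (1500 bp) with identity
#' above `anchor_min_identity` (80%).
#'
#' @param anchor anchor sequence (or `NULL`).
#' @param ref named reference sequences or a prebuilt [seed_index()].
#' @param t a [pav_thresholds()] object.
#' @return `NULL` when unplaced, else `list(chrom, t_start, t_end, strand,
#'   identity)`.
#' @export
place_anchor <- function(anchor, ref, t = pav_thresholds()) {
  if (is.null(anchor)) return(NULL)
  idx <- if (inherits(ref, "seed_index")) ref else seed_index(as_named_dna(ref))
  b <- align(c(anchor = unname(anchor)), idx, min_block_len = 100L)
  if (nrow(b) == 0L) return(NULL)
  b <- b[order(-b$block_len, -b$identity), , drop = FALSE]
  best <- b[1, ]
  if (best$block_len <= t$anchor_min_aln_len ||
      best$identity <= t$anchor_min_identity) return(NULL)
  list(chrom = best$target_id, t_start = best$t_start, t_end = best$t_end,
       strand = best$strand, identity = best$identity)
}

#' Assign a chromosomal locus from two placed anchors
#'
#' Requires both anchors on the same chromosome and strand; the locus is the
#' reference gap between the inner anchor boundaries, accepted iff shorter
#' than `placement_span_factor` (2) times the gene length. Abutting or
#' overlapping anchors yield the zero-length insertion point.
#'
#' @param gene_len gene length in bp.
#' @param left,right placements from [place_anchor()].
#' @param t a [pav_thresholds()] object.
#' @return `NULL` (with attribute `reason`) or `list(chrom, start, end)`.
#' @export
assign_locus <- function(gene_len, left, right, t = pav_thresholds()) {
  if (is.null(left) || is.null(right)) return(NULL_reason("unanchored"))
  if (left$chrom != right$chrom || left$strand != right$strand)
    return(NULL_reason("discordant"))
  gap_start <- min(left$t_end, right$t_end)
  gap_end <- max(left$t_start, right$t_start)
  if (gap_end < gap_start) { gap_end <- gap_start }  # overlapping anchors
  if (gap_end - gap_start >= t$placement_span_factor * gene_len)
    return(NULL_reason("span"))
  list(chrom = left$chrom, start = gap_start, end = gap_end)
}

NULL_reason <- function(reason) structure(list(), class = "pav_no_locus",
                                          reason = reason)

is_locus <- function(x) is.list(x) && !inherits(x, "pav_no_locus") &&
  !is.null(x$chrom)

#' Place a non-reference gene on the reference via long-read contigs
#'
#' Runs match -> anchors -> place -> assign per contig, clusters the
#' accepted loci by interval overlap (single linkage) and reports the
#' cluster with most supporting contigs (ties: leftmost), with consensus
#' (median) boundaries.
#'
#' @param gene_seq the gene's cassette/coding sequence.
#' @param contigs tibble with `contig_id` and `seq` (long-read contigs), or
#'   a named character vector.
#' @param ref named reference sequences or a prebuilt [seed_index()].
#' @param t a [pav_thresholds()] object.
#' @return `NULL`, or a tibble row `gene_locus`: `chrom`, `start`, `end`,
#'   `support`, `contigs` (list column of supporting contig ids).
#' @export
place_gene <- function(gene_seq, contigs, ref, t = pav_thresholds()) {
  if (is.character(contigs)) {
    contigs <- tibble(contig_id = names(as_named_dna(contigs, "contig")),
                      seq = unname(as_named_dna(contigs, "contig")))
  }
  ref_idx <- if (inherits(ref, "seed_index")) ref else
    seed_index(as_named_dna(ref))
  glen <- nchar(gene_seq)
  loci <- list()
  for (i in seq_len(nrow(contigs))) {
    hit <- match_gene_to_contig(gene_seq, contigs$seq[i], t)
    if (is.null(hit)) next
    an <- extract_anchors(contigs$seq[i], hit, t)
    lp <- place_anchor(an$left, ref_idx, t)
    rp <- place_anchor(an$right, ref_idx, t)
    if (is.null(lp) || is.null(rp)) next
    loc <- assign_locus(glen, lp, rp, t)
    if (!is_locus(loc)) next
    loci[[length(loci) + 1L]] <- tibble(
      contig_id = contigs$contig_id[i], chrom = loc$chrom,
      start = loc$start, end = loc$end)
  }
  if (length(loci) == 0L) return(NULL)
  loci <- bind_rows(loci)
  out <- list()
  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(l$start + 1L, pmax(l$end, l$start + 1L))
    l$cluster <- IRanges::findOverlaps(ir, IRanges::reduce(ir),
                                       select = "first")
    out[[ch]] <- l |>
      group_by(.data$cluster) |>
      summarise(chrom = ch, start = as.integer(round(median(.data$start))),
                end = as.integer(round(median(.data$end))),
                support = dplyr::n(),
                contigs = list(.data$contig_id), .groups = "drop") |>
      select(-"cluster")
  }
  out <- bind_rows(out) |>
    arrange(dplyr::desc(.data$support), .data$chrom, .data$start)
  out[1, , drop = FALSE]
}

#' Place several genes
#'
#' @param genes named character vector of gene sequences.
#' @param contigs long-read contigs (tibble or named character).
#' @param ref reference sequences or [seed_index()].
#' @param t a [pav_thresholds()] object.
#' @return Tibble with one row per placed gene: `gene_id`, `chrom`, `start`,
#'   `end`, `support`, `contigs`.
#' @export
place_genes <- function(genes, contigs, ref, t = pav_thresholds()) {
  ref_idx <- if (inherits(ref, "seed_index")) ref else
    seed_index(as_named_dna(ref))
  rows <- list()
  for (g in names(genes)) {
    res <- place_gene(genes[[g]], contigs, ref_idx, t)
    if (!is.null(res)) rows[[g]] <- res |> mutate(gene_id = g, .before = 1L)
  }
  if (length(rows)) bind_rows(rows) else
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), support = integer(), contigs = list())
}
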