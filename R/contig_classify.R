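# Partition of per-sample contigs against the reference, extraction of
# non-reference sequence, redundancy removal, pan-genome assembly, and
# read mapping rates.
#
# A contig is REFERENCE when it aligns at >= 95% identity over >= 95% of its
# length; with no alignment at all it is FULLY_UNALIGNED; otherwise it is
# partially unaligned and each maximal unaligned segment is anchored by its
# flanking aligned segments: both flanks placed on the same chromosome and
# strand (reference gap < 10x the segment length) give a two-end placement,
# exactly one qualifying flank a one-end placement.

#' Keep contigs longer than the minimum length
#'
#' Strictly longer than `min_contig_len` (default 500 bp); input order is
#' preserved.
#'
#' @param contigs tibble with a `seq` or `length` column, or a named
#'   character vector of sequences.
#' @param t a [pav_thresholds()] object.
#' @return Filtered input of the same shape.
#' @export
filter_contigs <- function(contigs, t = pav_thresholds()) {
  if (is.character(contigs)) {
    return(contigs[nchar(contigs) > t$min_contig_len])
  }
  len <- if ("length" %in% names(contigs)) contigs$length else nchar(contigs$seq)
  contigs[len > t$min_contig_len, , drop = FALSE]
}

# per-contig unaligned segments with flank qualification and placement
.contig_segments <- function(b, clen, t) {
  empty <- tibble(seg_start = integer(), seg_end = integer(),
                  placement = character(), chrom = NA_character_,
                  ref_left = NA_integer_, ref_right = NA_integer_,
                  side = NA_character_)
  if (nrow(b) == 0L) {
    return(tibble(seg_start = 0L, seg_end = as.integer(clen),
                  placement = "none", chrom = NA_character_,
                  ref_left = NA_integer_, ref_right = NA_integer_,
                  side = NA_character_))
  }
  cov <- IRanges::reduce(iranges0(b$q_start, b$q_end))
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(clen)), cov)
  if (length(gaps) == 0L) return(empty)
  rows <- lapply(seq_along(gaps), function(i) {
    s0 <- IRanges::start(gaps)[i] - 1L
    e0 <- IRanges::end(gaps)[i]
    seg_len <- e0 - s0
    lf <- b[b$q_end <= s0, , drop = FALSE]
    lf <- if (nrow(lf)) lf[order(-lf$q_end, -lf$block_len), ][1, , drop = FALSE] else NULL
    rf <- b[b$q_start >= e0, , drop = FALSE]
    rf <- if (nrow(rf)) rf[order(rf$q_start, -rf$block_len), ][1, , drop = FALSE] else NULL
    lq <- !is.null(lf) && lf$block_len >= t$min_contig_len
    rq <- !is.null(rf) && rf$block_len >= t$min_contig_len
    if (lq && rq && lf$target_id == rf$target_id && lf$strand == rf$strand) {
      inner <- if (lf$strand == "+") rf$t_start - lf$t_end else
        lf$t_start - rf$t_end
      if (abs(inner) < 10 * seg_len) {
        bounds <- sort(c(if (lf$strand == "+") c(lf$t_end, rf$t_start)
                         else c(rf$t_end, lf$t_start)))
        return(tibble(seg_start = s0, seg_end = e0, placement = "two_end",
                      chrom = lf$target_id, ref_left = as.integer(bounds[1]),
                      ref_right = as.integer(bounds[2]), side = NA_character_))
      }
    }
    if (xor(lq, rq) || (lq && rq)) {
      # one qualifying flank (or two discordant flanks: use the left one)
      fl <- if (lq) lf else rf
      side <- if (lq) "left" else "right"
      boundary <- if (side == "left") {
        if (fl$strand == "+") fl$t_end else fl$t_start
      } else {
        if (fl$strand == "+") fl$t_start else fl$t_end
      }
      return(tibble(seg_start = s0, seg_end = e0, placement = "one_end",
                    chrom = fl$target_id, ref_left = as.integer(boundary),
                    ref_right = NA_integer_, side = side))
    }
    tibble(seg_start = s0, seg_end = e0, placement = "none",
           chrom = NA_character_, ref_left = NA_integer_,
           ref_right = NA_integer_, side = NA_character_)
  })
  bind_rows(rows)
}

.classify_one <- function(summary_row, segs, t) {
  if (summary_row$weighted_identity >= t$ref_identity &&
      summary_row$covered_fraction >= t$ref_query_coverage) return("REFERENCE")
  if (summary_row$covered_fraction == 0) return("FULLY_UNALIGNED")
  if (any(segs$placement == "two_end")) return("PARTIAL_TWO_END")
  "PARTIAL_ONE_END"
}

#' Classify one contig from its alignment summary
#'
#' @param summary one-row tibble from [summarize_query()] for this contig.
#' @param blocks alignment blocks of this contig.
#' @param contig_len contig length in bp.
#' @param t a [pav_thresholds()] object.
#' @return One of `"REFERENCE"`, `"PARTIAL_ONE_END"`, `"PARTIAL_TWO_END"`,
#'   `"FULLY_UNALIGNED"`.
#' @export
classify_contig <- function(summary, blocks, contig_len, t = pav_thresholds()) {
  if (nrow(blocks) && max(blocks$q_end) > contig_len)
    abort("consistency error: alignment blocks exceed the stated contig length")
  segs <- .contig_segments(blocks, contig_len, t)
  segs <- segs[segs$seg_end - segs$seg_start >= t$min_contig_len, , drop = FALSE]
  .classify_one(summary, segs, t)
}

#' Classify a set of contigs against the reference
#'
#' @param contigs tibble with `contig_id` and `seq` (or `length`) columns.
#' @param blocks alignment blocks of these contigs against the reference
#'   (query ids = contig ids), e.g. from [align()] or [read_paf()].
#' @param t a [pav_thresholds()] object.
#' @return Tibble: `contig_id`, `length`, `covered_fraction`,
#'   `weighted_identity`, `class`.
#' @export
classify_contigs <- function(contigs, blocks, t = pav_thresholds()) {
  lens <- setNames(
    if ("length" %in% names(contigs)) contigs$length else nchar(contigs$seq),
    contigs$contig_id)
  sm <- summarize_query(blocks, lens)
  out <- lapply(contigs$contig_id, function(cid) {
    b <- blocks[blocks$query_id == cid, , drop = FALSE]
    srow <- sm[sm$query_id == cid, , drop = FALSE]
    segs <- .contig_segments(b, lens[[cid]], t)
    segs <- segs[segs$seg_end - segs$seg_start >= t$min_contig_len, ,
                 drop = FALSE]
    tibble(contig_id = cid, length = as.integer(lens[[cid]]),
           covered_fraction = srow$covered_fraction,
           weighted_identity = srow$weighted_identity,
           class = .classify_one(srow, segs, t))
  })
  bind_rows(out)
}

#' Extract non-reference sequences from classified contigs
#'
#' Fully unaligned contigs are emitted whole (placement `none`); for
#' partially unaligned contigs every maximal unaligned segment at least
#' `min_contig_len` long is emitted with its one-end or two-end placement.
#'
#' @param contigs tibble with `contig_id` and `seq`.
#' @param blocks alignment blocks against the reference.
#' @param t a [pav_thresholds()] object.
#' @return Tibble: `nonref_id`, `origin_contig`, `length`, `placement`
#'   (`none`/`one_end`/`two_end`), `chrom`, `ref_left`, `ref_right`, `side`,
#'   `seq`.
#' @export
extract_nonref <- function(contigs, blocks, t = pav_thresholds()) {
  cls <- classify_contigs(contigs, blocks, t)
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    klass <- cls$class[cls$contig_id == cid]
    if (klass == "REFERENCE") next
    b <- blocks[blocks$query_id == cid, , drop = FALSE]
    clen <- nchar(contigs$seq[i])
    segs <- .contig_segments(b, clen, t)
    segs <- segs[segs$seg_end - segs$seg_start >= t$min_contig_len, ,
                 drop = FALSE]
    if (nrow(segs) == 0L) next
    out[[cid]] <- tibble(
      nonref_id = sprintf("%s_nr%d", cid, seq_len(nrow(segs))),
      origin_contig = cid, length = segs$seg_end - segs$seg_start,
      placement = segs$placement, chrom = segs$chrom,
      ref_left = segs$ref_left, ref_right = segs$ref_right, side = segs$side,
      seq = substring(contigs$seq[i], segs$seg_start + 1L, segs$seg_end))
  }
  if (length(out)) bind_rows(out) else
    tibble(nonref_id = character(), origin_contig = character(),
           length = integer(), placement = character(), chrom = character(),
           ref_left = integer(), ref_right = integer(), side = character(),
           seq = character())
}

#' Remove redundant non-reference sequences
#'
#' Greedy longest-first: a sequence is absorbed when it aligns to an already
#' kept sequence with identity >= `redundancy_identity` over >=
#' `redundancy_coverage` of its own length. Idempotent.
#'
#' @param nonref tibble from [extract_nonref()].
#' @param t a [pav_thresholds()] object.
#' @return The kept rows, sorted by length descending, with a list column
#'   `absorbed` of the nonref ids each kept sequence absorbed.
#' @export
remove_redundancy <- function(nonref, t = pav_thresholds()) {
  if (nrow(nonref) == 0L) {
    nonref$absorbed <- list()
    return(nonref)
  }
  ord <- order(-nonref$length, nonref$nonref_id)
  nonref <- nonref[ord, , drop = FALSE]
  kept <- integer(0)
  absorbed <- list()
  idx <- NULL
  for (i in seq_len(nrow(nonref))) {
    taken <- FALSE
    if (length(kept)) {
      b <- align(setNames(nonref$seq[i], nonref$nonref_id[i]), idx,
                 min_block_len = min(100L, nonref$length[i]))
      if (nrow(b)) {
        sm <- summarize_query(b, setNames(nonref$length[i],
                                          nonref$nonref_id[i]))
        if (sm$covered_fraction >= t$redundancy_coverage &&
            sm$weighted_identity >= t$redundancy_identity) {
          host <- b$target_id[which.max(b$block_len)]
          absorbed[[host]] <- c(absorbed[[host]], nonref$nonref_id[i])
          taken <- TRUE
        }
      }
    }
    if (!taken) {
      kept <- c(kept, i)
      idx <- seed_index(setNames(nonref$seq[kept], nonref$nonref_id[kept]))
    }
  }
  out <- nonref[kept, , drop = FALSE]
  out$absorbed <- lapply(out$nonref_id, function(id)
    absorbed[[id]] %||% character(0))
  out
}

#' Assemble a pan-genome from the reference and non-reference sequences
#'
#' @param ref `list(genome, genes)` as from [simulate_reference()], or a
#'   named character vector of chromosomes.
#' @param nonref non-redundant tibble from [remove_redundancy()] (may be
#'   empty).
#' @param novel_genes optional gene-model tibble for genes hosted on
#'   non-reference sequences; hosts must exist in the pan-genome.
#' @return A `pangenome` object: list with `genome` (named sequences),
#'   `genes`, `nonref`, and `totals` (per-placement-class sequence counts
#'   and total lengths).
#' @export
build_pangenome <- function(ref, nonref = NULL, novel_genes = NULL) {
  genome <- if (is.list(ref) && !is.null(ref$genome)) ref$genome else
    as_named_dna(ref)
  genes <- if (is.list(ref) && !is.null(ref$genes)) ref$genes else NULL
  if (is.null(nonref) || nrow(nonref) == 0L) {
    nonref <- tibble(nonref_id = character(), length = integer(),
                     placement = character(), seq = character())
  }
  dup <- intersect(names(genome), nonref$nonref_id)
  if (length(dup))
    abort(paste0("duplicate sequence id between reference and non-reference: ",
                 paste(dup, collapse = ", ")))
  if (anyDuplicated(nonref$nonref_id)) abort("duplicate non-reference ids")
  pan <- c(genome, setNames(nonref$seq, nonref$nonref_id))
  if (!is.null(novel_genes) && nrow(novel_genes)) {
    missing_host <- setdiff(unique(novel_genes$seqnames), names(pan))
    if (length(missing_host))
      abort(paste0("novel gene host sequence(s) not in pan-genome: ",
                   paste(missing_host, collapse = ", ")))
    genes <- bind_rows(genes, novel_genes)
  }
  totals <- nonref |>
    mutate(group = if_else(.data$placement == "none", "fully_unaligned",
                           "partially_unaligned")) |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), total_bp = sum(.data$length), .groups = "drop")
  structure(list(genome = pan, genes = genes, nonref = nonref,
                 totals = totals, ref_names = names(genome)),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> %d reference + %d non-reference sequences (%s bp non-ref)\n",
              length(x$ref_names), nrow(x$nonref),
              format(sum(x$nonref$length), big.mark = ",")))
  invisible(x)
}

#' Fraction of reads mapping to a target sequence set
#'
#' A read counts as mapped when at least one alignment block covers at least
#' `min_cover` of its length (default 0.9, so substitution noise up to a few
#' percent never unmaps a read).
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param target a `pangenome`, or named sequences, or a prebuilt
#'   [seed_index()].
#' @param t a [pav_thresholds()] object.
#' @param min_cover minimum fraction of the read covered by one block.
#' @param index optional prebuilt [seed_index()] over the target (saves
#'   rebuilding when calling per sample).
#' @return Mapped fraction in `[0, 1]`.
#' @export
mapping_rate <- function(reads, target, t = pav_thresholds(),
                         min_cover = 0.9, index = NULL) {
  reads <- as_named_dna(reads, "read")
  if (length(reads) == 0L) return(NA_real_)
  if (is.null(index)) {
    genome <- if (inherits(target, "pangenome")) target$genome else
      if (inherits(target, "seed_index")) NULL else as_named_dna(target)
    index <- if (inherits(target, "seed_index")) target else seed_index(genome)
  }
  b <- align(reads, index, min_block_len = 50L)
  if (nrow(b) == 0L) return(0)
  ok <- b$block_len >= min_cover * b$q_len
  mean(names(reads) %in% unique(b$query_id[ok]))
}
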