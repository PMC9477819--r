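# Multi-caller SV merging (SURVIVOR-parameter semantics: max breakpoint
# distance 1000 bp, support >= 2 callers, type and strand agreement, no
# distance scaling, min size 30 bp), DEL-SV-derived PAV calls, a perfect
# tandem-repeat fraction for the insertion filter, and best-hit mapping of
# insertion sequences to the pan-genome.
#
# Clustering is seeded rather than single-linkage: the leftmost unassigned
# call seeds a cluster and recruits, per other caller, the closest
# unassigned call whose start and end both lie within the distance cap.
# Pure single linkage chains distinct neighbouring events (deletions of
# adjacent genes can sit closer than the 1000 bp cap) into one cluster and
# the one-call-per-caller rule would then discard genuine calls; seeding
# keeps neighbouring events separate the way SURVIVOR's pairwise merging
# does.

#' Merge SV calls across callers
#'
#' Calls smaller than `sv_min_size` are dropped; calls of the same type (and
#' strand, when required) on the same chromosome are clustered around seed
#' calls: the leftmost unassigned call opens a cluster and recruits, from
#' each other caller, its closest unassigned call whose start and end
#' breakpoints both differ by at most `sv_merge_max_dist`; at most one call
#' per caller joins a cluster. Clusters supported by at least
#' `sv_merge_min_support` distinct callers are reported with median
#' consensus breakpoints.
#'
#' @param calls tibble of SV calls (`caller`, `sample`, `chrom`, `pos`,
#'   `end`, `type`, `svlen`, `strands`, `genotype`, `id`), e.g. from
#'   [simulate_sv_callsets()] or [read_sv_tsv()]; merge one sample at a
#'   time.
#' @param t a [pav_thresholds()] object.
#' @return A `merged_svs` tibble: `chrom`, `pos`, `end`, `type`, `svlen`,
#'   `support`, `genotype` (hom iff all members hom), `callers` and
#'   `member_ids` list columns.
#' @export
merge_svs <- function(calls, t = pav_thresholds()) {
  empty <- structure(
    tibble(chrom = character(), pos = integer(), end = integer(),
           type = character(), svlen = integer(), support = integer(),
           genotype = character(), callers = list(), member_ids = list()),
    class = c("merged_svs", class(tibble())))
  if (nrow(calls) == 0L) return(empty)
  if (anyDuplicated(calls[, c("caller", "id")]))
    abort("input error: duplicate (caller, call id)")
  if (length(unique(calls$sample)) > 1L)
    abort("merge_svs expects calls of a single sample")
  calls <- calls[abs(calls$svlen) >= t$sv_min_size, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty)
  keys <- paste(calls$chrom,
                if (t$sv_merge_type_match) calls$type else "",
                if (t$sv_merge_strand_match) calls$strands else "")
  out <- list()
  D <- t$sv_merge_max_dist
  for (ky in unique(keys)) {
    g <- calls[keys == ky, , drop = FALSE]
    g <- g[order(g$pos, g$end, g$caller), , drop = FALSE]
    n <- nrow(g)
    unassigned <- rep(TRUE, n)
    for (s in seq_len(n)) {
      if (!unassigned[s]) next
      members <- s
      unassigned[s] <- FALSE
      for (cl in setdiff(unique(g$caller), g$caller[s])) {
        cand <- which(unassigned & g$caller == cl &
                        abs(g$pos - g$pos[s]) <= D &
                        abs(g$end - g$end[s]) <= D)
        if (length(cand) == 0L) next
        best <- cand[which.min(abs(g$pos[cand] - g$pos[s]) +
                                 abs(g$end[cand] - g$end[s]))]
        members <- c(members, best)
        unassigned[best] <- FALSE
      }
      m <- g[members, , drop = FALSE]
      if (length(unique(m$caller)) < t$sv_merge_min_support) next
      out[[length(out) + 1L]] <- tibble(
        chrom = m$chrom[1], pos = as.integer(round(median(m$pos))),
        end = as.integer(round(median(m$end))), type = m$type[1],
        svlen = as.integer(round(median(m$svlen))),
        support = length(unique(m$caller)),
        genotype = if (all(m$genotype == "hom")) "hom" else
          if (all(m$genotype == "het")) "het" else "unknown",
        callers = list(sort(unique(m$caller))),
        member_ids = list(m$id))
    }
  }
  if (length(out) == 0L) return(empty)
  res <- bind_rows(out) |> arrange(.data$chrom, .data$pos)
  structure(res, class = c("merged_svs", class(tibble())))
}

#' Gene PAV calls derived from merged deletion SVs
#'
#' Deleted intervals are subtracted from an everywhere-covered track over the
#' reference; CDS coverage and the > 80% presence rule are then reused
#' verbatim. Set `homozygous_only = TRUE` to restrict to homozygous DEL-SVs.
#'
#' @param merged a `merged_svs` tibble for one sample.
#' @param genes gene-model tibble (reference genes).
#' @param seq_lengths named vector of reference sequence lengths.
#' @param t a [pav_thresholds()] object.
#' @param homozygous_only use only genotype-hom DELs.
#' @return Tibble: `gene_id`, `coverage`, `present`.
#' @export
del_sv_pav <- function(merged, genes, seq_lengths, t = pav_thresholds(),
                       homozygous_only = FALSE) {
  dels <- merged[merged$type == "DEL", , drop = FALSE]
  if (homozygous_only) dels <- dels[dels$genotype == "hom", , drop = FALSE]
  track <- lapply(names(seq_lengths), function(ch) {
    full <- IRanges::IRanges(1L, as.integer(seq_lengths[[ch]]))
    d <- dels[dels$chrom == ch, , drop = FALSE]
    cov <- if (nrow(d)) IRanges::setdiff(full, iranges0(d$pos, d$end)) else full
    if (length(cov) == 0L) return(NULL)
    tibble(target = ch, start = IRanges::start(cov) - 1L,
           end = IRanges::end(cov), depth = 1L)
  })
  track <- bind_rows(track[!vapply(track, is.null, logical(1))])
  cov <- cds_coverage(genes, track, t)
  cov |> mutate(present = call_presence(.data$coverage, t))
}

#' Fraction of a sequence inside perfect tandem repeats
#'
#' Scans all periods up to `max_period` for perfect tandem tracts of at
#' least `min_tract` bp and returns the fraction of bases covered by their
#' union. A deliberately simple stand-in for full tandem-repeat masking; a
#' precomputed mask BED can be supplied to [filter_ins()] instead.
#'
#' @param seq DNA string.
#' @param max_period maximum repeat period (default 6).
#' @param min_tract minimum tract length in bp (default 20).
#' @return Fraction in `[0, 1]`.
#' @export
repeat_fraction <- function(seq, max_period = 6L, min_tract = 20L) {
  n <- nchar(seq)
  if (n == 0L) return(0)
  x <- utf8ToInt(seq)
  tracts <- list()
  for (p in seq_len(min(max_period, n - 1L))) {
    eq <- x[seq_len(n - p)] == x[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + p >= min_tract)
    if (!any(keep)) next
    # a run of L position-matches at period p implies a tract of L + p bases
    tracts[[p]] <- IRanges::IRanges(starts[keep], ends[keep] + p)
  }
  if (length(tracts) == 0L) return(0)
  un <- IRanges::reduce(do.call(c, tracts[!vapply(tracts, is.null, logical(1))]))
  sum(IRanges::width(un)) / n
}

#' Filter insertion calls by repeat content
#'
#' Drops INS calls whose sequence is more than half repetitive (strictly
#' greater than `ins_max_repeat_fraction`); exactly half is kept.
#'
#' @param ins_calls tibble of INS calls with a `seq` column, or with
#'   `repeat_frac` precomputed (e.g. from an external repeat mask).
#' @param t a [pav_thresholds()] object.
#' @return The kept rows, with a `repeat_frac` column.
#' @export
filter_ins <- function(ins_calls, t = pav_thresholds()) {
  if (!"repeat_frac" %in% names(ins_calls)) {
    ins_calls$repeat_frac <- vapply(ins_calls$seq, repeat_fraction, numeric(1))
  }
  ins_calls[ins_calls$repeat_frac <= t$ins_max_repeat_fraction, , drop = FALSE]
}

#' Map an insertion sequence to the pan-genome
#'
#' Best hit by (aligned length, identity) lexicographic order across all
#' pan-genome sequences; `novel` marks hits on non-reference sequences.
#'
#' @param ins_seq insertion sequence.
#' @param pan a `pangenome` object or a prebuilt [seed_index()] over one.
#' @param t a [pav_thresholds()] object.
#' @param ref_names reference sequence names (taken from `pan` when it is a
#'   `pangenome`).
#' @return `NULL` when unmapped, else a one-row tibble `target`, `t_start`,
#'   `t_end`, `identity`, `novel`.
#' @export
map_ins_to_pangenome <- function(ins_seq, pan, t = pav_thresholds(),
                                 ref_names = NULL) {
  if (inherits(pan, "pangenome")) {
    ref_names <- ref_names %||% pan$ref_names
    idx <- seed_index(pan$genome)
  } else if (inherits(pan, "seed_index")) {
    idx <- pan
  } else {
    idx <- seed_index(as_named_dna(pan))
  }
  b <- align(c(ins = unname(ins_seq)), idx,
             min_block_len = min(100L, nchar(ins_seq)))
  if (nrow(b) == 0L) return(NULL)
  b <- b[order(-b$block_len, -b$identity), , drop = FALSE]
  best <- b[1, ]
  tibble(target = best$target_id, t_start = best$t_start,
         t_end = best$t_end, identity = best$identity,
         novel = !is.null(ref_names) && !(best$target_id %in% ref_names))
}
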