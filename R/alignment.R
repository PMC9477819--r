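# Exact-seed chaining aligner and alignment I/O.
#
# The aligner is deliberately minimal: exact k-mer seeds on both strands,
# chained by identical (target, strand, diagonal) within a gap budget, each
# chain extended ungapped with an X-drop score and scored by column identity.
# This is adequate for substitution-only sequence (the simulator never plants
# indels); real-data users supply PAF from an external aligner instead.
# Alignment blocks are the currency of every classification and placement
# rule downstream: one row per local alignment, 0-based half-open on both
# query and target.

#' Build an exact k-mer seed index over target sequences
#'
#' @param targets named character vector or `DNAStringSet` of DNA sequences.
#' @param k seed length in bp (k >= 8). k-mers containing N are skipped.
#' @return A `seed_index` object.
#' @examples
#' idx <- seed_index(c(t1 = "ACGTACGTACGTACGT"), k = 8)
#' @export
seed_index <- function(targets, k = 15L) {
  targets <- as_named_dna(targets, "target")
  if (length(targets) == 0L) abort("empty target set")
  if (anyDuplicated(names(targets))) abort("duplicate target names")
  k <- as.integer(k)
  if (k < 8L) abort("k must be >= 8")
  tabs <- lapply(seq_along(targets), function(i) {
    s <- targets[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    if (!any(ok)) return(NULL)
    data.table(kmer = km[ok], tid = i, tpos = starts[ok] - 1L)
  })
  seeds <- rbindlist(tabs)
  if (nrow(seeds) == 0L) {
    seeds <- data.table(kmer = character(), tid = integer(), tpos = integer())
  }
  setkey(seeds, kmer)
  structure(list(seeds = seeds, targets = targets, k = k),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d targets, k = %d, %d seed positions\n",
              length(x$targets), x$k, nrow(x$seeds)))
  invisible(x)
}

# X-drop ungapped extension helper: outward match vector -> extension length.
# Besides the X-drop stop, an accepted extension must keep >= 90% identity
# (score >= 0.8 * length); this stops extensions at novel-sequence junctions,
# where random matches would otherwise drift a few bases past the boundary.
.extend_len <- function(eq, xdrop) {
  if (length(eq) == 0L) return(0L)
  sc <- cumsum(ifelse(eq, 1L, -1L))
  cm <- cummax(sc)
  stop_at <- which(cm - sc > xdrop)
  lim <- if (length(stop_at)) stop_at[1L] else length(sc)
  jj <- seq_len(lim)
  ok <- which(sc[jj] >= 0.8 * jj)
  if (length(ok) == 0L) return(0L)
  ok[which.max(sc[ok])]
}

#' Align queries against a seed index
#'
#' Seeds are chained on identical (target, strand, diagonal) with at most
#' `gap_budget` bp between consecutive seed starts, extended ungapped in both
#' directions under an X-drop criterion, and scored by exact column
#' comparison. Overlapping chains are all reported; selection happens only in
#' [summarize_query()].
#'
#' @param query named character vector or `DNAStringSet`.
#' @param index a [seed_index()].
#' @param min_block_len minimum reported block length in bp.
#' @param gap_budget max unseeded gap (bp) bridged within one chain.
#' @param xdrop score drop ending the ungapped extension (match +1,
#'   mismatch -1).
#' @return Tibble of alignment blocks with columns `query_id`, `q_len`,
#'   `q_start`, `q_end`, `target_id`, `t_len`, `t_start`, `t_end`, `strand`,
#'   `block_len`, `n_match`, `identity`, sorted by (`query_id`, `q_start`).
#'   Coordinates are 0-based half-open on the forward strand of both
#'   sequences; `strand == "-"` means the reverse complement of the query
#'   aligns.
#' @export
align <- function(query, index, min_block_len = 100L, gap_budget = 100L,
                  xdrop = 10L) {
  stopifnot(inherits(index, "seed_index"))
  qs <- as_named_dna(query, "query")
  k <- index$k
  qlens <- nchar(qs)
  tlens <- nchar(index$targets)
  tints <- new.env(parent = emptyenv())
  get_tints <- function(i) {
    key <- as.character(i)
    v <- tints[[key]]
    if (is.null(v)) {
      v <- utf8ToInt(index$targets[[i]])
      tints[[key]] <- v
    }
    v
  }
  prefloor <- min(as.integer(min_block_len), k + 5L)

  out <- vector("list", 2L)
  for (si in 1:2) {
    str <- c("+", "-")[si]
    wseqs <- if (str == "+") qs else setNames(revcomp(unname(qs)), names(qs))
    qtabs <- lapply(seq_along(wseqs), function(i) {
      s <- wseqs[[i]]
      n <- nchar(s)
      if (n < k) return(NULL)
      starts <- seq_len(n - k + 1L)
      km <- substring(s, starts, starts + k - 1L)
      ok <- !grepl("N", km, fixed = TRUE)
      if (!any(ok)) return(NULL)
      data.table(kmer = km[ok], qid = i, qpos = starts[ok] - 1L)
    })
    qdt <- rbindlist(qtabs)
    if (is.null(qdt) || nrow(qdt) == 0L || nrow(index$seeds) == 0L) next
    hits <- index$seeds[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) next
    hits[, diag_ := tpos - qpos]
    setorder(hits, qid, tid, diag_, qpos)
    brk <- c(TRUE, diff(hits$qid) != 0L | diff(hits$tid) != 0L |
               diff(hits$diag_) != 0L)
    brk <- brk | c(TRUE, diff(hits$qpos) > gap_budget)
    hits[, chain := cumsum(brk)]
    chains <- hits[, .(qid = qid[1L], tid = tid[1L], diag_ = diag_[1L],
                       q_start = min(qpos), q_end = max(qpos) + k),
                   by = chain]
    chains <- chains[q_end - q_start >= prefloor]
    if (nrow(chains) == 0L) next

    qint_cache <- new.env(parent = emptyenv())
    get_qints <- function(i) {
      key <- as.character(i)
      v <- qint_cache[[key]]
      if (is.null(v)) {
        v <- utf8ToInt(wseqs[[i]])
        qint_cache[[key]] <- v
      }
      v
    }
    res <- vector("list", nrow(chains))
    for (r in seq_len(nrow(chains))) {
      qid <- chains$qid[r]; tid <- chains$tid[r]
      qi <- get_qints(qid); ti <- get_tints(tid)
      qn <- qlens[[qid]]; tn <- tlens[[tid]]
      qs0 <- chains$q_start[r]; qe0 <- chains$q_end[r]
      d <- chains$diag_[r]
      ts0 <- qs0 + d; te0 <- qe0 + d
      # left extension
      L <- min(qs0, ts0, 400L)
      if (L > 0L) {
        j <- seq_len(L)
        ext <- .extend_len(qi[qs0 - j + 1L] == ti[ts0 - j + 1L], xdrop)
        qs0 <- qs0 - ext; ts0 <- ts0 - ext
      }
      # right extension
      R <- min(qn - qe0, tn - te0, 400L)
      if (R > 0L) {
        j <- seq_len(R)
        ext <- .extend_len(qi[qe0 + j] == ti[te0 + j], xdrop)
        qe0 <- qe0 + ext; te0 <- te0 + ext
      }
      len <- qe0 - qs0
      if (len < min_block_len) { res[[r]] <- NULL; next }
      nm <- sum(qi[(qs0 + 1L):qe0] == ti[(ts0 + 1L):te0])
      if (str == "-") {
        q1 <- qn - qe0; q2 <- qn - qs0
      } else {
        q1 <- qs0; q2 <- qe0
      }
      res[[r]] <- data.table(
        query_id = names(qs)[qid], q_len = qn, q_start = q1, q_end = q2,
        target_id = names(index$targets)[tid], t_len = tn,
        t_start = ts0, t_end = te0, strand = str,
        block_len = len, n_match = nm, identity = nm / len)
    }
    out[[si]] <- rbindlist(res)
  }
  blocks <- rbindlist(out)
  if (is.null(blocks) || nrow(blocks) == 0L) {
    return(tibble(query_id = character(), q_len = integer(),
                  q_start = integer(), q_end = integer(),
                  target_id = character(), t_len = integer(),
                  t_start = integer(), t_end = integer(), strand = character(),
                  block_len = integer(), n_match = integer(),
                  identity = numeric()))
  }
  setorder(blocks, query_id, q_start, t_start)
  as_tibble(blocks)
}

#' Summarise alignment blocks per query
#'
#' `covered_fraction` is the width of the union of the query intervals
#' divided by query length. `weighted_identity` is the block-length-weighted
#' mean identity over the best non-overlapping subset of blocks, chosen by
#' maximal total aligned length (ties broken toward higher identity) with
#' weighted-interval-scheduling dynamic programming.
#'
#' @param blocks tibble of alignment blocks (one or several queries).
#' @param query_len named vector of query lengths; defaults to the blocks'
#'   `q_len` column.
#' @return Tibble with `query_id`, `covered_fraction`, `weighted_identity`.
#' @export
summarize_query <- function(blocks, query_len = NULL) {
  if (nrow(blocks) == 0L) {
    if (is.null(query_len) || is.null(names(query_len))) {
      return(tibble(query_id = character(), covered_fraction = numeric(),
                    weighted_identity = numeric()))
    }
    return(tibble(query_id = names(query_len), covered_fraction = 0,
                  weighted_identity = 0))
  }
  if (is.null(query_len)) {
    query_len <- setNames(blocks$q_len, blocks$query_id)
    query_len <- query_len[!duplicated(names(query_len))]
  } else if (is.null(names(query_len))) {
    stopifnot(length(query_len) == 1L)
    query_len <- setNames(rep(query_len, length(unique(blocks$query_id))),
                          unique(blocks$query_id))
  }
  res <- lapply(names(query_len), function(q) {
    b <- blocks[blocks$query_id == q, , drop = FALSE]
    qlen <- as.numeric(query_len[[q]])
    if (nrow(b) == 0L) {
      return(tibble(query_id = q, covered_fraction = 0, weighted_identity = 0))
    }
    cov <- union_width0(b$q_start, b$q_end) / qlen
    o <- order(b$q_end, b$q_start)
    b <- b[o, , drop = FALSE]
    nb <- nrow(b)
    # predecessor: last block ending at or before this block's start
    pred <- findInterval(b$q_start, b$q_end)
    len_dp <- numeric(nb + 1L)
    idm_dp <- numeric(nb + 1L)
    for (i in seq_len(nb)) {
      skip_len <- len_dp[i]; skip_idm <- idm_dp[i]
      take_len <- len_dp[pred[i] + 1L] + b$block_len[i]
      take_idm <- idm_dp[pred[i] + 1L] + b$block_len[i] * b$identity[i]
      if (take_len > skip_len ||
          (take_len == skip_len && take_idm > skip_idm)) {
        len_dp[i + 1L] <- take_len; idm_dp[i + 1L] <- take_idm
      } else {
        len_dp[i + 1L] <- skip_len; idm_dp[i + 1L] <- skip_idm
      }
    }
    wid <- if (len_dp[nb + 1L] > 0) idm_dp[nb + 1L] / len_dp[nb + 1L] else 0
    tibble(query_id = q, covered_fraction = cov, weighted_identity = wid)
  })
  bind_rows(res)
}

#' Read alignment blocks from a PAF file
#'
#' Standard minimap2-dialect PAF columns 1-12. Identity is
#' `matches / alignment_block_length` from columns 10 and 11.
#'
#' @param path PAF file path.
#' @return Tibble of alignment blocks as produced by [align()].
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(query_id = character(), q_len = integer(),
                  q_start = integer(), q_end = integer(),
                  target_id = character(), t_len = integer(),
                  t_start = integer(), t_end = integer(), strand = character(),
                  block_len = integer(), n_match = integer(),
                  identity = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 12L)
      abort(sprintf("PAF parse error at line %d: expected >= 12 columns, got %d",
                    i, length(p)))
    num <- suppressWarnings(as.numeric(p[c(2, 3, 4, 7, 8, 9, 10, 11)]))
    if (anyNA(num))
      abort(sprintf("PAF parse error at line %d: non-numeric coordinate", i))
    if (!p[5] %in% c("+", "-"))
      abort(sprintf("PAF parse error at line %d: bad strand '%s'", i, p[5]))
    tibble(query_id = p[1], q_len = as.integer(num[1]),
           q_start = as.integer(num[2]), q_end = as.integer(num[3]),
           target_id = p[6], t_len = as.integer(num[4]),
           t_start = as.integer(num[5]), t_end = as.integer(num[6]),
           strand = p[5],
           block_len = as.integer(num[2 + 1]) - as.integer(num[2]),
           n_match = as.integer(num[7]),
           identity = num[7] / num[8])
  })
  out <- bind_rows(rows)
  out$block_len <- out$q_end - out$q_start
  dplyr::arrange(out, .data$query_id, .data$q_start)
}

#' Write alignment blocks to a PAF file
#'
#' @param blocks tibble of alignment blocks.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  alen <- blocks$q_end - blocks$q_start
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   blocks$query_id, blocks$q_len, blocks$q_start, blocks$q_end,
                   blocks$strand, blocks$target_id, blocks$t_len,
                   blocks$t_start, blocks$t_end, blocks$n_match, alen, 255L)
  writeLines(lines, path)
  invisible(path)
}
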