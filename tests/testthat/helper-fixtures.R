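# Shared fixtures: all built in code, deterministic under fixed seeds.

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# plant exactly k substitutions at distinct positions; returns list(seq, k)
plant_subs <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  list(seq = paste(ch, collapse = ""), k = k, pos = pos)
}

# a small but complete study design used by non-acceptance tests
small_params <- function(seed = 11L, ...) {
  defaults <- list(
    seed = seed, chrom_len = 60000L, n_ref_genes = 24L, n_novel_genes = 3L,
    cohorts = list(
      case = list(n = 4L, absence = c(g001 = 1.0, g002 = 0.5)),
      control = list(n = 4L, absence = c(g001 = 0.0, g002 = 0.1))))
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_params, defaults)
}

# build a pav_matrix directly from a logical samples x genes presence matrix
make_pav_matrix <- function(presence, meta, seqnames = NULL) {
  genes_ids <- colnames(presence)
  if (is.null(seqnames)) seqnames <- rep("chr1", length(genes_ids))
  genes <- tibble::tibble(
    gene_id = genes_ids, transcript = "t1", seqnames = seqnames,
    start = 1000L * seq_along(genes_ids),
    end = 1000L * seq_along(genes_ids) + 500L, strand = "+", novel = FALSE)
  calls <- tibble::tibble(
    sample = rep(rownames(presence), times = ncol(presence)),
    gene_id = rep(genes_ids, each = nrow(presence)),
    coverage = as.numeric(as.vector(presence)),
    present = as.vector(presence))
  m <- structure(list(calls = calls, genes = genes, meta = meta,
                      labels = NULL), class = "pav_matrix")
  m$labels <- classify_core_distributed(m)
  m
}

# independent Fisher two-sided oracle: binomial-coefficient enumeration with
# the probability-ordering convention
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d; n <- row1 + row2
  lo <- max(0L, col1 - row2); hi <- min(row1, col1)
  k <- lo:hi
  pk <- choose(col1, k) * choose(col2, row1 - k) / choose(n, row1)
  pobs <- pk[match(a, k)]
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
}

# hand-computed Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# minimal manual alignment-block tibble
mk_blocks <- function(q_start, q_end, identity = 1, query_id = "q",
                      q_len = max(q_end, 1L), target_id = "t",
                      t_start = q_start, strand = "+") {
  tibble::tibble(
    query_id = query_id, q_len = q_len, q_start = q_start, q_end = q_end,
    target_id = target_id, t_len = 10L * q_len, t_start = t_start,
    t_end = t_start + (q_end - q_start), strand = strand,
    block_len = q_end - q_start,
    n_match = round(identity * (q_end - q_start)), identity = identity)
}
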