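test_that("the contig length filter keeps strictly longer than 500 bp", {
  set.seed(8)
  v <- setNames(c(rdna(400), rdna(500), rdna(501)), c("a", "b", "c"))
  expect_identical(names(filter_contigs(v)), "c")
  expect_length(filter_contigs(character(0)), 0L)
  tb <- tibble::tibble(contig_id = names(v), seq = unname(v))
  expect_equal(filter_contigs(tb)$contig_id, "c")
  big <- tibble::tibble(contig_id = c("x", "y"), length = c(10000L, 10000L))
  expect_equal(filter_contigs(big), big)
})

test_that("the 95/95 rule and flanking logic classify contigs", {
  t <- pav_thresholds()
  s_ref <- tibble::tibble(query_id = "c", covered_fraction = 0.96,
                          weighted_identity = 0.96)
  expect_equal(classify_contig(s_ref, mk_blocks(0L, 960L, query_id = "c",
                                                q_len = 1000L), 1000L, t),
               "REFERENCE")
  s_none <- tibble::tibble(query_id = "c", covered_fraction = 0,
                           weighted_identity = 0)
  expect_equal(classify_contig(s_none, mk_blocks(integer(0), integer(0)),
                               1000L, t), "FULLY_UNALIGNED")
  # aligned prefix only, high identity but half coverage -> one-end partial
  b <- mk_blocks(0L, 1000L, identity = 0.99, query_id = "c", q_len = 2000L)
  s_half <- tibble::tibble(query_id = "c", covered_fraction = 0.5,
                           weighted_identity = 0.99)
  expect_equal(classify_contig(s_half, b, 2000L, t), "PARTIAL_ONE_END")
  expect_error(classify_contig(s_half, b, 900L, t), "consistency")
})

test_that("non-reference segments are extracted with correct placements", {
  set.seed(9)
  ref <- c(chr2 = rdna(30000))
  idx <- seed_index(ref)
  t <- pav_thresholds()
  novel <- rdna(4000)
  # 6 kb contig: 2 kb aligned prefix + 4 kb novel tail -> ONE_END at the
  # flank boundary
  c1 <- paste0(substring(ref, 5001, 7000), novel)
  # 8 kb contig: 3 kb aligned + 2 kb novel + 3 kb aligned, reference flanks
  # 100 bp apart -> TWO_END bounded by both flanks
  c2 <- paste0(substring(ref, 10001, 13000), substring(novel, 1, 2000),
               substring(ref, 13101, 16100))
  # contig fully contained in the reference -> nothing extracted
  c3 <- substring(ref, 20001, 26000)
  contigs <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                            seq = c(c1, c2, c3))
  blocks <- align(setNames(contigs$seq, contigs$contig_id), idx)
  cls <- classify_contigs(contigs, blocks, t)
  expect_equal(cls$class[cls$contig_id == "c1"], "PARTIAL_ONE_END")
  expect_equal(cls$class[cls$contig_id == "c2"], "PARTIAL_TWO_END")
  expect_equal(cls$class[cls$contig_id == "c3"], "REFERENCE")

  nr <- extract_nonref(contigs, blocks, t)
  n1 <- nr[nr$origin_contig == "c1", ]
  expect_equal(nrow(n1), 1L)
  expect_equal(n1$placement, "one_end")
  expect_equal(n1$chrom, "chr2")
  expect_lt(abs(n1$length - 4000L), 20L)
  expect_lt(abs(n1$ref_left - 7000L), 20L)
  n2 <- nr[nr$origin_contig == "c2", ]
  expect_equal(nrow(n2), 1L)
  expect_equal(n2$placement, "two_end")
  expect_lt(abs(n2$length - 2000L), 20L)
  expect_lt(abs(n2$ref_left - 13000L), 20L)
  expect_lt(abs(n2$ref_right - 13100L), 20L)
  expect_false("c3" %in% nr$origin_contig)
  # fully unaligned contig comes out whole, unplaced
  c4 <- tibble::tibble(contig_id = "c4", seq = rdna(1200))
  b4 <- align(c(c4 = c4$seq), idx)
  nr4 <- extract_nonref(c4, b4, t)
  expect_equal(nr4$placement, "none")
  expect_equal(nr4$length, 1200L)
})

test_that("redundancy removal is greedy, containment-aware and idempotent", {
  set.seed(10)
  t <- pav_thresholds()
  s5k <- rdna(5000)
  nr <- tibble::tibble(
    nonref_id = c("dup1", "dup2", "cont", "other"),
    origin_contig = NA_character_,
    length = c(2000L, 2000L, 1000L, 1500L),
    placement = "none", chrom = NA_character_, ref_left = NA_integer_,
    ref_right = NA_integer_, side = NA_character_,
    seq = c(substring(s5k, 1, 2000), substring(s5k, 1, 2000),
            substring(s5k, 2500, 3499), rdna(1500)))
  nr_big <- dplyr::bind_rows(
    tibble::tibble(nonref_id = "host", origin_contig = NA_character_,
                   length = 5000L, placement = "none", chrom = NA_character_,
                   ref_left = NA_integer_, ref_right = NA_integer_,
                   side = NA_character_, seq = s5k), nr)
  kept <- remove_redundancy(nr_big, t)
  expect_setequal(kept$nonref_id, c("host", "other"))
  host_abs <- kept$absorbed[[which(kept$nonref_id == "host")]]
  expect_setequal(host_abs, c("dup1", "dup2", "cont"))
  # identical pair without a host: one kept, one absorbed
  kept2 <- remove_redundancy(nr[1:2, ], t)
  expect_equal(nrow(kept2), 1L)
  expect_equal(kept2$absorbed[[1]], setdiff(c("dup1", "dup2"),
                                            kept2$nonref_id))
  # disjoint sequences are all kept
  kept3 <- remove_redundancy(nr[3:4, ], t)
  expect_equal(nrow(kept3), 2L)
  # idempotence
  again <- remove_redundancy(kept, t)
  expect_equal(again$nonref_id, kept$nonref_id)
})

test_that("pan-genome assembly validates ids and reports additive totals", {
  set.seed(12)
  ref <- list(genome = c(chr1 = rdna(2000)),
              genes = tibble::tibble(gene_id = character(),
                                     transcript = character(),
                                     seqnames = character(),
                                     start = integer(), end = integer(),
                                     strand = character(), novel = logical()))
  empty_pan <- build_pangenome(ref, NULL)
  expect_identical(empty_pan$genome, ref$genome)
  nr <- tibble::tibble(
    nonref_id = c("n1", "n2", "n3"), length = c(800L, 600L, 400L),
    placement = c("none", "one_end", "two_end"),
    seq = c(rdna(800), rdna(600), rdna(400)))
  pan <- build_pangenome(ref, nr)
  expect_equal(sum(pan$totals$total_bp), sum(nr$length))
  expect_equal(pan$totals$total_bp[pan$totals$group == "fully_unaligned"],
               800L)
  expect_equal(pan$totals$total_bp[pan$totals$group == "partially_unaligned"],
               1000L)
  nr_dup <- nr; nr_dup$nonref_id[1] <- "chr1"
  expect_error(build_pangenome(ref, nr_dup), "duplicate")
  novel <- tibble::tibble(gene_id = "nvX", transcript = "t1",
                          seqnames = "missing_host", start = 0L, end = 100L,
                          strand = "+", novel = TRUE)
  expect_error(build_pangenome(ref, nr, novel), "host")
})

test_that("mapping rates are 1 for reference reads and monotone under the pan-genome", {
  set.seed(13)
  ref <- c(chr1 = rdna(20000))
  novel <- rdna(3000)
  ref_idx <- seed_index(ref)
  pan_idx <- seed_index(c(ref, nrs_1 = novel))
  mk_reads <- function(src, n) {
    starts <- sample(nchar(src) - 150, n)
    setNames(substring(src, starts, starts + 149), paste0("r", seq_len(n)))
  }
  ref_reads <- mk_reads(ref[[1]], 40)
  expect_equal(mapping_rate(ref_reads, ref_idx), 1.0)
  expect_equal(mapping_rate(ref_reads, pan_idx), 1.0)
  nov_reads <- mk_reads(novel, 40)
  expect_equal(mapping_rate(nov_reads, ref_idx), 0.0)
  expect_equal(mapping_rate(nov_reads, pan_idx), 1.0)
  mixed <- c(ref_reads, nov_reads)
  expect_gte(mapping_rate(mixed, pan_idx), mapping_rate(mixed, ref_idx))
})
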