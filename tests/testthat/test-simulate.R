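test_that("identical parameters give byte-identical study files", {
  p <- small_params()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(p, dir = d1)
  simulate_study(p, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  expect_gt(length(f1), 10L)
})

test_that("reference simulation is deterministic and rejects infeasible packing", {
  p <- small_params()
  r1 <- simulate_reference(p)
  r2 <- simulate_reference(p)
  expect_identical(r1, r2)
  expect_equal(names(r1$genome), c("chr1", "chr2", "chrY"))
  expect_equal(length(unique(r1$genes$gene_id)), 24L)
  # genes do not overlap within a chromosome
  for (ch in unique(r1$genes$seqnames)) {
    sp <- gene_spans(r1$genes[r1$genes$seqnames == ch, ])
    sp <- sp[order(sp$start), ]
    if (nrow(sp) > 1) expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  }
  # no genes at all
  p0 <- sim_params(seed = 1, n_ref_genes = 0, n_novel_genes = 0,
                   chrom_len = 5000,
                   cohorts = list(a = list(n = 1, absence = NULL)))
  expect_equal(nrow(simulate_reference(p0)$genes), 0L)
  # infeasible packing
  expect_error(
    simulate_reference(sim_params(seed = 1, chrom_len = 1000,
                                  n_ref_genes = 120)),
    "sizing")
})

test_that("degenerate absence frequencies produce degenerate truth", {
  p <- small_params()  # g001 at 1.0 in case, 0.0 in control
  ref <- simulate_reference(p)
  pop <- simulate_population(ref, p)
  tr <- pop$truth$pav_truth
  case_g1 <- tr[tr$gene_id == "g001" & grepl("^case", tr$sample), ]
  ctrl_g1 <- tr[tr$gene_id == "g001" & grepl("^control", tr$sample), ]
  expect_true(all(!case_g1$present))
  expect_true(all(ctrl_g1$present))
  expect_error(
    simulate_population(ref, small_params(seed = 1,
      cohorts = list(a = list(n = 2, absence = c(nope = 0.5))))),
    "unknown gene id")
  # zero frequencies everywhere: all autosomal genes present
  p0 <- small_params(cohorts = list(a = list(n = 3, absence = NULL)),
                     n_novel_genes = 0, sex_ratio = 1)
  pop0 <- simulate_population(simulate_reference(p0), p0)
  expect_true(all(pop0$truth$pav_truth$present))
})

test_that("planted absence counts fall in the binomial 99% interval", {
  p <- sim_params(seed = 21, chrom_len = 50000L, n_ref_genes = 12L,
                  n_novel_genes = 0L,
                  cohorts = list(
                    A = list(n = 50L, absence = c(g001 = 0.6)),
                    B = list(n = 50L, absence = c(g001 = 0.0))))
  pop <- simulate_population(simulate_reference(p), p)
  tr <- pop$truth$pav_truth
  nA <- sum(!tr$present[tr$gene_id == "g001" & grepl("^A", tr$sample)])
  ci <- qbinom(c(0.005, 0.995), 50, 0.6)
  expect_gte(nA, ci[1]); expect_lte(nA, ci[2])
  nB <- sum(!tr$present[tr$gene_id == "g001" & grepl("^B", tr$sample)])
  expect_equal(nB, 0L)
})

test_that("contigs conserve the genome and match the expected N50", {
  p <- small_params(contig_break_rate = 0, base_error_rate = 0)
  pop <- simulate_population(simulate_reference(p), p)
  ind <- pop$individuals[[1]]
  ct <- simulate_contigs(ind, p)
  expect_equal(nrow(ct), length(ind$seqs))  # one contig per chromosome
  for (ch in names(ind$seqs))
    expect_identical(ct$seq[ct$chrom == ch], ind$seqs[[ch]])
  # conservation with fragmentation
  p2 <- small_params(contig_break_rate = 2)
  pop2 <- simulate_population(simulate_reference(p2), p2)
  ind2 <- pop2$individuals[[1]]
  ct2 <- simulate_contigs(ind2, p2)
  for (ch in names(ind2$seqs)) {
    d <- ct2[ct2$chrom == ch, ]
    expect_identical(paste(d$seq[order(d$src_start)], collapse = ""),
                     ind2$seqs[[ch]])
  }
  # N50 against an independent re-simulation of the fragment process
  n50 <- function(x) { x <- sort(x, decreasing = TRUE)
                       x[which(cumsum(x) >= sum(x) / 2)[1]] }
  lens <- unlist(lapply(pop2$individuals[1:4], function(i)
    simulate_contigs(i, p2)$length))
  set.seed(99)
  oracle <- replicate(200, {
    L <- 60000L
    nb <- rpois(1, L * 2 / 1e4)
    b <- sort(sample.int(L - 1, min(nb, L - 1)))
    n50(diff(c(0, b, L)))
  })
  expect_lt(abs(n50(lens) - mean(oracle)) / mean(oracle), 0.2)
})

test_that("depth drops to zero over deletions and saturates present CDS", {
  p <- small_params()
  ref <- simulate_reference(p)
  pop <- simulate_population(ref, p)
  ind <- pop$individuals[["case_01"]]  # g001 deleted at frequency 1
  dp <- simulate_depth(ind, p)
  g1 <- ref$genes[ref$genes$gene_id == "g001", ]
  cov1 <- cds_coverage(g1, dp$track)
  expect_equal(cov1$coverage, 0)
  # present autosomal genes: depth-30 Poisson coverage leaves essentially
  # no CDS base uncovered (per-base miss probability exp(-30))
  present <- pop$truth$pav_truth
  present <- present$gene_id[present$sample == ind$sample_id & present$present]
  gp <- ref$genes[ref$genes$gene_id %in% present, ]
  covp <- cds_coverage(gp, dp$track)
  expect_gte(min(covp$coverage), 0.999)
  # zero depth -> empty track
  p0 <- small_params(depth = 0)
  dp0 <- simulate_depth(pop$individuals[[1]], p0)
  expect_equal(nrow(dp0$track), 0L)
})

test_that("long-read contigs span insertions with true reference flanks", {
  p <- small_params(cohorts = list(a = list(n = 6, absence = NULL)),
                    novel_carrier_freq = 1, sex_ratio = 1)
  ref <- simulate_reference(p)
  pop <- simulate_population(ref, p)
  ind <- pop$individuals[[1]]
  lr <- simulate_long_reads(ind, p)
  expect_equal(sort(lr$gene_id), sort(pop$truth$novel_gene_loci$gene_id))
  loci <- pop$truth$novel_gene_loci
  for (i in seq_len(nrow(lr))) {
    loc <- loci[loci$gene_id == lr$gene_id[i], ]
    cass <- pop$cassettes[[loc$host_id]]
    expect_gte(nchar(lr$seq[i]), loc$cassette_len + 2 * 3000)
    # the contig contains the cassette verbatim
    expect_true(grepl(cass, lr$seq[i], fixed = TRUE))
    # flanks equal the reference sequence around the insertion point (this
    # sample carries no deletions)
    at <- regexpr(cass, lr$seq[i], fixed = TRUE)[1]
    left <- substring(lr$seq[i], at - 500, at - 1)
    expect_identical(left,
                     substring(ref$genome[[loc$chrom]], loc$pos - 499,
                               loc$pos))
  }
  # no insertions carried -> empty
  p0 <- small_params(novel_carrier_freq = 0)
  pop0 <- simulate_population(simulate_reference(p0), p0)
  expect_equal(nrow(simulate_long_reads(pop0$individuals[[1]], p0)), 0L)
})

test_that("SV callsets reproduce truth exactly when noise-free", {
  p <- small_params(sv_caller_fn_rate = 0, sv_caller_fp_rate = 0,
                    sv_caller_jitter_sd = 0)
  pop <- simulate_population(simulate_reference(p), p)
  sv <- simulate_sv_callsets(pop$truth$sv_truth, p)
  truth <- pop$truth$sv_truth[order(pop$truth$sv_truth$sample,
                                    pop$truth$sv_truth$chrom,
                                    pop$truth$sv_truth$pos), ]
  for (cl in unique(sv$caller)) {
    got <- sv[sv$caller == cl, ]
    got <- got[order(got$sample, got$chrom, got$pos), ]
    expect_equal(got$pos, truth$pos)
    expect_equal(got$end, truth$end)
    expect_equal(got$type, truth$type)
    expect_equal(got$svlen, truth$svlen)
  }
  # all-false-negative callers emit nothing
  p1 <- small_params(sv_caller_fn_rate = 1, sv_caller_fp_rate = 0)
  expect_equal(nrow(simulate_sv_callsets(pop$truth$sv_truth, p1)), 0L)
})

test_that("breakpoint jitter has the half-normal mean offset", {
  p <- sim_params(seed = 31, chrom_len = 60000L, n_ref_genes = 20L,
                  n_novel_genes = 0L, sex_ratio = 1,
                  cohorts = list(A = list(n = 30L, absence = setNames(
                    rep(0.5, 5), sprintf("g%03d", 1:5)))),
                  sv_caller_fn_rate = 0, sv_caller_fp_rate = 0,
                  sv_caller_jitter_sd = 50)
  pop <- simulate_population(simulate_reference(p), p)
  truth <- pop$truth$sv_truth
  truth <- truth[order(truth$sample, truth$chrom, truth$pos), ]
  sv <- simulate_sv_callsets(truth, p)
  offs <- unlist(lapply(unique(sv$caller), function(cl) {
    got <- sv[sv$caller == cl, ]
    got <- got[order(got$sample, got$id), ]  # ids follow truth order
    got$pos - truth$pos
  }))
  expect_gt(length(offs), 150)
  # E|N(0, 50)| = 50 * sqrt(2/pi) ~= 39.9
  expect_lt(abs(mean(abs(offs)) - 50 * sqrt(2 / pi)), 8)
})

test_that("deleted genes in the PAV truth match the DEL truth exactly", {
  p <- small_params()
  pop <- simulate_population(simulate_reference(p), p)
  del_pav <- pop$truth$pav_truth
  del_pav <- del_pav[!del_pav$present & del_pav$reason %in% "deleted", ]
  del_sv <- pop$truth$sv_truth[pop$truth$sv_truth$type == "DEL", ]
  expect_setequal(paste(del_pav$sample, del_pav$gene_id),
                  paste(del_sv$sample, del_sv$gene_id))
  ins_sv <- pop$truth$sv_truth[pop$truth$sv_truth$type == "INS", ]
  carried <- pop$truth$pav_truth
  carried <- carried[carried$present & grepl("^nv", carried$gene_id), ]
  expect_setequal(paste(carried$sample, carried$gene_id),
                  paste(ins_sv$sample, ins_sv$gene_id))
})
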