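# Deterministic synthetic-study generator.
#
# Emulates, at toy scale, a paired-cohort whole-genome PAV study: a small
# multi-chromosome reference (last chromosome is chrY), annotated genes,
# cohorts of individuals carrying planted full-gene deletions at
# cohort-specific frequencies, planted novel-gene insertion cassettes at
# fixed intergenic loci, fragmentary per-sample contigs, uniform read depth
# with dropout over deleted regions, long-read contigs spanning novel
# insertions with reference flanks, and jittered multi-caller SV callsets.
# A single seed makes every output byte-identical across runs; per-sample
# randomness uses sub-seeds derived by stable hashing of the sample id so
# adding a sample never perturbs the others.

#' Simulation parameters for a synthetic PAV study
#'
#' Defaults define the package's reference study design: 3 chromosomes of
#' 100 kb (one chrY), 120 reference genes (10% on chrY), 6 novel genes
#' carried by half the population, two cohorts of 25 samples ("case" and
#' "control") with ten genes planted at elevated case absence frequencies
#' (g001-g005 at 0.6, g006-g010 at 0.3, controls at 0.05), read length 150,
#' mean depth 30, one assembly break per 10 kb, error-free bases, and SV
#' callers with 50 bp breakpoint jitter, 10% false-negative and 5%
#' false-positive rates.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes number of chromosomes; the last is named "chrY".
#' @param chrom_len chromosome length in bp.
#' @param n_ref_genes number of reference genes.
#' @param n_novel_genes number of novel (non-reference) genes.
#' @param cds_exons_per_gene integer range (min, max) of CDS exons per gene.
#' @param gene_len integer range (min, max) of gene span in bp.
#' @param chry_gene_frac fraction of reference genes placed on chrY.
#' @param cohorts named list; each element `list(n =, absence = named
#'   numeric)` giving cohort size and per-gene absence frequencies.
#' @param novel_carrier_freq fraction of samples carrying each novel
#'   insertion.
#' @param sex_ratio fraction of male samples.
#' @param read_len read length in bp.
#' @param depth mean per-base depth.
#' @param contig_break_rate expected assembly breaks per 10 kb.
#' @param base_error_rate substitution rate per bp in contigs.
#' @param sv_caller_jitter_sd Gaussian sd (bp) of caller breakpoint jitter.
#' @param sv_caller_fn_rate per-call false-negative rate of each caller.
#' @param sv_caller_fp_rate false positives per true SV per caller.
#' @param long_read_flank reference flank (bp) on each side of a simulated
#'   long-read contig spanning a novel insertion.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_len = 100000L,
                       n_ref_genes = 120L,
                       n_novel_genes = 6L,
                       cds_exons_per_gene = c(1L, 3L),
                       gene_len = c(600L, 2000L),
                       chry_gene_frac = 0.1,
                       cohorts = NULL,
                       novel_carrier_freq = 0.5,
                       sex_ratio = 0.5,
                       read_len = 150L,
                       depth = 30,
                       contig_break_rate = 1,
                       base_error_rate = 0,
                       sv_caller_jitter_sd = 50,
                       sv_caller_fn_rate = 0.1,
                       sv_caller_fp_rate = 0.05,
                       long_read_flank = 4000L) {
  if (is.null(cohorts)) cohorts <- default_cohorts()
  p <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
            chrom_len = as.integer(chrom_len),
            n_ref_genes = as.integer(n_ref_genes),
            n_novel_genes = as.integer(n_novel_genes),
            cds_exons_per_gene = as.integer(cds_exons_per_gene),
            gene_len = as.integer(gene_len),
            chry_gene_frac = chry_gene_frac, cohorts = cohorts,
            novel_carrier_freq = novel_carrier_freq, sex_ratio = sex_ratio,
            read_len = as.integer(read_len), depth = depth,
            contig_break_rate = contig_break_rate,
            base_error_rate = base_error_rate,
            sv_caller_jitter_sd = sv_caller_jitter_sd,
            sv_caller_fn_rate = sv_caller_fn_rate,
            sv_caller_fp_rate = sv_caller_fp_rate,
            long_read_flank = as.integer(long_read_flank))
  stopifnot(p$n_chromosomes >= 1L, p$chrom_len >= 1000L, p$n_ref_genes >= 0L,
            p$n_novel_genes >= 0L, length(p$cds_exons_per_gene) == 2L,
            p$cds_exons_per_gene[1] >= 1L,
            p$cds_exons_per_gene[2] >= p$cds_exons_per_gene[1],
            length(p$gene_len) == 2L, p$gene_len[1] >= 200L,
            p$gene_len[2] >= p$gene_len[1],
            p$read_len >= 20L, p$depth >= 0, p$contig_break_rate >= 0,
            p$long_read_flank >= 1L)
  for (v in c("chry_gene_frac", "novel_carrier_freq", "sex_ratio",
              "base_error_rate", "sv_caller_fn_rate")) {
    if (p[[v]] < 0 || p[[v]] > 1) abort(paste0(v, " must be in [0, 1]"))
  }
  if (p$sv_caller_fp_rate < 0) abort("sv_caller_fp_rate must be >= 0")
  if (!is.list(cohorts) || is.null(names(cohorts)))
    abort("cohorts must be a named list")
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    if (is.null(co$n) || co$n < 1L) abort("each cohort needs n >= 1")
    fr <- co$absence %||% numeric(0)
    if (length(fr) && (is.null(names(fr)) || any(fr < 0) || any(fr > 1)))
      abort("cohort absence frequencies must be named values in [0, 1]")
  }
  structure(p, class = c("sim_params", "list"))
}

#' @rdname sim_params
#' @export
default_cohorts <- function() {
  list(
    case = list(n = 25L, absence = c(
      setNames(rep(0.6, 5), sprintf("g%03d", 1:5)),
      setNames(rep(0.3, 5), sprintf("g%03d", 6:10)))),
    control = list(n = 25L, absence = setNames(rep(0.05, 10),
                                               sprintf("g%03d", 1:10)))
  )
}

# non-overlapping gene placements on one chromosome; min_gap keeps room for
# the +/-50 bp excisions and insertion loci
.place_gene_intervals <- function(m, chrom_len, lens, min_gap = 200L) {
  if (m == 0L) return(tibble(start = integer(), end = integer()))
  need <- sum(lens) + (m + 1L) * min_gap
  if (need > chrom_len)
    abort(sprintf(
      "sizing error: %d genes (total %d bp + gaps) do not fit in %d bp",
      m, sum(lens), chrom_len))
  free <- chrom_len - need
  extra <- if (free > 0) as.vector(stats::rmultinom(1L, free, rep(1, m + 1L)))
           else rep(0L, m + 1L)
  gaps <- min_gap + extra
  starts <- cumsum(gaps[seq_len(m)]) + c(0L, cumsum(lens[-m]))
  tibble(start = as.integer(starts), end = as.integer(starts + lens))
}

# CDS exon structure within a gene span of length L (0-based, span-relative);
# first exon starts at 0 and last ends at L
.make_exons <- function(L, k_range) {
  k <- if (k_range[1] == k_range[2]) k_range[1] else
    sample(seq(k_range[1], k_range[2]), 1L)
  while (k > 1L && L < k * 60L + (k - 1L) * 40L) k <- k - 1L
  if (k == 1L) return(tibble(ex_start = 0L, ex_end = as.integer(L)))
  introns <- sample(20:40, k - 1L, replace = TRUE)
  cds_total <- L - sum(introns)
  parts <- 50L + as.vector(stats::rmultinom(1L, cds_total - k * 50L, rep(1, k)))
  starts <- cumsum(c(0L, parts[-k] + introns))
  tibble(ex_start = as.integer(starts), ex_end = as.integer(starts + parts))
}

#' Simulate the reference genome and its gene models
#'
#' Chromosomes are uniform random A/C/G/T; genes are placed without overlap,
#' chrY genes receive the highest gene indices so that the default cohort
#' absence maps (g001...) always name autosomal genes.
#'
#' @param params a [sim_params()] object.
#' @return `list(genome, genes)`: a named character vector of chromosome
#'   sequences and a gene-model tibble (one row per CDS exon; columns
#'   `gene_id`, `transcript`, `seqnames`, `start`, `end`, `strand`, `novel`;
#'   0-based half-open coordinates).
#' @export
simulate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    nc <- params$n_chromosomes
    chroms <- if (nc == 1L) "chrY" else c(paste0("chr", seq_len(nc - 1L)), "chrY")
    genome <- setNames(
      vapply(chroms, function(x) random_dna(params$chrom_len), character(1)),
      chroms)
    n <- params$n_ref_genes
    autos <- setdiff(chroms, "chrY")
    n_y <- if (length(autos)) as.integer(round(params$chry_gene_frac * n)) else n
    n_auto <- n - n_y
    counts <- integer(0)
    if (length(autos)) {
      counts <- setNames(rep(n_auto %/% length(autos), length(autos)), autos)
      if (n_auto %% length(autos) > 0)
        counts[seq_len(n_auto %% length(autos))] <-
          counts[seq_len(n_auto %% length(autos))] + 1L
    }
    counts <- c(counts, chrY = n_y)
    gid <- 0L
    rows <- list()
    for (ch in names(counts)) {
      m <- counts[[ch]]
      if (m == 0L) next
      lens <- sample(seq(params$gene_len[1], params$gene_len[2]), m,
                     replace = TRUE)
      spans <- .place_gene_intervals(m, params$chrom_len, lens)
      for (i in seq_len(m)) {
        gid <- gid + 1L
        ex <- .make_exons(lens[i], params$cds_exons_per_gene)
        rows[[length(rows) + 1L]] <- tibble(
          gene_id = sprintf("g%03d", gid), transcript = "t1",
          seqnames = ch, start = spans$start[i] + ex$ex_start,
          end = spans$start[i] + ex$ex_end,
          strand = sample(c("+", "-"), 1L), novel = FALSE)
      }
    }
    genes <- if (length(rows)) bind_rows(rows) else
      tibble(gene_id = character(), transcript = character(),
             seqnames = character(), start = integer(), end = integer(),
             strand = character(), novel = logical())
    list(genome = genome, genes = genes)
  })
}

# gene span (min CDS start, max CDS end) per gene
gene_spans <- function(genes) {
  genes |>
    group_by(.data$gene_id, .data$seqnames) |>
    summarise(start = min(.data$start), end = max(.data$end),
              novel = .data$novel[1], .groups = "drop")
}

#' Simulate a population of individual genomes with planted PAVs
#'
#' Each sample deletes each gene listed in its cohort's absence-frequency map
#' independently at that frequency (exact excision of the gene span +/- 50
#' bp), and carries each novel-gene cassette (inserted at a fixed intergenic
#' autosomal locus shared by all carriers) with probability
#' `novel_carrier_freq`. Females carry no chrY sequence. Machine-readable
#' truth is recorded for presence/absence, novel loci, and the implied
#' DEL/INS structural variants.
#'
#' @param ref result of [simulate_reference()].
#' @param params a [sim_params()] object.
#' @return A `pav_population`: list with `individuals` (named list; each has
#'   `sample_id`, `cohort`, `sex`, `seqs`, `segments`, `deleted`, `carried`),
#'   `meta` (tibble sample/cohort/sex), `truth` (list of `pav_truth`,
#'   `novel_gene_loci`, `sv_truth` tibbles), `novel_genes` (gene-model
#'   tibble on cassette hosts), and `cassettes` (named cassette sequences).
#' @export
simulate_population <- function(ref, params) {
  stopifnot(inherits(params, "sim_params"))
  genes <- ref$genes
  spans <- gene_spans(genes)
  known <- spans$gene_id
  for (nm in names(params$cohorts)) {
    bad <- setdiff(names(params$cohorts[[nm]]$absence %||% numeric(0)), known)
    if (length(bad))
      abort(paste0("unknown gene id in cohort '", nm, "' absence frequencies: ",
                   paste(bad, collapse = ", ")))
  }
  chroms <- names(ref$genome)
  autos <- setdiff(chroms, "chrY")

  pop_level <- withr::with_seed(params$seed + 1L, {
    # novel genes as cassettes: 50 bp pad + gene + 50 bp pad
    novel_rows <- list(); cassettes <- character(0); loci <- list()
    occupied <- spans |> mutate(start = .data$start - 80L, end = .data$end + 80L)
    for (j in seq_len(params$n_novel_genes)) {
      id <- sprintf("nv%d", j)
      host <- paste0("nrs_", id)
      L <- sample(seq(params$gene_len[1], params$gene_len[2]), 1L)
      ex <- .make_exons(L, params$cds_exons_per_gene)
      cassettes[[host]] <- random_dna(L + 100L)
      novel_rows[[j]] <- tibble(
        gene_id = id, transcript = "t1", seqnames = host,
        start = 50L + ex$ex_start, end = 50L + ex$ex_end,
        strand = "+", novel = TRUE)
      # fixed intergenic locus on an autosome (or chrY if no autosomes)
      ch <- if (length(autos)) autos[(j - 1L) %% length(autos) + 1L] else "chrY"
      occ <- occupied |> filter(.data$seqnames == ch)
      occ_ir <- iranges0(occ$start, occ$end)
      # loci stay at least a long-read flank away from the chromosome ends
      # so spanning contigs always carry full anchor flanks
      edge <- params$long_read_flank + 1000L
      free <- IRanges::setdiff(
        IRanges::IRanges(edge, params$chrom_len - edge),
        IRanges::reduce(occ_ir))
      free <- free[IRanges::width(free) >= 160L]
      if (length(free) == 0L)
        abort("sizing error: no intergenic space left for novel-gene loci")
      g <- free[sample.int(length(free), 1L)]
      # midpoint of the gap keeps the insertion clear of the +/-50 bp
      # deletion excisions of the flanking genes
      pos <- as.integer((IRanges::start(g) - 1L + IRanges::end(g)) %/% 2L)
      loci[[j]] <- tibble(gene_id = id, host_id = host, chrom = ch,
                          pos = as.integer(pos),
                          cassette_len = nchar(cassettes[[host]]))
      occupied <- bind_rows(occupied,
                            tibble(gene_id = id, seqnames = ch,
                                   start = pos - 80L, end = pos + 80L,
                                   novel = TRUE))
    }
    novel_genes <- if (length(novel_rows)) bind_rows(novel_rows) else
      genes[0, ]
    novel_loci <- if (length(loci)) bind_rows(loci) else
      tibble(gene_id = character(), host_id = character(), chrom = character(),
             pos = integer(), cassette_len = integer())
    # sample roster and sexes
    meta <- list()
    for (nm in names(params$cohorts)) {
      nsamp <- params$cohorts[[nm]]$n
      meta[[nm]] <- tibble(
        sample = sprintf("%s_%02d", nm, seq_len(nsamp)), cohort = nm,
        sex = ifelse(runif(nsamp) < params$sex_ratio, "male", "female"))
    }
    list(novel_genes = novel_genes, novel_loci = novel_loci,
         cassettes = cassettes, meta = bind_rows(meta))
  })
  novel_genes <- pop_level$novel_genes
  novel_loci <- pop_level$novel_loci
  cassettes <- pop_level$cassettes
  meta <- pop_level$meta

  chry_genes <- spans$gene_id[spans$seqnames == "chrY"]
  individuals <- list()
  truth_rows <- list(); sv_rows <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample[i]; cohort <- meta$cohort[i]; sex <- meta$sex[i]
    absence <- params$cohorts[[cohort]]$absence %||% numeric(0)
    draws <- withr::with_seed(sub_seed(params$seed, sid, "genotype"), {
      del <- names(absence)[runif(length(absence)) < absence]
      carried <- novel_loci$gene_id[
        runif(nrow(novel_loci)) < params$novel_carrier_freq]
      list(del = del, carried = carried)
    })
    deleted <- draws$del
    if (sex == "female") deleted <- setdiff(deleted, chry_genes)
    carried <- draws$carried
    ind_chroms <- if (sex == "female") setdiff(chroms, "chrY") else chroms
    seqs <- character(0); seg_rows <- list()
    for (ch in ind_chroms) {
      refseq <- ref$genome[[ch]]
      clen <- nchar(refseq)
      dels <- spans |> filter(.data$gene_id %in% deleted, .data$seqnames == ch)
      edits <- tibble(pos = integer(), end = integer(), kind = character(),
                      id = character())
      if (nrow(dels)) {
        edits <- bind_rows(edits, tibble(
          pos = dels$start - 50L, end = dels$end + 50L, kind = "del",
          id = dels$gene_id))
      }
      ins <- novel_loci |> filter(.data$gene_id %in% carried, .data$chrom == ch)
      if (nrow(ins)) {
        edits <- bind_rows(edits, tibble(pos = ins$pos, end = ins$pos,
                                         kind = "ins", id = ins$gene_id))
      }
      edits <- edits |> arrange(.data$pos)
      pieces <- character(0)
      cur <- 0L; ind_pos <- 0L
      add_seg <- function(target, t_start, len) {
        seg_rows[[length(seg_rows) + 1L]] <<- tibble(
          chrom = ch, ind_start = ind_pos, ind_end = ind_pos + len,
          target = target, t_start = t_start)
        ind_pos <<- ind_pos + len
      }
      for (e in seq_len(nrow(edits))) {
        p <- edits$pos[e]
        if (p > cur) {
          pieces <- c(pieces, substring(refseq, cur + 1L, p))
          add_seg(ch, cur, p - cur)
        }
        if (edits$kind[e] == "del") {
          cur <- edits$end[e]
        } else {
          host <- paste0("nrs_", edits$id[e])
          cass <- cassettes[[host]]
          pieces <- c(pieces, cass)
          add_seg(host, 0L, nchar(cass))
          cur <- p
        }
      }
      if (clen > cur) {
        pieces <- c(pieces, substring(refseq, cur + 1L, clen))
        add_seg(ch, cur, clen - cur)
      }
      seqs[[ch]] <- paste(pieces, collapse = "")
    }
    segments <- if (length(seg_rows)) bind_rows(seg_rows) else
      tibble(chrom = character(), ind_start = integer(), ind_end = integer(),
             target = character(), t_start = integer())
    individuals[[sid]] <- structure(
      list(sample_id = sid, cohort = cohort, sex = sex, seqs = seqs,
           segments = segments, deleted = deleted, carried = carried),
      class = "pav_individual")

    # truth rows
    ref_truth <- tibble(
      sample = sid, gene_id = spans$gene_id,
      present = !(spans$gene_id %in% deleted) &
        !(sex == "female" & spans$gene_id %in% chry_genes),
      reason = dplyr::case_when(
        sex == "female" & spans$gene_id %in% chry_genes ~ "no_chry",
        spans$gene_id %in% deleted ~ "deleted",
        TRUE ~ NA_character_))
    nov_truth <- tibble(
      sample = sid, gene_id = novel_loci$gene_id,
      present = novel_loci$gene_id %in% carried,
      reason = as.character(ifelse(novel_loci$gene_id %in% carried,
                                   NA_character_, "not_carried")))
    truth_rows[[sid]] <- bind_rows(ref_truth, nov_truth)
    dels <- spans |> filter(.data$gene_id %in% deleted)
    svs <- list()
    if (nrow(dels)) {
      svs$del <- tibble(sample = sid, chrom = dels$seqnames,
                        pos = dels$start - 50L, end = dels$end + 50L,
                        type = "DEL", svlen = -(dels$end - dels$start + 100L),
                        genotype = "hom", gene_id = dels$gene_id)
    }
    ins <- novel_loci |> filter(.data$gene_id %in% carried)
    if (nrow(ins)) {
      svs$ins <- tibble(sample = sid, chrom = ins$chrom, pos = ins$pos,
                        end = ins$pos + 1L, type = "INS",
                        svlen = ins$cassette_len, genotype = "hom",
                        gene_id = ins$gene_id)
    }
    if (length(svs)) sv_rows[[sid]] <- bind_rows(svs)
  }
  sv_truth <- if (length(sv_rows)) bind_rows(sv_rows) else
    tibble(sample = character(), chrom = character(), pos = integer(),
           end = integer(), type = character(), svlen = integer(),
           genotype = character(), gene_id = character())
  structure(list(
    individuals = individuals, meta = meta,
    truth = list(pav_truth = bind_rows(truth_rows),
                 novel_gene_loci = novel_loci, sv_truth = sv_truth),
    novel_genes = novel_genes, cassettes = cassettes),
    class = "pav_population")
}

#' Fragment an individual genome into assembly-like contigs
#'
#' Breakpoints are Poisson (`contig_break_rate` per 10 kb); substitution
#' errors at `base_error_rate`. Each contig records its true source interval
#' on the individual genome.
#'
#' @param ind a `pav_individual` from [simulate_population()].
#' @param params a [sim_params()] object.
#' @return Tibble: `contig_id`, `sample`, `chrom`, `src_start`, `src_end`,
#'   `length`, `seq`.
#' @export
simulate_contigs <- function(ind, params) {
  withr::with_seed(sub_seed(params$seed, ind$sample_id, "contigs"), {
    rows <- list()
    for (ch in names(ind$seqs)) {
      s <- ind$seqs[[ch]]
      L <- nchar(s)
      nb <- rpois(1L, L * params$contig_break_rate / 1e4)
      bp <- if (nb > 0L) sort(unique(sample.int(L - 1L, min(nb, L - 1L)))) else integer(0)
      bounds <- c(0L, bp, L)
      for (i in seq_len(length(bounds) - 1L)) {
        frag <- substring(s, bounds[i] + 1L, bounds[i + 1L])
        frag <- mutate_sequence(frag, params$base_error_rate)
        rows[[length(rows) + 1L]] <- tibble(
          contig_id = sprintf("%s_%s_c%03d", ind$sample_id, ch, i),
          sample = ind$sample_id, chrom = ch,
          src_start = bounds[i], src_end = bounds[i + 1L],
          length = bounds[i + 1L] - bounds[i], seq = frag)
      }
    }
    bind_rows(rows)
  })
}

#' Simulate uniform read placement and the resulting depth track
#'
#' Reads of `read_len` are placed uniformly over the individual's actual
#' sequence at rate `depth / read_len` per bp, then lifted through the
#' individual's segment map to reference/pan-genome coordinates; the depth
#' track is the exact pileup of the lifted placements. Deleted regions
#' receive zero depth by construction.
#'
#' @param ind a `pav_individual`.
#' @param params a [sim_params()] object.
#' @return List: `track` (tibble `target`, `start`, `end`, `depth`; 0-based
#'   half-open runs with depth >= 1), `reads` (placements in individual
#'   coordinates), `placements` (read pieces in pan-genome coordinates).
#' @export
simulate_depth <- function(ind, params) {
  withr::with_seed(sub_seed(params$seed, ind$sample_id, "depth"), {
    read_rows <- list()
    for (ch in names(ind$seqs)) {
      L <- nchar(ind$seqs[[ch]])
      if (L < params$read_len || params$depth <= 0) next
      n <- rpois(1L, L * params$depth / params$read_len)
      if (n == 0L) next
      starts <- sample.int(L - params$read_len + 1L, n, replace = TRUE) - 1L
      read_rows[[ch]] <- tibble(
        read_id = sprintf("%s_%s_r%06d", ind$sample_id, ch, seq_len(n)),
        chrom = ch, start = starts, end = starts + params$read_len)
    }
    reads <- if (length(read_rows)) bind_rows(read_rows) else
      tibble(read_id = character(), chrom = character(), start = integer(),
             end = integer())
    placements <- lift_to_targets(reads, ind$segments)
    track <- pileup_track(placements)
    list(track = track, reads = reads, placements = placements)
  })
}

# lift intervals in individual coordinates to target (reference/cassette)
# coordinates through the segment map; intervals spanning segment boundaries
# are split into pieces
lift_to_targets <- function(reads, segments) {
  empty <- tibble(read_id = character(), target = character(),
                  t_start = integer(), t_end = integer())
  if (nrow(reads) == 0L || nrow(segments) == 0L) return(empty)
  out <- list()
  for (ch in unique(reads$chrom)) {
    r <- reads[reads$chrom == ch, , drop = FALSE]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) next
    fo <- IRanges::findOverlaps(iranges0(r$start, r$end),
                                iranges0(seg$ind_start, seg$ind_end))
    qi <- S4Vectors::queryHits(fo); si <- S4Vectors::subjectHits(fo)
    ps <- pmax(r$start[qi], seg$ind_start[si])
    pe <- pmin(r$end[qi], seg$ind_end[si])
    out[[ch]] <- tibble(
      read_id = r$read_id[qi], target = seg$target[si],
      t_start = seg$t_start[si] + (ps - seg$ind_start[si]),
      t_end = seg$t_start[si] + (pe - seg$ind_start[si]))
  }
  if (length(out)) bind_rows(out) else empty
}

# exact pileup of placements -> run-length depth track (depth >= 1 runs)
pileup_track <- function(placements) {
  empty <- tibble(target = character(), start = integer(), end = integer(),
                  depth = integer())
  if (nrow(placements) == 0L) return(empty)
  out <- list()
  for (tg in unique(placements$target)) {
    p <- placements[placements$target == tg, , drop = FALSE]
    cov <- IRanges::coverage(iranges0(p$t_start, p$t_end))
    rl <- S4Vectors::runLength(cov); rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl); starts <- ends - rl
    keep <- rv > 0
    if (!any(keep)) next
    out[[tg]] <- tibble(target = tg, start = as.integer(starts[keep]),
                        end = as.integer(ends[keep]),
                        depth = as.integer(rv[keep]))
  }
  if (length(out)) bind_rows(out) else empty
}

#' Extract read sequences from an individual genome
#'
#' @param ind a `pav_individual`.
#' @param reads tibble of read placements in individual coordinates
#'   (`read_id`, `chrom`, `start`, `end`), e.g. from [simulate_depth()].
#' @return Named character vector of read sequences.
#' @export
read_sequences <- function(ind, reads) {
  out <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    idx <- which(reads$chrom == ch)
    out[idx] <- substring(ind$seqs[[ch]], reads$start[idx] + 1L,
                          reads$end[idx])
  }
  setNames(out, reads$read_id)
}

#' Simulate long-read contigs spanning novel insertions
#'
#' For every novel-gene cassette an individual carries, one contig is emitted
#' covering the cassette plus `long_read_flank` bp of the individual's true
#' flanking sequence on each side (clipped at chromosome ends).
#'
#' @param ind a `pav_individual`.
#' @param params a [sim_params()] object.
#' @return Tibble: `contig_id`, `sample`, `gene_id`, `chrom`, `start`, `end`
#'   (individual coordinates), `seq`.
#' @export
simulate_long_reads <- function(ind, params) {
  seg <- ind$segments[grepl("^nrs_", ind$segments$target), , drop = FALSE]
  if (nrow(seg) == 0L) {
    return(tibble(contig_id = character(), sample = character(),
                  gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), seq = character()))
  }
  fl <- params$long_read_flank
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    ch <- seg$chrom[i]
    L <- nchar(ind$seqs[[ch]])
    s <- max(0L, seg$ind_start[i] - fl)
    e <- min(L, seg$ind_end[i] + fl)
    gid <- sub("^nrs_", "", seg$target[i])
    tibble(contig_id = sprintf("%s_lr_%s", ind$sample_id, gid),
           sample = ind$sample_id, gene_id = gid, chrom = ch,
           start = s, end = e,
           seq = substring(ind$seqs[[ch]], s + 1L, e))
  })
  bind_rows(rows)
}

#' Simulate noisy multi-caller SV callsets from the truth set
#'
#' Each caller reports each true SV with probability `1 - sv_caller_fn_rate`,
#' with breakpoints jittered by rounded Gaussian noise of sd
#' `sv_caller_jitter_sd`, plus Poisson false positives at
#' `sv_caller_fp_rate` per true SV. Types and genotypes are preserved.
#'
#' @param sv_truth truth tibble from [simulate_population()].
#' @param params a [sim_params()] object.
#' @param n_callers number of callers to simulate.
#' @param callers optional caller names.
#' @return Tibble of SV calls: `caller`, `sample`, `chrom`, `pos`, `end`,
#'   `type`, `svlen`, `strands`, `genotype`, `id`.
#' @export
simulate_sv_callsets <- function(sv_truth, params, n_callers = 3L,
                                 callers = NULL) {
  if (is.null(callers)) callers <- paste0("caller", seq_len(n_callers))
  truth <- sv_truth |> arrange(.data$sample, .data$chrom, .data$pos)
  chroms <- sort(unique(truth$chrom))
  if (length(chroms) == 0L) chroms <- "chr1"
  withr::with_seed(params$seed + 3L, {
    rows <- list()
    for (cl in callers) {
      for (sid in unique(truth$sample)) {
        tr <- truth[truth$sample == sid, , drop = FALSE]
        keep <- runif(nrow(tr)) >= params$sv_caller_fn_rate
        tp <- tr[keep, , drop = FALSE]
        if (nrow(tp)) {
          jp <- as.integer(round(rnorm(nrow(tp), 0, params$sv_caller_jitter_sd)))
          je <- as.integer(round(rnorm(nrow(tp), 0, params$sv_caller_jitter_sd)))
          pos <- pmax(0L, tp$pos + jp)
          end <- ifelse(tp$type == "INS", pos + 1L,
                        pmax(pos + 1L, tp$end + je))
          rows[[length(rows) + 1L]] <- tibble(
            caller = cl, sample = sid, chrom = tp$chrom,
            pos = as.integer(pos), end = as.integer(end), type = tp$type,
            svlen = tp$svlen, strands = "+-", genotype = tp$genotype,
            id = sprintf("%s_%s_tp%03d", cl, sid, seq_len(nrow(tp))))
        }
        nfp <- rpois(1L, params$sv_caller_fp_rate * nrow(tr))
        if (nfp > 0L) {
          ty <- sample(c("DEL", "INS"), nfp, replace = TRUE)
          ln <- sample(50:5000, nfp, replace = TRUE)
          p0 <- sample.int(params$chrom_len - 6000L, nfp, replace = TRUE)
          rows[[length(rows) + 1L]] <- tibble(
            caller = cl, sample = sid,
            chrom = sample(chroms, nfp, replace = TRUE),
            pos = as.integer(p0),
            end = as.integer(ifelse(ty == "INS", p0 + 1L, p0 + ln)),
            type = ty, svlen = as.integer(ifelse(ty == "DEL", -ln, ln)),
            strands = "+-",
            genotype = sample(c("het", "hom"), nfp, replace = TRUE),
            id = sprintf("%s_%s_fp%03d", cl, sid, seq_len(nfp)))
        }
      }
    }
    if (length(rows)) bind_rows(rows) else
      tibble(caller = character(), sample = character(), chrom = character(),
             pos = integer(), end = integer(), type = character(),
             svlen = integer(), strands = character(), genotype = character(),
             id = character())
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper: reference, population, per-sample contigs, depth,
#' long-read contigs, and SV callsets, optionally written to `dir` in the
#' standard plain-text formats (FASTA, GFF3, samtools-depth TSV, caller TSV,
#' truth/metadata TSV).
#'
#' @param params a [sim_params()] object.
#' @param dir optional output directory.
#' @param what which per-sample products to generate.
#' @return List with `params`, `ref`, `pop`, and the requested products.
#' @export
simulate_study <- function(params = sim_params(), dir = NULL,
                           what = c("contigs", "depth", "long_reads", "svs")) {
  ref <- simulate_reference(params)
  pop <- simulate_population(ref, params)
  out <- list(params = params, ref = ref, pop = pop)
  if ("contigs" %in% what)
    out$contigs <- lapply(pop$individuals, simulate_contigs, params = params)
  if ("depth" %in% what)
    out$depth <- lapply(pop$individuals, simulate_depth, params = params)
  if ("long_reads" %in% what)
    out$long_reads <- bind_rows(
      lapply(pop$individuals, simulate_long_reads, params = params))
  if ("svs" %in% what)
    out$sv_calls <- simulate_sv_callsets(pop$truth$sv_truth, params)
  if (!is.null(dir)) write_study(out, dir)
  out
}
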