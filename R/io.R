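# Plain-text format adapters. All conversions between the package's 0-based
# half-open coordinates and 1-based file formats (GFF3, depth TSV, VCF-like
# SV tables) happen here and nowhere else.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; the reader tolerates line wrapping and
#' lowercase and returns uppercase sequences.
#'
#' @param path file path.
#' @return `read_fasta`: named uppercase character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_dna(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read / write gene models as GFF3 CDS features
#'
#' One `CDS` feature per exon, 1-based closed intervals per the GFF3
#' standard; attributes carry `gene_id`, `transcript_id` and `novel`.
#'
#' @param genes gene-model tibble (`gene_id`, `transcript`, `seqnames`,
#'   `start`, `end`, `strand`, `novel`; 0-based half-open).
#' @param path file path.
#' @return `read_gff3`: a gene-model tibble.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  if (nrow(genes)) {
    attrs <- sprintf("ID=%s.%s.cds%d;gene_id=%s;transcript_id=%s;novel=%s",
                     genes$gene_id, genes$transcript,
                     stats::ave(seq_len(nrow(genes)),
                                paste(genes$gene_id, genes$transcript),
                                FUN = seq_along),
                     genes$gene_id, genes$transcript,
                     ifelse(genes$novel, "true", "false"))
    lines <- c(lines, sprintf("%s\tpavpan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              genes$seqnames, genes$start + 1L, genes$end,
                              genes$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(gene_id = character(), transcript = character(),
                  seqnames = character(), start = integer(), end = integer(),
                  strand = character(), novel = logical()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 9L)
      abort(sprintf("GFF3 parse error at line %d: expected 9 columns", i))
    if (p[3] != "CDS") return(NULL)
    s <- suppressWarnings(as.integer(p[4])); e <- suppressWarnings(as.integer(p[5]))
    if (is.na(s) || is.na(e))
      abort(sprintf("GFF3 parse error at line %d: non-numeric coordinate", i))
    attr_get <- function(key) {
      m <- regmatches(p[9], regexpr(paste0("(^|;)", key, "=[^;]*"), p[9]))
      if (length(m) == 0L) NA_character_ else sub(paste0(".*", key, "="), "", m)
    }
    tibble(gene_id = attr_get("gene_id"), transcript = attr_get("transcript_id"),
           seqnames = p[1], start = s - 1L, end = e, strand = p[7],
           novel = identical(attr_get("novel"), "true"))
  })
  out <- bind_rows(rows)
  out$transcript[is.na(out$transcript)] <- "t1"
  out
}

#' Read / write per-base depth (samtools-depth dialect)
#'
#' Three tab-separated columns `target`, 1-based position, depth. The reader
#' retains positions with depth at or above `depth_presence_min`, merges
#' adjacent equal-depth positions into runs, and converts to 0-based
#' half-open intervals.
#'
#' @param path file path.
#' @param t a [pav_thresholds()] object.
#' @return `read_depth_tsv`: depth-track tibble (`target`, `start`, `end`,
#'   `depth`).
#' @export
read_depth_tsv <- function(path, t = pav_thresholds()) {
  empty <- tibble(target = character(), start = integer(), end = integer(),
                  depth = integer())
  if (file.size(path) == 0L) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("target", "pos", "depth"),
              colClasses = list(character = 1L, integer = 2:3))
  dt <- dt[dt$depth >= t$depth_presence_min]
  if (nrow(dt) == 0L) return(empty)
  setorder(dt, target, pos)
  run <- cumsum(c(TRUE, dt$target[-1L] != dt$target[-nrow(dt)] |
                    diff(dt$pos) != 1L | diff(dt$depth) != 0L))
  dt[, chain := run]
  runs <- dt[, .(target = target[1L], start = min(pos) - 1L, end = max(pos),
                 depth = depth[1L]), by = chain]
  as_tibble(runs[, -"chain"])
}

#' @rdname read_depth_tsv
#' @param track depth-track tibble.
#' @export
write_depth_tsv <- function(track, path) {
  if (nrow(track) == 0L) { file.create(path); return(invisible(path)) }
  n <- track$end - track$start
  dt <- data.table(target = rep(track$target, n),
                   pos = unlist(lapply(seq_len(nrow(track)), function(i)
                     seq.int(track$start[i] + 1L, track$end[i]))),
                   depth = rep(track$depth, n))
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write SV calls as a VCF-like TSV
#'
#' Columns `CHROM POS ID TYPE END SVLEN STRANDS SAMPLE GENOTYPE CALLER`,
#' with 1-based `POS` as in VCF; `END` equals the 0-based half-open end.
#'
#' @param calls SV-call tibble (as from [simulate_sv_callsets()]).
#' @param path file path.
#' @return `read_sv_tsv`: SV-call tibble.
#' @export
write_sv_tsv <- function(calls, path) {
  dt <- data.table(CHROM = calls$chrom, POS = calls$pos + 1L, ID = calls$id,
                   TYPE = calls$type, END = calls$end, SVLEN = calls$svlen,
                   STRANDS = calls$strands, SAMPLE = calls$sample,
                   GENOTYPE = calls$genotype, CALLER = calls$caller)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sv_tsv
#' @export
read_sv_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  tibble(caller = as.character(dt$CALLER), sample = as.character(dt$SAMPLE),
         chrom = as.character(dt$CHROM), pos = as.integer(dt$POS) - 1L,
         end = as.integer(dt$END), type = as.character(dt$TYPE),
         svlen = as.integer(dt$SVLEN), strands = as.character(dt$STRANDS),
         genotype = as.character(dt$GENOTYPE), id = as.character(dt$ID))
}

#' Write all products of a simulated study to a directory
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(study$ref$genome, file.path(dir, "reference.fa"))
  write_gff3(study$ref$genes, file.path(dir, "genes.gff3"))
  pop <- study$pop
  write_gff3(pop$novel_genes, file.path(dir, "novel_genes.gff3"))
  if (length(pop$cassettes))
    write_fasta(pop$cassettes, file.path(dir, "novel_cassettes.fa"))
  fwrite(as.data.table(pop$meta), file.path(dir, "meta.tsv"), sep = "\t")
  fwrite(as.data.table(pop$truth$pav_truth),
         file.path(dir, "truth_pav.tsv"), sep = "\t")
  fwrite(as.data.table(pop$truth$novel_gene_loci),
         file.path(dir, "truth_novel_loci.tsv"), sep = "\t")
  fwrite(as.data.table(pop$truth$sv_truth),
         file.path(dir, "truth_sv.tsv"), sep = "\t")
  if (!is.null(study$contigs)) {
    cdir <- file.path(dir, "contigs")
    dir.create(cdir, showWarnings = FALSE)
    for (sid in names(study$contigs)) {
      ct <- study$contigs[[sid]]
      write_fasta(setNames(ct$seq, ct$contig_id),
                  file.path(cdir, paste0(sid, ".fa")))
    }
  }
  if (!is.null(study$depth)) {
    ddir <- file.path(dir, "depth")
    dir.create(ddir, showWarnings = FALSE)
    for (sid in names(study$depth))
      write_depth_tsv(study$depth[[sid]]$track,
                      file.path(ddir, paste0(sid, ".tsv")))
  }
  if (!is.null(study$long_reads) && nrow(study$long_reads))
    write_fasta(setNames(study$long_reads$seq, study$long_reads$contig_id),
                file.path(dir, "long_reads.fa"))
  if (!is.null(study$sv_calls))
    write_sv_tsv(study$sv_calls, file.path(dir, "sv_calls.tsv"))
  invisible(dir)
}
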