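# End-to-end analysis of a (simulated or adapted) study: contig
# classification and pan-genome assembly, depth-based PAV matrix, per-sample
# mapping rates against reference and pan-genome, anchor placement of novel
# genes, and multi-caller SV merging with DEL-derived PAV.

#' Run the full PAV analysis over a study
#'
#' Glues the pipeline stages together over the products of
#' [simulate_study()] (or equivalently structured real-data adapters):
#' filters and classifies every sample's contigs against the reference,
#' extracts and de-duplicates non-reference sequence, builds the pan-genome,
#' computes the depth-based PAV matrix over reference plus novel genes,
#' measures per-sample read mapping rates against reference and pan-genome,
#' places novel genes via long-read anchors, and merges the per-caller SV
#' callsets per sample.
#'
#' @param study result of [simulate_study()].
#' @param t a [pav_thresholds()] object.
#' @param reads_per_sample number of reads per sample used for the
#'   mapping-rate comparison (evenly strided over the sample's reads).
#' @return List: `classes` (per-contig classification), `nonref` (kept
#'   non-redundant non-reference sequences), `pan` (pangenome), `pav`
#'   (`pav_matrix` over all samples), `mapping` (tibble sample/reference/
#'   pangenome rates), `placements` (novel-gene placements), `merged_svs`
#'   (named list per sample), `del_pav` (named list per sample).
#' @export
analyze_study <- function(study, t = pav_thresholds(),
                          reads_per_sample = 800L) {
  ref <- study$ref
  pop <- study$pop
  ref_idx <- seed_index(ref$genome)

  # contigs -> classes -> non-reference catalog -> pan-genome
  classes <- list(); nonref <- list(); blocks <- list()
  for (sid in names(study$contigs)) {
    ct <- filter_contigs(study$contigs[[sid]], t)
    b <- align(setNames(ct$seq, ct$contig_id), ref_idx)
    blocks[[sid]] <- b
    classes[[sid]] <- classify_contigs(ct, b, t) |>
      mutate(sample = sid, .before = 1L)
    nr <- extract_nonref(ct, b, t)
    if (nrow(nr)) nonref[[sid]] <- nr |> mutate(sample = sid)
  }
  classes <- bind_rows(classes)
  nonref_all <- if (length(nonref)) bind_rows(nonref) else
    extract_nonref(study$contigs[[1]][0, ], blocks[[1]][0, ], t)
  kept <- remove_redundancy(nonref_all, t)
  pan <- build_pangenome(ref, kept)
  pan_idx <- seed_index(pan$genome)

  # depth-based PAV over reference + novel genes
  tracks <- lapply(study$depth, `[[`, "track")
  genes_all <- bind_rows(ref$genes, pop$novel_genes)
  pav <- build_pav_matrix(genes_all, tracks, pop$meta, t)

  # per-sample mapping rates (evenly strided read subsample)
  mapping <- lapply(names(pop$individuals), function(sid) {
    rd <- study$depth[[sid]]$reads
    n <- nrow(rd)
    sel <- unique(as.integer(round(seq(1L, n,
                                       length.out = min(reads_per_sample, n)))))
    rs <- read_sequences(pop$individuals[[sid]], rd[sel, , drop = FALSE])
    tibble(sample = sid,
           reference = mapping_rate(rs, ref_idx, t),
           pangenome = mapping_rate(rs, pan_idx, t))
  })
  mapping <- bind_rows(mapping)

  # anchor placement of novel genes with long-read support
  placements <- NULL
  if (!is.null(study$long_reads) && nrow(study$long_reads)) {
    cass <- pop$cassettes
    names(cass) <- sub("^nrs_", "", names(cass))
    gene_ids <- intersect(names(cass), unique(study$long_reads$gene_id))
    placements <- place_genes(
      cass[gene_ids],
      study$long_reads[, c("contig_id", "seq")], ref_idx, t)
  }

  # per-sample SV merging and DEL-derived PAV
  merged <- list(); del_pav <- list()
  if (!is.null(study$sv_calls) && nrow(study$sv_calls)) {
    lens <- setNames(nchar(ref$genome), names(ref$genome))
    for (sid in unique(study$sv_calls$sample)) {
      m <- merge_svs(study$sv_calls[study$sv_calls$sample == sid, ], t)
      merged[[sid]] <- m
      del_pav[[sid]] <- del_sv_pav(m, ref$genes, lens, t)
    }
  }

  list(classes = classes, nonref = kept, pan = pan, pav = pav,
       mapping = mapping, placements = placements, merged_svs = merged,
       del_pav = del_pav)
}
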