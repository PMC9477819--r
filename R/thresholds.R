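#' Numeric thresholds used across the pipeline
#'
#' Every numeric rule of the analysis lives here, declared once and threaded
#' explicitly to each operation: the contig length filter (> 500 bp kept), the
#' 95/95 reference-classification rule, the > 80% CDS-coverage presence rule,
#' the < 50% CDS-coverage split between highly and lowly absent genes, the
#' anchor-placement rules (3000 bp anchors, alignments accepted when longer
#' than 1500 bp at identity above 80%, locus accepted when shorter than twice
#' the gene length), the multi-caller SV merge parameters (max breakpoint
#' distance 1000 bp, at least 2 supporting callers, type and strand agreement,
#' minimum size 30 bp), the insertion repeat-fraction filter (more than half
#' repetitive dropped), and the statistical flags (FDR < 0.05, OR > 1.5).
#'
#' Comparison semantics follow the rules' wording literally: presence is
#' strict (`coverage > presence_cds_coverage`), reference classification is
#' inclusive (`identity >= ref_identity` and `coverage >= ref_query_coverage`),
#' anchor acceptance and the span rule are strict.
#'
#' @param ... named overrides of individual thresholds.
#' @return A `pav_thresholds` object (validated named list).
#' @examples
#' t <- pav_thresholds()
#' t$presence_cds_coverage
#' pav_thresholds(presence_cds_coverage = 0.9)$presence_cds_coverage
#' @export
pav_thresholds <- function(...) {
  t <- .threshold_defaults()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(t))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      abort(paste0("unknown threshold key(s): ",
                   paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")))
    }
    t[names(over)] <- over
  }
  validate_thresholds(t)
}

.threshold_defaults <- function() {
  list(
    min_contig_len        = 500L,
    ref_identity          = 0.95,
    ref_query_coverage    = 0.95,
    presence_cds_coverage = 0.80,
    hag_cds_coverage      = 0.50,
    anchor_flank_len      = 3000L,
    anchor_min_aln_len    = 1500L,
    anchor_min_identity   = 0.80,
    placement_span_factor = 2.0,
    gene_contig_min_identity = 0.80,
    sv_merge_max_dist     = 1000L,
    sv_merge_min_support  = 2L,
    sv_merge_type_match   = TRUE,
    sv_merge_strand_match = TRUE,
    sv_min_size           = 30L,
    ins_max_repeat_fraction = 0.5,
    fdr_alpha             = 0.05,
    or_flag_threshold     = 1.5,
    redundancy_identity   = 0.95,
    redundancy_coverage   = 0.95,
    depth_presence_min    = 1L
  )
}

.threshold_fields <- list(
  fraction = c("ref_identity", "ref_query_coverage", "presence_cds_coverage",
               "hag_cds_coverage", "anchor_min_identity",
               "gene_contig_min_identity", "ins_max_repeat_fraction",
               "fdr_alpha", "redundancy_identity", "redundancy_coverage"),
  pos_int  = c("min_contig_len", "anchor_flank_len", "anchor_min_aln_len",
               "sv_merge_max_dist", "sv_min_size", "depth_presence_min",
               "sv_merge_min_support"),
  pos_num  = c("placement_span_factor", "or_flag_threshold"),
  bool     = c("sv_merge_type_match", "sv_merge_strand_match")
)

validate_thresholds <- function(t) {
  for (k in .threshold_fields$fraction) {
    v <- t[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      abort(paste0("invalid threshold '", k, "': must be a fraction in [0, 1]"))
    t[[k]] <- as.numeric(v)
  }
  for (k in .threshold_fields$pos_int) {
    v <- t[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      abort(paste0("invalid threshold '", k, "': must be a positive integer"))
    t[[k]] <- as.integer(v)
  }
  for (k in .threshold_fields$pos_num) {
    v <- t[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      abort(paste0("invalid threshold '", k, "': must be positive"))
    t[[k]] <- as.numeric(v)
  }
  for (k in .threshold_fields$bool) {
    v <- t[[k]]
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      abort(paste0("invalid threshold '", k, "': must be TRUE or FALSE"))
  }
  structure(t[names(.threshold_defaults())], class = c("pav_thresholds", "list"))
}

#' Load thresholds from a YAML key/value file
#'
#' Missing file path returns all defaults. The file is a flat `key: value`
#' document; unknown keys are rejected and every value is validated.
#'
#' @param path path to a YAML file, or `NULL` for defaults.
#' @return A `pav_thresholds` object.
#' @seealso [write_thresholds()]
#' @export
load_thresholds <- function(path = NULL) {
  if (is.null(path)) return(pav_thresholds())
  if (!file.exists(path)) abort(paste0("thresholds file not found: ", path))
  vals <- tryCatch(yaml::read_yaml(path), error = function(e)
    abort(paste0("malformed thresholds file '", path, "': ", conditionMessage(e))))
  if (is.null(vals)) return(pav_thresholds())
  if (!is.list(vals) || is.null(names(vals)))
    abort("thresholds file must be a flat key: value mapping")
  do.call(pav_thresholds, vals)
}

#' Write thresholds to a YAML file
#'
#' `load_thresholds(write_thresholds(t, path))` is the identity on any valid
#' thresholds object.
#'
#' @param t a `pav_thresholds` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(t, path) {
  stopifnot(inherits(t, "pav_thresholds"))
  yaml::write_yaml(unclass(t), path)
  invisible(path)
}

#' @export
print.pav_thresholds <- function(x, ...) {
  cat("<pav_thresholds>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}
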