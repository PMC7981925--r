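#' Build a gene-by-sample SV breakpoint matrix
#'
#' For each gene and sample, the unweighted entry is 1 if at least one
#' breakpoint of any of the sample's SVs falls in the chosen region window of
#' the gene (both breakpoints of every SV are tested independently), 0
#' otherwise. With \code{weighted = TRUE} (flank window only) the entry is
#' the maximum distance weight over the sample's in-window breakpoints, in
#' [0, 1].
#'
#' @param genes Gene table.
#' @param svs SV table (internal 0-based form).
#' @param window One of \code{\link{region_windows}}.
#' @param config \code{\link{sv_config}}.
#' @param samples Cohort sample ids forming the matrix columns; samples with
#'   no SVs get all-zero columns. Default: samples present in \code{svs}.
#' @param weighted Apply the relative distance metric (flank window only).
#' @param sv_type Optional filter on the sv_type column.
#' @return Numeric gene-by-sample matrix with attributes \code{window} and
#'   \code{weighted}.
#' @export
build_bp_matrix <- function(genes, svs, window = "flank1mb",
                            config = sv_config(), samples = NULL,
                            weighted = config$use_distance_metric,
                            sv_type = NULL) {
  window <- match.arg(window, region_windows)
  genes <- validate_genes(genes)
  if (nrow(genes) == 0) stop("empty gene set")
  if (weighted && window != "flank1mb")
    stop("distance weighting applies only to the flank1mb window")
  if (!is.null(sv_type))
    svs <- svs[!is.na(svs$sv_type) & svs$sv_type %in% sv_type, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(svs$sample_id))
  if (length(samples) == 0) stop("empty sample cohort")
  if (anyDuplicated(samples)) stop("duplicate sample ids in cohort")

  m <- matrix(0, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  bps <- sv_breakpoints(svs)
  bps <- bps[bps$sample_id %in% samples, , drop = FALSE]
  if (nrow(bps) > 0) {
    win <- window_interval(genes, window, config)
    hits <- GenomicRanges::findOverlaps(.gr_points(bps$chrom, bps$pos),
                                        .gr_intervals(win))
    bi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    si <- match(bps$sample_id[bi], samples)
    if (weighted) {
      d <- bp_gene_distance(bps$pos[bi], genes$start[gi], genes$end[gi])
      w <- breakpoint_weight(d, config$window_flank)
      if (length(w) > 0) {
        key <- (gi - 1) * length(samples) + si
        agg <- tapply(w, key, max)
        idx <- as.integer(names(agg))
        m[cbind((idx - 1) %/% length(samples) + 1,
                (idx - 1) %% length(samples) + 1)] <- as.numeric(agg)
      }
    } else {
      m[cbind(gi, si)] <- 1
    }
  }
  attr(m, "window") <- window
  attr(m, "weighted") <- weighted
  m
}

#' Gene-to-SV associations underlying the breakpoint matrix
#'
#' For each (gene, sample) with at least one in-window breakpoint, reports
#' exactly one association, using the breakpoint closest to the strand-aware
#' gene start (TSS); ties broken by lower genomic coordinate, then
#' lexicographic sv_id. The mate breakpoint is flagged distal when it lies on
#' another chromosome or outside the gene's flank window.
#'
#' @inheritParams build_bp_matrix
#' @return Data frame with gene_id, sample_id, sv_id, near_bp (mate index of
#'   the in-window breakpoint), bp_chrom, bp_pos, distance_to_gene (0 inside
#'   the body), tss_distance, mate_chrom, mate_pos, mate_is_distal.
#' @export
gene_sv_associations <- function(genes, svs, window = "flank1mb",
                                 config = sv_config(), samples = NULL,
                                 sv_type = NULL) {
  window <- match.arg(window, region_windows)
  genes <- validate_genes(genes)
  if (nrow(genes) == 0) stop("empty gene set")
  if (!is.null(sv_type))
    svs <- svs[!is.na(svs$sv_type) & svs$sv_type %in% sv_type, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(svs$sample_id))
  bps <- sv_breakpoints(svs)
  bps <- bps[bps$sample_id %in% samples, , drop = FALSE]
  empty <- data.frame(gene_id = character(), sample_id = character(),
                      sv_id = character(), near_bp = integer(),
                      bp_chrom = character(), bp_pos = numeric(),
                      distance_to_gene = numeric(), tss_distance = numeric(),
                      mate_chrom = character(), mate_pos = numeric(),
                      mate_is_distal = logical(), stringsAsFactors = FALSE)
  if (nrow(bps) == 0) return(empty)

  win <- window_interval(genes, window, config)
  hits <- GenomicRanges::findOverlaps(.gr_points(bps$chrom, bps$pos),
                                      .gr_intervals(win))
  bi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  if (length(bi) == 0) return(empty)

  tss <- gene_tss(genes)
  cand <- data.frame(
    gene_idx = gi,
    gene_id = genes$gene_id[gi],
    sample_id = bps$sample_id[bi],
    sv_id = bps$sv_id[bi],
    near_bp = bps$mate_index[bi],
    bp_chrom = bps$chrom[bi],
    bp_pos = bps$pos[bi],
    distance_to_gene = bp_gene_distance(bps$pos[bi], genes$start[gi],
                                        genes$end[gi]),
    tss_distance = abs(bps$pos[bi] - tss[gi]),
    stringsAsFactors = FALSE
  )
  ord <- order(cand$gene_idx, cand$sample_id, cand$tss_distance,
               cand$bp_pos, cand$sv_id, cand$near_bp)
  cand <- cand[ord, , drop = FALSE]
  keep <- !duplicated(cand[c("gene_idx", "sample_id")])
  cand <- cand[keep, , drop = FALSE]

  # mate coordinates from the SV table
  svi <- match(cand$sv_id, svs$sv_id)
  mate1 <- cand$near_bp == 1L
  cand$mate_chrom <- ifelse(mate1, svs$chrom2[svi], svs$chrom1[svi])
  cand$mate_pos <- ifelse(mate1, svs$pos2[svi], svs$pos1[svi])

  flank <- window_interval(genes, "flank1mb", config)
  fi <- cand$gene_idx
  cand$mate_is_distal <- cand$mate_chrom != genes$chrom[fi] |
    cand$mate_pos < flank$start[fi] | cand$mate_pos >= flank$end[fi]

  rownames(cand) <- NULL
  cand$gene_idx <- NULL
  cand
}
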