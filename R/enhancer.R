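# distance from a point to a 0-based half-open interval [s, e):
# 0 when the point overlaps, otherwise the gap to the nearest edge
.point_interval_dist <- function(pos, s, e) {
  pmax(0, s - pos, pos - e)
}

#' Distance from each gene's TSS to its nearest native upstream enhancer
#'
#' Scans the strand-aware 1 Mb (configurable) region upstream of the
#' unaltered gene for enhancers; returns the minimum TSS-to-enhancer edge
#' distance (0 when an enhancer overlaps the TSS), or Inf when none is
#' found. Enhancers strictly downstream of the TSS are not counted.
#'
#' @param genes Gene table.
#' @param enhancers Enhancer intervals (chrom, start, end), 0-based
#'   half-open.
#' @param scan Scan distance upstream of the TSS in bp.
#' @return Named numeric vector of distances (Inf when no enhancer), one per
#'   gene.
#' @export
native_enhancer_distance <- function(genes, enhancers, scan = 1e6) {
  genes <- validate_genes(genes)
  tss <- gene_tss(genes)
  out <- rep(Inf, nrow(genes))
  names(out) <- genes$gene_id
  for (chr in unique(genes$chrom)) {
    enh <- enhancers[enhancers$chrom == chr, , drop = FALSE]
    if (nrow(enh) == 0) next
    idx <- which(genes$chrom == chr)
    for (i in idx) {
      t <- tss[i]
      if (genes$strand[i] == "+") {
        cand <- enh$start <= t & enh$end > t - scan
      } else {
        cand <- enh$end > t & enh$start < t + scan
      }
      if (!any(cand)) next
      d <- .point_interval_dist(t, enh$start[cand], enh$end[cand])
      out[i] <- min(d)
    }
  }
  out
}

#' Call putative enhancer translocation (hijacking) events
#'
#' For each gene-to-SV association whose mate breakpoint is distal (other
#' chromosome or beyond the gene's flank window), scans the region around
#' the mate breakpoint for enhancers. The rearrangement is modeled as
#' placing the nearest such enhancer at post-rearrangement distance
#' d_new = d(bp1, TSS) + d(bp2, enhancer) from the gene. An event is called
#' when an enhancer exists within the scan distance of the mate breakpoint,
#' d_new does not exceed \code{hijack_max_dist} (500 kb by default), and
#' d_new is smaller than the distance to any native enhancer within the
#' upstream scan window of the unaltered gene.
#'
#' @param assocs Associations from \code{\link{gene_sv_associations}} (only
#'   rows with \code{mate_is_distal} produce calls).
#' @param genes Gene table.
#' @param enhancers Enhancer intervals.
#' @param config \code{\link{sv_config}}.
#' @return Data frame with gene_id, sample_id, sv_id, d_bp1_to_tss,
#'   d_bp2_to_enh, d_new, d_native, enh_start, enh_end, is_event.
#' @export
call_hijacks <- function(assocs, genes, enhancers, config = sv_config()) {
  genes <- validate_genes(genes)
  calls <- assocs[assocs$mate_is_distal, , drop = FALSE]
  tss <- gene_tss(genes)
  gi <- match(calls$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("association references a gene absent from the gene table")
  d1 <- abs(calls$bp_pos - tss[gi])

  n <- nrow(calls)
  d2 <- rep(Inf, n)
  enh_start <- rep(NA_real_, n)
  enh_end <- rep(NA_real_, n)
  for (chr in unique(calls$mate_chrom)) {
    enh <- enhancers[enhancers$chrom == chr, , drop = FALSE]
    rows <- which(calls$mate_chrom == chr)
    if (nrow(enh) == 0) next
    for (i in rows) {
      d <- .point_interval_dist(calls$mate_pos[i], enh$start, enh$end)
      within <- d <= config$enhancer_scan_dist
      if (!any(within)) next
      j <- which(within)[which.min(d[within])]
      d2[i] <- d[j]
      enh_start[i] <- enh$start[j]
      enh_end[i] <- enh$end[j]
    }
  }
  d_native <- native_enhancer_distance(genes, enhancers,
                                       scan = config$enhancer_scan_dist)[gi]
  d_new <- d1 + d2
  is_event <- is.finite(d2) & d_new <= config$hijack_max_dist &
    d_new < d_native
  data.frame(
    gene_id = calls$gene_id, sample_id = calls$sample_id,
    sv_id = calls$sv_id,
    d_bp1_to_tss = d1, d_bp2_to_enh = d2, d_new = d_new,
    d_native = d_native,
    enh_start = enh_start, enh_end = enh_end,
    is_event = is_event,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Enrichment of hijack events among over-expressed associations
#'
#' Compares the fraction of enhancer translocation events among associations
#' whose harboring sample over-expresses a significant gene with the
#' fraction among all other associations, by Pearson chi-squared test.
#'
#' @param calls Output of \code{\link{call_hijacks}}.
#' @param overexpressed Logical vector along the rows of \code{calls}, e.g.
#'   from \code{\link{overexpressed_flags}}.
#' @return List with table (2x2), statistic, p_value.
#' @export
hijack_enrichment <- function(calls, overexpressed) {
  if (length(overexpressed) != nrow(calls))
    stop("overexpressed flags must align with the call rows")
  tab <- matrix(c(
    sum(calls$is_event & overexpressed),
    sum(!calls$is_event & overexpressed),
    sum(calls$is_event & !overexpressed),
    sum(!calls$is_event & !overexpressed)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(group = c("overexpressed", "other"),
                  event = c("event", "no_event")))
  c(chisq_2x2(tab)[c("statistic", "p_value")], list(table = tab))
}
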