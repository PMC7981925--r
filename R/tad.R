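#' Classify SVs as TAD-preserving or TAD-disrupting
#'
#' Each breakpoint is assigned to the TAD containing it (half-open
#' containment; with nested or overlapping annotations the smallest
#' containing TAD wins). An SV is preserving when both breakpoints lie in
#' the same TAD, disrupting when they lie in different TADs (including
#' different chromosomes), and unassigned when either breakpoint falls in a
#' TAD gap.
#'
#' @param svs SV table (internal 0-based form).
#' @param tads TAD intervals (chrom, start, end), 0-based half-open.
#' @return Data frame: sv_id, sample_id, class in
#'   {preserving, disrupting, unassigned}, tad1, tad2 (interval labels or
#'   NA).
#' @export
classify_sv_tads <- function(svs, tads) {
  tad_label <- paste0(tads$chrom, ":",
                      format(tads$start, scientific = FALSE, trim = TRUE),
                      "-", format(tads$end, scientific = FALSE, trim = TRUE))
  assign_tad <- function(chrom, pos) {
    hits <- GenomicRanges::findOverlaps(.gr_points(chrom, pos),
                                        .gr_intervals(tads))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out <- rep(NA_integer_, length(pos))
    if (length(qi) > 0) {
      w <- tads$end[si] - tads$start[si]
      ord <- order(qi, w, si)
      qi <- qi[ord]; si <- si[ord]
      first <- !duplicated(qi)
      out[qi[first]] <- si[first]
    }
    out
  }
  t1 <- assign_tad(svs$chrom1, svs$pos1)
  t2 <- assign_tad(svs$chrom2, svs$pos2)
  class <- ifelse(is.na(t1) | is.na(t2), "unassigned",
                  ifelse(t1 == t2, "preserving", "disrupting"))
  data.frame(
    sv_id = svs$sv_id, sample_id = svs$sample_id, class = class,
    tad1 = ifelse(is.na(t1), NA_character_, tad_label[t1]),
    tad2 = ifelse(is.na(t2), NA_character_, tad_label[t2]),
    stringsAsFactors = FALSE
  )
}

#' Enrichment of TAD disruption among expression-linked SVs
#'
#' Compares the fraction of TAD-disrupting SVs among SVs linked (through the
#' gene-to-SV associations) to over-expressed significant genes with the
#' fraction among all other classified SVs, by Pearson chi-squared test.
#' Unassigned SVs are excluded from both groups.
#'
#' @param tad_calls Output of \code{\link{classify_sv_tads}}.
#' @param linked_sv_ids sv_ids of SVs linked to over-expressed significant
#'   genes.
#' @return List with table (2x2), statistic, p_value.
#' @export
tad_enrichment <- function(tad_calls, linked_sv_ids) {
  cl <- tad_calls[tad_calls$class != "unassigned", , drop = FALSE]
  linked <- cl$sv_id %in% linked_sv_ids
  disrupting <- cl$class == "disrupting"
  tab <- matrix(c(
    sum(disrupting & linked), sum(!disrupting & linked),
    sum(disrupting & !linked), sum(!disrupting & !linked)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(group = c("linked_overexpressed", "other"),
                  class = c("disrupting", "preserving")))
  c(chisq_2x2(tab)[c("statistic", "p_value")], list(table = tab))
}
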