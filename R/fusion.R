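#' Annotate RNA-seq fusion candidates with SV breakpoint support
#'
#' For each candidate (gene5, gene3, sample), checks whether any breakpoint
#' of that sample's SVs falls inside either partner's gene body. Partners
#' missing from the gene table are skipped (support computed on the
#' available partner) with a warning.
#'
#' @param fusions Data frame with gene5, gene3, sample_id.
#' @param genes Gene table.
#' @param svs SV table (internal 0-based form).
#' @return \code{fusions} with logical columns sv_in_gene5, sv_in_gene3 and
#'   a support column in {none, sv_one_gene, sv_both_genes}.
#' @export
annotate_sv_support <- function(fusions, genes, svs) {
  genes <- validate_genes(genes)
  bps <- sv_breakpoints(svs)
  hit_keys <- character(0)
  if (nrow(bps) > 0) {
    body <- window_interval(genes, "body")
    hits <- GenomicRanges::findOverlaps(.gr_points(bps$chrom, bps$pos),
                                        .gr_intervals(body))
    hit_keys <- unique(paste(genes$gene_id[S4Vectors::subjectHits(hits)],
                             bps$sample_id[S4Vectors::queryHits(hits)],
                             sep = "\r"))
  }
  missing <- setdiff(unique(c(fusions$gene5, fusions$gene3)), genes$gene_id)
  if (length(missing) > 0)
    warning(sprintf("%d fusion partner gene(s) absent from the gene table; support computed on the available partner",
                    length(missing)))
  in5 <- fusions$gene5 %in% genes$gene_id &
    paste(fusions$gene5, fusions$sample_id, sep = "\r") %in% hit_keys
  in3 <- fusions$gene3 %in% genes$gene_id &
    paste(fusions$gene3, fusions$sample_id, sep = "\r") %in% hit_keys
  fusions$sv_in_gene5 <- in5
  fusions$sv_in_gene3 <- in3
  fusions$support <- ifelse(in5 & in3, "sv_both_genes",
                            ifelse(in5 | in3, "sv_one_gene", "none"))
  fusions
}

#' Annotate fusion candidates with the high-expression rule
#'
#' A candidate has a high expression association when either: (1) the fusion
#' pair occurs in at most two samples and every harboring sample
#' over-expresses at least one partner (z > 0.4 SD above the gene's
#' cross-sample median); or (2) either partner shows a significant positive
#' association between breakpoints and expression (p below
#' \code{fusion_p_threshold}, positive t) in the CNA-corrected model, in
#' either the distance-weighted flank window or the gene-body window.
#' Recurrence is counted on the unordered gene pair.
#'
#' @param fusions Data frame with gene5, gene3, sample_id.
#' @param expr Expression matrix.
#' @param assoc_results Screen results from
#'   \code{\link{run_association_screen}} covering the qualifying windows.
#' @param config \code{\link{sv_config}}.
#' @param windows Window labels that qualify for rule (2).
#' @param model Model family that qualifies for rule (2).
#' @return \code{fusions} with n_samples_with_fusion and high_expression
#'   columns.
#' @export
annotate_high_expression <- function(fusions, expr, assoc_results,
                                     config = sv_config(),
                                     windows = c("flank1mb_wt", "body"),
                                     model = "type_plus_cna") {
  pair <- paste(pmin(fusions$gene5, fusions$gene3),
                pmax(fusions$gene5, fusions$gene3), sep = "\r")
  pair_sample <- paste(pair, fusions$sample_id, sep = "\r")
  n_per_pair <- tapply(fusions$sample_id, pair,
                       function(s) length(unique(s)))
  fusions$n_samples_with_fusion <- as.integer(n_per_pair[pair])

  z <- expr_zscores(expr)
  zmax <- function(g5, g3, s) {
    si <- match(s, colnames(z))
    v5 <- ifelse(g5 %in% rownames(z) & !is.na(si), z[cbind(match(g5, rownames(z)), si)], NA)
    v3 <- ifelse(g3 %in% rownames(z) & !is.na(si), z[cbind(match(g3, rownames(z)), si)], NA)
    pmax(v5, v3, na.rm = TRUE)
  }
  # rule 1: every harboring sample of a <=2-sample pair passes the z rule
  zrow <- suppressWarnings(zmax(fusions$gene5, fusions$gene3, fusions$sample_id))
  zrow[!is.finite(zrow)] <- -Inf
  sample_pass <- zrow > config$overexpr_sd_threshold
  # a sample harboring the pair passes if any of its candidate rows pass
  ps_pass <- tapply(sample_pass, pair_sample, any)
  pair_all_pass <- tapply(ps_pass, sub("\r[^\r]*$", "", names(ps_pass)), all)
  rule1 <- fusions$n_samples_with_fusion <= 2 & as.logical(pair_all_pass[pair])

  # rule 2: significant positive association for either partner
  qual <- assoc_results$status == "ok" &
    assoc_results$model == model &
    assoc_results$window %in% windows &
    assoc_results$p_value < config$fusion_p_threshold &
    assoc_results$t_stat > 0
  qual_genes <- unique(assoc_results$gene_id[qual])
  rule2 <- fusions$gene5 %in% qual_genes | fusions$gene3 %in% qual_genes

  fusions$high_expression <- rule1 | rule2
  fusions
}
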