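#' Strand-aware transcription start coordinate
#'
#' For a + strand gene the TSS is the start coordinate; for a - strand gene
#' it is the end coordinate (the first transcribed position in half-open
#' coordinates). All upstream windows and breakpoint-to-gene-start distances
#' are measured from this point.
#'
#' @param genes Gene table (gene_id, chrom, start, end, strand).
#' @return Numeric vector of TSS coordinates, one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Region window interval for each gene
#'
#' Computes the genomic interval of a region window relative to each gene,
#' strand-aware for upstream/downstream, clipped at the chromosome origin.
#' All intervals are 0-based half-open. For a + strand gene:
#' up100k = [start-s, start), down100k = [end, end+s), body = [start, end),
#' flank1mb = [start-f, end+f) including the body; upstream and downstream
#' are mirrored on the - strand.
#'
#' @param genes Gene table.
#' @param window One of \code{\link{region_windows}}.
#' @param config \code{\link{sv_config}} supplying the window sizes.
#' @return Data frame with gene_id, chrom, start, end.
#' @export
window_interval <- function(genes, window = region_windows,
                            config = sv_config()) {
  window <- match.arg(window)
  s <- config$window_updown
  f <- config$window_flank
  plus <- genes$strand == "+"
  if (window == "body") {
    start <- genes$start; end <- genes$end
  } else if (window == "flank1mb") {
    start <- genes$start - f; end <- genes$end + f
  } else if (window == "up100k") {
    start <- ifelse(plus, genes$start - s, genes$end)
    end <- ifelse(plus, genes$start, genes$end + s)
  } else { # down100k
    start <- ifelse(plus, genes$end, genes$start - s)
    end <- ifelse(plus, genes$end + s, genes$start)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, start), end = pmax(0, end),
             stringsAsFactors = FALSE)
}

#' Distance from a breakpoint to a gene
#'
#' Zero inside the gene body, otherwise the distance to the nearer of the
#' gene's two ends: min(|pos - start|, |pos - end|). This is the distance
#' used by the relative distance metric.
#'
#' @param pos Breakpoint position(s), 0-based.
#' @param gene_start,gene_end Gene body interval, 0-based half-open.
#' @return Numeric vector of distances in bp.
#' @export
bp_gene_distance <- function(pos, gene_start, gene_end) {
  inside <- pos >= gene_start & pos < gene_end
  ifelse(inside, 0, pmin(abs(pos - gene_start), abs(pos - gene_end)))
}

#' Distance weight of a breakpoint
#'
#' Linear decay with distance from the gene: w = 1 - d / window_size, so a
#' breakpoint inside the gene body (d = 0) has full weight and one exactly at
#' the window edge has weight 0. Breakpoints close to the gene therefore
#' carry more numeric weight in the association model, while breakpoints
#' further away but within the window retain some influence.
#'
#' @param distance_to_gene Distance(s) in bp, from
#'   \code{\link{bp_gene_distance}}.
#' @param window_size Flank window size in bp (default 1 Mb).
#' @return Weights in [0, 1].
#' @export
breakpoint_weight <- function(distance_to_gene, window_size = 1e6) {
  if (any(distance_to_gene < 0))
    stop("negative distance_to_gene")
  if (any(distance_to_gene > window_size))
    stop("distance_to_gene exceeds window_size; pre-filter to the window")
  1 - distance_to_gene / window_size
}
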