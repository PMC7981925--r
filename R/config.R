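#' Analysis configuration
#'
#' Bundles the tunable constants used across the pipeline. Distances are in
#' base pairs on 0-based half-open coordinates; thresholds on probabilities
#' lie in (0,1).
#'
#' @param window_updown Size of the upstream/downstream region windows
#'   (default 100 kb).
#' @param window_flank Size of the flanking window on each side of the gene
#'   (default 1 Mb); the only window eligible for distance weighting.
#' @param use_distance_metric Default for weighting the 1 Mb flank matrix.
#' @param overexpr_sd_threshold Over-expression cutoff: a sample's expression
#'   must exceed the gene's cross-sample median by more than this many
#'   cross-sample standard deviations (default 0.4).
#' @param hijack_max_dist Maximum modeled post-rearrangement gene-enhancer
#'   distance for an enhancer translocation call (default 500 kb).
#' @param enhancer_scan_dist Scan radius around the mate breakpoint (and the
#'   native upstream scan from the TSS) for enhancers (default 1 Mb).
#' @param fusion_p_threshold Per-gene p-value cutoff used by the fusion
#'   high-expression rule (default 0.01).
#' @param fdr_threshold Storey q-value significance cutoff (default 0.10).
#' @param min_altered_samples Minimum number of breakpoint-carrying samples a
#'   gene needs before its model is fit (default 1).
#' @return A list of class \code{sv_config}.
#' @export
sv_config <- function(window_updown = 1e5,
                      window_flank = 1e6,
                      use_distance_metric = FALSE,
                      overexpr_sd_threshold = 0.4,
                      hijack_max_dist = 5e5,
                      enhancer_scan_dist = 1e6,
                      fusion_p_threshold = 0.01,
                      fdr_threshold = 0.10,
                      min_altered_samples = 1L) {
  stopifnot(
    window_updown > 0, window_flank > 0,
    hijack_max_dist > 0, enhancer_scan_dist > 0,
    overexpr_sd_threshold > 0,
    fusion_p_threshold > 0, fusion_p_threshold < 1,
    fdr_threshold > 0, fdr_threshold < 1,
    min_altered_samples >= 1
  )
  structure(list(
    window_updown = as.numeric(window_updown),
    window_flank = as.numeric(window_flank),
    use_distance_metric = isTRUE(use_distance_metric),
    overexpr_sd_threshold = overexpr_sd_threshold,
    hijack_max_dist = as.numeric(hijack_max_dist),
    enhancer_scan_dist = as.numeric(enhancer_scan_dist),
    fusion_p_threshold = fusion_p_threshold,
    fdr_threshold = fdr_threshold,
    min_altered_samples = as.integer(min_altered_samples)
  ), class = "sv_config")
}

#' Region window labels
#'
#' The four region windows relative to a gene over which breakpoint matrices
#' are built: 100 kb upstream, 100 kb downstream, the gene body, and the
#' gene body plus 1 Mb on each side. Only \code{"flank1mb"} supports
#' distance weighting.
#' @export
region_windows <- c("up100k", "down100k", "body", "flank1mb")
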