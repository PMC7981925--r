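#' Run the full integration pipeline from a config file
#'
#' Executes matrix construction, the association screen, enhancer-hijack
#' calling, TAD classification and fusion annotation in order, skipping any
#' stage whose inputs are absent from the config (e.g. no enhancer BED means
#' no hijack stage), and writes every stage output plus a run manifest to
#' \code{out_dir}.
#'
#' The config is a YAML file (or an equivalent named list) with an
#' \code{inputs} block (paths: sv_table, genes, expr, cna, samples,
#' enhancers, tads, fusions) and an optional \code{params} block overriding
#' \code{\link{sv_config}} fields plus \code{window} and
#' \code{distance_weight}.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory; defaults to the config's \code{out_dir}
#'   or "svexpr_out".
#' @return Invisible list with the in-memory stage results and the output
#'   paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs
  if (is.null(inputs)) stop("config has no 'inputs' block")
  params <- config$params
  if (is.null(params)) params <- list()
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- "svexpr_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_args <- params[intersect(names(params), names(formals(sv_config)))]
  cfg <- do.call(sv_config, cfg_args)
  window <- if (is.null(params$window)) "flank1mb" else params$window
  weighted <- isTRUE(params$distance_weight)

  need <- function(key) {
    p <- inputs[[key]]
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) stop(sprintf("stage input '%s' not found: %s", key, p))
    p
  }
  svs_path <- need("sv_table"); genes_path <- need("genes")
  if (is.null(svs_path) || is.null(genes_path))
    stop("config must provide 'sv_table' and 'genes' inputs")
  cm <- c(sample = "sample", chrom1 = "chrom1", pos1 = "pos1",
          chrom2 = "chrom2", pos2 = "pos2")
  if (!is.null(params$column_mapping)) cm <- unlist(params$column_mapping)
  svs <- read_sv_table(svs_path, column_mapping = cm)
  genes <- read_gene_table(genes_path)

  expr <- if (!is.null(need("expr"))) read_matrix(inputs$expr) else NULL
  cna <- if (!is.null(need("cna"))) read_matrix(inputs$cna) else NULL
  annot <- if (!is.null(need("samples"))) read_sample_annotation(inputs$samples) else NULL
  enhancers <- if (!is.null(need("enhancers"))) read_bed_intervals(inputs$enhancers) else NULL
  tads <- if (!is.null(need("tads"))) read_bed_intervals(inputs$tads) else NULL
  fusions <- if (!is.null(need("fusions")))
    utils::read.delim(inputs$fusions, stringsAsFactors = FALSE) else NULL

  out <- list()
  skipped <- character(0)
  samples <- if (!is.null(expr)) colnames(expr) else sort(unique(svs$sample_id))

  # matrix stage
  bp <- build_bp_matrix(genes, svs, window, cfg, samples = samples,
                        weighted = weighted)
  assocs <- gene_sv_associations(genes, svs, window, cfg, samples = samples)
  write_matrix(bp, file.path(out_dir, "bp_matrix.tsv"))
  write_tsv(assocs, file.path(out_dir, "gene_sv_associations.tsv"))
  out$bp_matrix <- bp
  out$assocs <- assocs

  # association stage
  sig_genes <- character(0)
  if (!is.null(expr) && !is.null(annot)) {
    models <- if (is.null(cna)) "type_only" else c("type_only", "type_plus_cna")
    screen <- run_association_screen(expr, bp, annot, cna = cna, config = cfg,
                                     models = models)
    write_tsv(screen, file.path(out_dir, "association_results.tsv"))
    out$screen <- screen
    pref <- if ("type_plus_cna" %in% models) "type_plus_cna" else "type_only"
    sig_genes <- screen$gene_id[screen$model == pref & screen$significant]
  } else {
    skipped <- c(skipped, "associate")
  }

  over <- if (!is.null(expr) && length(sig_genes) >= 0 && !is.null(out$screen))
    overexpressed_flags(assocs, expr, sig_genes, cfg$overexpr_sd_threshold)
  else NULL

  # hijack stage
  if (!is.null(enhancers)) {
    calls <- call_hijacks(assocs, genes, enhancers, cfg)
    write_tsv(calls, file.path(out_dir, "hijack_calls.tsv"))
    out$hijack_calls <- calls
    if (!is.null(over)) {
      over_calls <- overexpressed_flags(calls, expr, sig_genes,
                                        cfg$overexpr_sd_threshold)
      enr <- hijack_enrichment(calls, over_calls)
      write_tsv(data.frame(statistic = enr$statistic, p_value = enr$p_value),
                file.path(out_dir, "hijack_enrichment.tsv"))
      out$hijack_enrichment <- enr
    }
  } else {
    skipped <- c(skipped, "hijack")
  }

  # tad stage
  if (!is.null(tads)) {
    tad_calls <- classify_sv_tads(svs, tads)
    write_tsv(tad_calls, file.path(out_dir, "tad_calls.tsv"))
    out$tad_calls <- tad_calls
    if (!is.null(over)) {
      linked <- unique(assocs$sv_id[over])
      enr <- tad_enrichment(tad_calls, linked)
      write_tsv(data.frame(statistic = enr$statistic, p_value = enr$p_value),
                file.path(out_dir, "tad_enrichment.tsv"))
      out$tad_enrichment <- enr
    }
  } else {
    skipped <- c(skipped, "tad")
  }

  # fusion stage
  if (!is.null(fusions)) {
    fus <- annotate_sv_support(fusions, genes, svs)
    if (!is.null(out$screen))
      fus <- annotate_high_expression(fus, expr, out$screen, cfg)
    write_tsv(fus, file.path(out_dir, "fusion_annotations.tsv"))
    out$fusions <- fus
  } else {
    skipped <- c(skipped, "fusions")
  }

  if (length(skipped) > 0)
    message("skipped stage(s) with absent inputs: ",
            paste(skipped, collapse = ", "))

  manifest <- list(
    tool = "svexpr",
    version = as.character(utils::packageVersion("svexpr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_digests = as.list(tools::md5sum(unlist(Filter(Negate(is.null),
      inputs[c("sv_table", "genes", "expr", "cna", "samples",
               "enhancers", "tads", "fusions")])))),
    stages_skipped = skipped
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$out_dir <- out_dir
  invisible(out)
}
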