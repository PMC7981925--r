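#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The defaults describe the
#' reference study conditions used throughout the test suite: 1000 genes on
#' evenly spaced loci, 200 samples in 3 cancer types, a background SV
#' process of 2.5 SVs per sample, expression effects of 2 SD planted in 5%
#' of genes, and unit Gaussian noise on log-scale expression.
#'
#' @param n_genes,n_samples,n_cancer_types,n_svs Cohort dimensions;
#'   \code{n_svs} is the number of background SVs (default
#'   \code{round(2.5 * n_samples)}).
#' @param effect_size_sd Expression shift (in noise-SD units) added for each
#'   sample carrying a breakpoint in the effect window of an effect gene.
#' @param frac_genes_with_effect Fraction of genes receiving a planted
#'   effect.
#' @param cna_confounding_strength Added CNA dosage in breakpoint-carrying
#'   samples, coupling SV presence to expression through the CNA slope.
#' @param frac_hijack_mechanism,frac_tad_mechanism Fractions of effect genes
#'   whose SVs are engineered with enhancer-translocation or TAD-disruption
#'   geometry (the remainder inherit the background SV geometry).
#' @param seed Random seed; runs are byte-identical per seed.
#' @param gene_spacing,gene_width,margin Genome layout in bp.
#' @param tad_width,tad_gap TAD tiling: TADs of \code{tad_width} separated
#'   by boundary gaps of \code{tad_gap}.
#' @param enhancer_per_mb Mean scattered enhancer density.
#' @param noise_sd,cna_sd,cna_slope,type_effect_sd Expression model terms:
#'   expr = cancer-type mean + cna_slope * CNA + effect + N(0, noise_sd).
#' @param intra_tad_prob Probability that a background SV's second
#'   breakpoint is placed inside the same TAD as the first.
#' @param mech_samples_per_gene Planted SVs (carrier samples) per effect
#'   gene.
#' @param n_fusions_supported,n_fusions_unsupported Fusion candidates to
#'   emit with and without matching within-gene SV breakpoints.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 1000, n_samples = 200, n_cancer_types = 3,
                       n_svs = round(2.5 * n_samples),
                       effect_size_sd = 2, frac_genes_with_effect = 0.05,
                       cna_confounding_strength = 0,
                       frac_hijack_mechanism = 0, frac_tad_mechanism = 0,
                       seed = 1,
                       gene_spacing = 2.5e5, gene_width = 2e4, margin = 2e6,
                       tad_width = 7.5e5, tad_gap = 5e4,
                       enhancer_per_mb = 2,
                       noise_sd = 1, cna_sd = 0.5, cna_slope = 0.5,
                       type_effect_sd = 0.7,
                       intra_tad_prob = 0.7,
                       mech_samples_per_gene = 8,
                       n_fusions_supported = 0, n_fusions_unsupported = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$n_samples >= 2, cfg$n_cancer_types >= 1,
            cfg$n_svs >= 0,
            cfg$frac_genes_with_effect >= 0, cfg$frac_genes_with_effect <= 1,
            cfg$frac_hijack_mechanism >= 0, cfg$frac_hijack_mechanism <= 1,
            cfg$frac_tad_mechanism >= 0, cfg$frac_tad_mechanism <= 1,
            cfg$frac_hijack_mechanism + cfg$frac_tad_mechanism <= 1,
            cfg$intra_tad_prob >= 0, cfg$intra_tad_prob <= 1,
            cfg$noise_sd > 0)
  structure(cfg, class = "sim_config")
}

#' Preset simulation scenarios
#'
#' \describe{
#'   \item{null}{No planted effects: calibration of type-I error and pi0.}
#'   \item{signal}{2 SD effects in 5\% of genes; SV geometry identical for
#'     effect and non-effect genes, so mechanism enrichments are null.}
#'   \item{hijack}{As signal, but every effect gene's SVs are engineered
#'     with callable enhancer-translocation geometry.}
#'   \item{tad}{As signal, but every effect gene's SVs are engineered to
#'     span TAD boundaries.}
#' }
#'
#' @param preset Scenario name.
#' @param seed Random seed.
#' @param ... Overrides passed to \code{\link{sim_config}}.
#' @return \code{sim_config}.
#' @export
preset_sim_config <- function(preset = c("null", "signal", "hijack", "tad"),
                              seed = 1, ...) {
  preset <- match.arg(preset)
  over <- list(...)
  base <- switch(preset,
    null = list(effect_size_sd = 0, frac_genes_with_effect = 0),
    signal = list(),
    hijack = list(frac_hijack_mechanism = 1),
    tad = list(frac_tad_mechanism = 1)
  )
  do.call(sim_config, c(list(seed = seed), utils::modifyList(base, over)))
}

.sim_genome <- function(cfg) {
  n_chrom <- max(2, min(8, ceiling(cfg$n_genes / 300)))
  genes_per_chrom <- ceiling(cfg$n_genes / n_chrom)
  chrom_len <- 2 * cfg$margin + genes_per_chrom * cfg$gene_spacing
  chroms <- paste0("chr", seq_len(n_chrom))
  list(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
       chrom_len = chrom_len, chroms = chroms)
}

#' Simulate a full synthetic cohort
#'
#' Generates every input the pipeline consumes: gene models on synthetic
#' chromosomes with TAD tiling and scattered enhancers, a background somatic
#' SV process, expression and CNA matrices, sample annotations, optional
#' fusion candidates, and a truth table of planted effects. Expression
#' effects are added from the realized breakpoint pattern in the 1 Mb flank
#' window (effect genes are drawn among genes with enough breakpoint
#' carriers), so in mechanism-free scenarios SV geometry is exchangeable
#' between effect and non-effect genes. Mechanism presets additionally plant
#' engineered SVs with hijack or TAD-disruption geometry for the effect
#' genes. Fully reproducible per seed.
#'
#' @param cfg \code{\link{sim_config}}.
#' @return List of class \code{sv_cohort} with elements genes, svs, expr,
#'   cna, sample_annot, enhancers, tads, fusions, truth, bp_matrix, config.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  geo <- .sim_genome(cfg)
  total_len <- geo$n_chrom * geo$chrom_len
  if (cfg$n_svs > total_len / 1e3)
    stop("infeasible placement: too many SVs for the synthetic genome size")

  # genes: evenly spaced, random strand
  gi <- seq_len(cfg$n_genes)
  chrom_idx <- (gi - 1) %/% geo$genes_per_chrom + 1
  within <- (gi - 1) %% geo$genes_per_chrom
  start <- cfg$margin + within * cfg$gene_spacing
  genes <- data.frame(
    gene_id = sprintf("G%04d", gi),
    chrom = geo$chroms[chrom_idx],
    start = start, end = start + cfg$gene_width,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # TAD tiling with boundary gaps
  step <- cfg$tad_width + cfg$tad_gap
  n_tads <- floor(geo$chrom_len / step)
  tads <- do.call(rbind, lapply(geo$chroms, function(ch) {
    s <- (seq_len(n_tads) - 1) * step
    data.frame(chrom = ch, start = s, end = s + cfg$tad_width,
               name = paste0(ch, "_tad", seq_len(n_tads)),
               stringsAsFactors = FALSE)
  }))

  # scattered enhancers
  n_enh_per_chrom <- round(geo$chrom_len / 1e6 * cfg$enhancer_per_mb)
  enhancers <- do.call(rbind, lapply(geo$chroms, function(ch) {
    s <- sort(round(stats::runif(n_enh_per_chrom, 0, geo$chrom_len - 1e3)))
    data.frame(chrom = ch, start = s, end = s + 1e3,
               name = paste0(ch, "_enh", seq_len(n_enh_per_chrom)),
               stringsAsFactors = FALSE)
  }))

  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  annot <- data.frame(
    sample_id = samples,
    cancer_type = paste0("type", (seq_len(cfg$n_samples) - 1) %%
                           cfg$n_cancer_types + 1),
    stringsAsFactors = FALSE
  )

  rand_pos <- function(n) {
    ci <- sample.int(geo$n_chrom, n, replace = TRUE)
    data.frame(chrom = geo$chroms[ci],
               pos = floor(stats::runif(n, 0, geo$chrom_len)))
  }
  tad_of <- function(chrom, pos) {
    ti <- floor(pos / step)
    inside <- pos - ti * step < cfg$tad_width & ti < n_tads
    ifelse(inside, ti, NA_integer_)
  }

  # background SV process
  sv_rows <- list()
  if (cfg$n_svs > 0) {
    p1 <- rand_pos(cfg$n_svs)
    t1 <- tad_of(p1$chrom, p1$pos)
    same_tad <- stats::runif(cfg$n_svs) < cfg$intra_tad_prob & !is.na(t1)
    p2 <- rand_pos(cfg$n_svs)
    in_tad_pos <- floor(t1 * step + stats::runif(cfg$n_svs, 0, cfg$tad_width))
    p2$chrom[same_tad] <- p1$chrom[same_tad]
    p2$pos[same_tad] <- in_tad_pos[same_tad]
    clash <- p1$chrom == p2$chrom & p1$pos == p2$pos
    p2$pos[clash] <- p2$pos[clash] + 1
    sv_rows$background <- data.frame(
      sample_id = sample(samples, cfg$n_svs, replace = TRUE),
      chrom1 = p1$chrom, pos1 = p1$pos,
      chrom2 = p2$chrom, pos2 = p2$pos,
      sv_type = "background", stringsAsFactors = FALSE
    )
  }

  # choose effect genes and mechanisms
  n_eff <- round(cfg$frac_genes_with_effect * cfg$n_genes)
  n_hij <- round(cfg$frac_hijack_mechanism * n_eff)
  n_tadm <- round(cfg$frac_tad_mechanism * n_eff)
  n_plain <- n_eff - n_hij - n_tadm
  if (n_eff > cfg$n_genes)
    stop("infeasible placement: more effect genes than genes")
  eff_all <- sort(sample.int(cfg$n_genes, n_eff))
  hij_idx <- if (n_hij > 0) sort(sample(eff_all, n_hij)) else integer(0)
  rest <- setdiff(eff_all, hij_idx)
  tad_idx <- if (n_tadm > 0) sort(sample(rest, n_tadm)) else integer(0)
  plain_idx <- setdiff(rest, tad_idx)

  tss <- gene_tss(genes)
  # planted SVs for plain effect genes: the near breakpoint is uniform in
  # the gene's flank window and the mate follows the background mate
  # process, so planted and background associations share one geometry
  if (n_plain > 0) {
    sv_rows$planted <- do.call(rbind, lapply(plain_idx, function(g) {
      k <- min(cfg$mech_samples_per_gene, cfg$n_samples)
      smp <- sample(samples, k)
      f <- 1e6
      bp1 <- floor(stats::runif(k, max(0, genes$start[g] - f),
                                genes$end[g] + f))
      t1 <- tad_of(genes$chrom[g], bp1)
      same <- stats::runif(k) < cfg$intra_tad_prob & !is.na(t1)
      mate <- rand_pos(k)
      in_tad <- floor(t1 * step + stats::runif(k, 0, cfg$tad_width))
      mate$chrom[same] <- genes$chrom[g]
      mate$pos[same] <- in_tad[same]
      data.frame(sample_id = smp,
                 chrom1 = genes$chrom[g], pos1 = bp1,
                 chrom2 = mate$chrom, pos2 = mate$pos,
                 sv_type = "planted", stringsAsFactors = FALSE)
    }))
  }
  # engineered hijack SVs: bp1 100 kb upstream of the TSS, mate on another
  # chromosome 50 kb from a planted donor enhancer; native upstream
  # enhancers of the gene are cleared so the translocated enhancer wins
  if (n_hij > 0) {
    hij <- lapply(hij_idx, function(g) {
      k <- min(cfg$mech_samples_per_gene, cfg$n_samples)
      smp <- sample(samples, k)
      up <- if (genes$strand[g] == "+") tss[g] - 1e5 else tss[g] + 1e5
      donor_chrom <- sample(setdiff(geo$chroms, genes$chrom[g]), 1)
      donor_pos <- floor(stats::runif(1, cfg$margin,
                                      geo$chrom_len - cfg$margin))
      list(svs = data.frame(sample_id = smp,
                            chrom1 = genes$chrom[g], pos1 = up,
                            chrom2 = donor_chrom, pos2 = donor_pos,
                            sv_type = "hijack", stringsAsFactors = FALSE),
           enh = data.frame(chrom = donor_chrom, start = donor_pos + 5e4,
                            end = donor_pos + 5e4 + 1e3,
                            name = paste0("donor_", genes$gene_id[g]),
                            stringsAsFactors = FALSE))
    })
    sv_rows$hijack <- do.call(rbind, lapply(hij, `[[`, "svs"))
    enhancers <- rbind(enhancers, do.call(rbind, lapply(hij, `[[`, "enh")))
    # clear native enhancers within the upstream scan of hijack genes
    for (g in hij_idx) {
      t <- tss[g]
      if (genes$strand[g] == "+") {
        drop <- enhancers$chrom == genes$chrom[g] &
          enhancers$start <= t & enhancers$end > t - 1.1e6
      } else {
        drop <- enhancers$chrom == genes$chrom[g] &
          enhancers$end > t & enhancers$start < t + 1.1e6
      }
      drop <- drop & !grepl("^donor_", enhancers$name)
      enhancers <- enhancers[!drop, , drop = FALSE]
    }
  }

  # engineered TAD-disrupting SVs: bp1 inside the gene body, mate four TADs
  # away on the same chromosome
  if (n_tadm > 0) {
    sv_rows$tad <- do.call(rbind, lapply(tad_idx, function(g) {
      k <- min(cfg$mech_samples_per_gene, cfg$n_samples)
      smp <- sample(samples, k)
      bp1 <- floor(stats::runif(k, genes$start[g], genes$end[g]))
      t1 <- tad_of(genes$chrom[g], bp1)
      t_target <- (ifelse(is.na(t1), 0, t1) + 4) %% n_tads
      bp2 <- floor(t_target * step + stats::runif(k, 0, cfg$tad_width))
      data.frame(sample_id = smp,
                 chrom1 = genes$chrom[g], pos1 = bp1,
                 chrom2 = genes$chrom[g], pos2 = bp2,
                 sv_type = "tad", stringsAsFactors = FALSE)
    }))
  }

  # fusion-supporting SVs and candidate table
  fusions <- NULL
  if (cfg$n_fusions_supported + cfg$n_fusions_unsupported > 0) {
    n_f <- cfg$n_fusions_supported + cfg$n_fusions_unsupported
    pair_idx <- replicate(n_f, sample.int(cfg$n_genes, 2), simplify = FALSE)
    f_samples <- sample(samples, n_f, replace = TRUE)
    fusions <- data.frame(
      gene5 = genes$gene_id[vapply(pair_idx, `[`, 0L, 1)],
      gene3 = genes$gene_id[vapply(pair_idx, `[`, 0L, 2)],
      sample_id = f_samples,
      truth_supported = rep(c(TRUE, FALSE),
                            c(cfg$n_fusions_supported,
                              cfg$n_fusions_unsupported)),
      stringsAsFactors = FALSE
    )
    sup <- which(fusions$truth_supported)
    if (length(sup) > 0) {
      g5 <- match(fusions$gene5[sup], genes$gene_id)
      g3 <- match(fusions$gene3[sup], genes$gene_id)
      sv_rows$fusion <- data.frame(
        sample_id = fusions$sample_id[sup],
        chrom1 = genes$chrom[g5],
        pos1 = floor(stats::runif(length(sup), genes$start[g5], genes$end[g5])),
        chrom2 = genes$chrom[g3],
        pos2 = floor(stats::runif(length(sup), genes$start[g3], genes$end[g3])),
        sv_type = "fusion", stringsAsFactors = FALSE
      )
    }
  }

  svs <- do.call(rbind, sv_rows)
  if (is.null(svs) || nrow(svs) == 0)
    stop("no SVs simulated; increase n_svs or plant mechanisms")
  svs <- cbind(sv_id = sprintf("sv%05d", seq_len(nrow(svs))), svs,
               stringsAsFactors = FALSE)
  rownames(svs) <- NULL
  degen <- svs$chrom1 == svs$chrom2 & svs$pos1 == svs$pos2
  svs$pos2[degen] <- svs$pos2[degen] + 1

  # realized breakpoint pattern drives the planted effects
  B <- build_bp_matrix(genes, svs, "flank1mb", samples = samples)
  I <- (B > 0) * 1

  effect_idx <- sort(c(plain_idx, hij_idx, tad_idx))
  effect <- matrix(0, cfg$n_genes, cfg$n_samples)
  if (length(effect_idx) > 0 && cfg$effect_size_sd != 0)
    effect[effect_idx, ] <- cfg$effect_size_sd * I[effect_idx, , drop = FALSE]

  type_idx <- match(annot$cancer_type, unique(annot$cancer_type))
  mu_type <- matrix(stats::rnorm(cfg$n_genes * cfg$n_cancer_types,
                                 0, cfg$type_effect_sd),
                    cfg$n_genes, cfg$n_cancer_types)
  cna <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$cna_sd),
                cfg$n_genes, cfg$n_samples)
  if (cfg$cna_confounding_strength != 0)
    cna <- cna + cfg$cna_confounding_strength * I
  noise <- matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$noise_sd),
                  cfg$n_genes, cfg$n_samples)
  expr <- mu_type[, type_idx] + cfg$cna_slope * cna + effect + noise
  dimnames(expr) <- dimnames(cna) <- list(genes$gene_id, samples)

  mech <- rep("none", cfg$n_genes)
  mech[hij_idx] <- "hijack"
  mech[tad_idx] <- "tad"
  truth <- data.frame(
    gene_id = genes$gene_id,
    is_effect = seq_len(cfg$n_genes) %in% effect_idx,
    effect_size = ifelse(seq_len(cfg$n_genes) %in% effect_idx,
                         cfg$effect_size_sd, 0),
    mechanism = ifelse(seq_len(cfg$n_genes) %in% effect_idx, mech, "none"),
    n_carriers = as.integer(rowSums(I)),
    stringsAsFactors = FALSE
  )

  structure(list(genes = genes, svs = svs, expr = expr, cna = cna,
                 sample_annot = annot, enhancers = enhancers, tads = tads,
                 fusions = fusions, truth = truth, bp_matrix = B,
                 config = cfg),
            class = "sv_cohort")
}

#' Write a simulated cohort to disk in the pipeline's file formats
#'
#' Emits genes.tsv, svs.tsv (1-based positions, caller convention),
#' expr.tsv, cna.tsv, samples.tsv, enhancers.bed, tads.bed, truth.tsv and
#' (when simulated) fusions.tsv under \code{dir}.
#'
#' @param cohort \code{\link{simulate_cohort}} output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    svs = file.path(dir, "svs.tsv"),
    expr = file.path(dir, "expr.tsv"),
    cna = file.path(dir, "cna.tsv"),
    samples = file.path(dir, "samples.tsv"),
    enhancers = file.path(dir, "enhancers.bed"),
    tads = file.path(dir, "tads.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  write_tsv(cohort$genes, paths["genes"])
  sv_out <- cohort$svs
  sv_out$pos1 <- sv_out$pos1 + 1
  sv_out$pos2 <- sv_out$pos2 + 1
  names(sv_out)[names(sv_out) == "sample_id"] <- "sample"
  write_tsv(sv_out, paths["svs"])
  write_matrix(cohort$expr, paths["expr"])
  write_matrix(cohort$cna, paths["cna"])
  write_tsv(cohort$sample_annot, paths["samples"])
  utils::write.table(cohort$enhancers, paths["enhancers"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$tads, paths["tads"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(cohort$truth, paths["truth"])
  if (!is.null(cohort$fusions)) {
    paths["fusions"] <- file.path(dir, "fusions.tsv")
    write_tsv(cohort$fusions, paths["fusions"])
  }
  invisible(paths)
}
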