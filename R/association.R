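#' Fit one gene's expression-versus-breakpoint linear model
#'
#' Ordinary least squares of expression on the gene's breakpoint pattern
#' (binary or distance-weighted) with cancer-type indicators (reference level
#' dropped) and optionally the gene's copy-number values as covariates.
#' Reports the two-sided t-test on the breakpoint coefficient. Samples with
#' missing expression (or CNA, when used) are dropped for this gene only.
#' Genes whose breakpoint pattern is constant after filtering, or that
#' survive in fewer than \code{min_altered} altered samples, are skipped;
#' cancer-type indicators made collinear by the filtering are dropped by the
#' model-matrix pivoting (level order), never the breakpoint term.
#'
#' @param expr_row Numeric expression vector across samples.
#' @param sv_row Numeric breakpoint pattern across the same samples.
#' @param cancer_type Character or factor of cancer types, same samples.
#' @param cna_row Optional numeric CNA vector, same samples.
#' @param min_altered Minimum altered (nonzero-pattern) samples.
#' @return One-row data frame: beta_sv, t_stat, p_value, n_altered, df,
#'   status in {ok, skipped_constant, skipped_min_alt}.
#' @export
fit_gene_model <- function(expr_row, sv_row, cancer_type, cna_row = NULL,
                           min_altered = 1L) {
  n <- length(expr_row)
  if (length(sv_row) != n || length(cancer_type) != n ||
      (!is.null(cna_row) && length(cna_row) != n))
    stop("expression, breakpoint, cancer-type (and CNA) vectors must align on the same samples")
  res <- function(status, beta = NA_real_, t = NA_real_, p = NA_real_,
                  n_alt = NA_integer_, df = NA_integer_) {
    data.frame(beta_sv = beta, t_stat = t, p_value = p,
               n_altered = n_alt, df = df, status = status,
               stringsAsFactors = FALSE)
  }
  keep <- !is.na(expr_row) & !is.na(sv_row)
  if (!is.null(cna_row)) keep <- keep & !is.na(cna_row)
  y <- expr_row[keep]
  sv <- sv_row[keep]
  ct <- factor(as.character(cancer_type[keep]))
  n_alt <- sum(sv != 0)
  if (length(y) < 3 || length(unique(sv)) < 2)
    return(res("skipped_constant", n_alt = n_alt))
  if (n_alt < min_altered)
    return(res("skipped_min_alt", n_alt = n_alt))

  X <- cbind(`(Intercept)` = 1, sv = sv)
  if (nlevels(ct) > 1)
    X <- cbind(X, stats::model.matrix(~ ct)[, -1, drop = FALSE])
  if (!is.null(cna_row)) X <- cbind(X, cna = cna_row[keep])

  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  piv <- fit$qr$pivot[seq_len(r)]
  sv_col <- 2L
  if (!(sv_col %in% piv))
    return(res("skipped_constant", n_alt = n_alt))
  dfree <- length(y) - r
  if (dfree < 1)
    return(res("skipped_constant", n_alt = n_alt))
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dfree
  Rr <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  xtx_inv <- chol2inv(Rr)
  se <- sqrt(sigma2 * xtx_inv[match(sv_col, piv), match(sv_col, piv)])
  beta <- unname(fit$coefficients["sv"])
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), dfree)
  res("ok", beta, t, p, n_alt, dfree)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05-0.95 (step
#' 0.05) with a cubic smoothing spline (df = 3) evaluated at the largest
#' lambda, clamped to (0, 1]; falls back to pi0 = 1 (equivalent to
#' Benjamini-Hochberg) when fewer than 4 usable grid points are available.
#' q-values are the step-up transform q_(i) = min_{j >= i} pi0 m p_(j) / j,
#' capped at 1.
#'
#' @param p P-values in (0, 1].
#' @param lambda Grid for the pi0 smoother.
#' @param pi0 Optionally force pi0 (e.g. 1 for BH).
#' @return Numeric q-values in the order of \code{p}, with the pi0 estimate
#'   attached as attribute \code{"pi0"}.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    usable <- which(pi0_l > 0)
    if (length(usable) < 4) {
      pi0 <- 1
    } else {
      fit <- stats::smooth.spline(lambda[usable], pi0_l[usable], df = 3)
      pi0 <- stats::predict(fit, x = max(lambda[usable]))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  q_sorted <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1)))
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Genome-wide association screen of expression against breakpoint pattern
#'
#' Fits \code{\link{fit_gene_model}} for every gene shared by the expression
#' and breakpoint matrices, for each requested model family (with and
#' without the CNA covariate). q-values are computed within each
#' (window, model) family over the status = ok genes only.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param bp Gene-by-sample breakpoint matrix from
#'   \code{\link{build_bp_matrix}}.
#' @param annot Sample annotation (sample_id, cancer_type).
#' @param cna Optional gene-by-sample CNA matrix (required for the
#'   type_plus_cna family; genes must cover the screened set).
#' @param config \code{\link{sv_config}}.
#' @param models Model families to fit.
#' @param window_label Label recorded in the window column (defaults to the
#'   breakpoint matrix's window attribute, with "_wt" appended when
#'   weighted).
#' @return Data frame: gene_id, window, model, beta_sv, t_stat, p_value,
#'   q_value, n_altered, status, significant.
#' @export
run_association_screen <- function(expr, bp, annot, cna = NULL,
                                   config = sv_config(),
                                   models = c("type_only", "type_plus_cna"),
                                   window_label = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if ("type_plus_cna" %in% models && is.null(cna))
    stop("type_plus_cna model requested but no CNA matrix supplied")
  if (is.null(window_label)) {
    window_label <- attr(bp, "window")
    if (is.null(window_label)) window_label <- "window"
    if (isTRUE(attr(bp, "weighted")))
      window_label <- paste0(window_label, "_wt")
  }
  samples <- intersect(colnames(expr), colnames(bp))
  samples <- intersect(samples, annot$sample_id)
  if (!is.null(cna)) samples <- intersect(samples, colnames(cna))
  if (length(samples) < 2) stop("fewer than 2 samples shared across inputs")
  genes <- intersect(rownames(expr), rownames(bp))
  if (length(genes) == 0) stop("no genes shared between expression and breakpoint matrices")
  if (!is.null(cna) && !all(genes %in% rownames(cna)))
    stop("CNA matrix does not cover all screened genes")

  ct <- annot$cancer_type[match(samples, annot$sample_id)]
  expr <- expr[genes, samples, drop = FALSE]
  bp <- bp[genes, samples, drop = FALSE]
  if (!is.null(cna)) cna <- cna[genes, samples, drop = FALSE]

  out <- vector("list", length(models))
  names(out) <- models
  for (mod in models) {
    rows <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      rows[[i]] <- fit_gene_model(
        expr[i, ], bp[i, ], ct,
        cna_row = if (mod == "type_plus_cna") cna[i, ] else NULL,
        min_altered = config$min_altered_samples
      )
    }
    tab <- do.call(rbind, rows)
    tab <- cbind(data.frame(gene_id = genes, window = window_label,
                            model = mod, stringsAsFactors = FALSE), tab)
    ok <- tab$status == "ok"
    tab$q_value <- NA_real_
    if (any(ok)) tab$q_value[ok] <- as.numeric(storey_qvalues(tab$p_value[ok]))
    tab$significant <- !is.na(tab$q_value) & tab$q_value < config$fdr_threshold
    out[[mod]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sided Fisher's exact test for gene-set overlap
#'
#' Upper-tail hypergeometric probability P(X >= n_overlap) for the overlap
#' of two gene sets drawn from a common universe.
#'
#' @param n_universe Universe size.
#' @param set_a,set_b Sizes of the two sets.
#' @param n_overlap Observed overlap.
#' @return One-sided p-value.
#' @export
overlap_fisher <- function(n_universe, set_a, set_b, n_overlap) {
  if (any(c(n_universe, set_a, set_b, n_overlap) < 0) ||
      set_a > n_universe || set_b > n_universe ||
      n_overlap > min(set_a, set_b))
    stop("inconsistent overlap counts")
  stats::phyper(n_overlap - 1, set_a, n_universe - set_a, set_b,
                lower.tail = FALSE)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One degree of freedom, no continuity correction.
#'
#' @param tab 2x2 numeric matrix or table.
#' @return List with statistic, df, p_value, table.
#' @export
chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("chisq_2x2 expects a 2x2 table")
  if (any(tab < 0)) stop("negative cell count")
  n <- sum(tab)
  rm <- rowSums(tab); cm <- colSums(tab)
  if (any(rm == 0) || any(cm == 0)) {
    stat <- NA_real_; p <- NA_real_
  } else {
    stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      (rm[1] * rm[2] * cm[1] * cm[2])
    stat <- unname(stat)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, df = 1L, p_value = p, table = tab)
}

#' Per-gene expression z-scores against the cross-sample median
#'
#' z = (expression - gene median) / gene SD, the construction behind the
#' 0.4 SD over-expression rule.
#'
#' @param expr Gene-by-sample expression matrix.
#' @return Matrix of z-scores (rows with zero SD become NA).
#' @export
expr_zscores <- function(expr) {
  med <- apply(expr, 1, stats::median, na.rm = TRUE)
  sd <- apply(expr, 1, stats::sd, na.rm = TRUE)
  sd[sd == 0] <- NA_real_
  (expr - med) / sd
}

#' Flag associations whose sample over-expresses the gene
#'
#' An association is in the over-expressed group when its gene belongs to
#' \code{sig_genes} (e.g. q < 0.10 in the screen) and the harboring sample's
#' expression z-score exceeds the configured threshold.
#'
#' @param assocs Data frame with gene_id and sample_id columns (associations
#'   or mechanism calls).
#' @param expr Expression matrix.
#' @param sig_genes Character vector of significant gene ids.
#' @param threshold Over-expression z threshold (default 0.4).
#' @return Logical vector along the rows of \code{assocs}.
#' @export
overexpressed_flags <- function(assocs, expr, sig_genes, threshold = 0.4) {
  z <- expr_zscores(expr)
  gi <- match(assocs$gene_id, rownames(z))
  si <- match(assocs$sample_id, colnames(z))
  zi <- ifelse(is.na(gi) | is.na(si), NA_real_, z[cbind(gi, si)])
  assocs$gene_id %in% sig_genes & !is.na(zi) & zi > threshold
}
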