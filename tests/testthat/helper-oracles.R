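# Independent brute-force oracles and random-instance generators.
# These deliberately re-derive every quantity with naive loops and
# closed-form algebra, sharing no code path with the package internals.

# interval conventions: 0-based half-open everywhere
o_point_in <- function(pos, s, e) pos >= s & pos < e

o_window <- function(gene, window, up = 1e5, flank = 1e6) {
  if (window == "body") c(gene$start, gene$end)
  else if (window == "flank1mb") c(max(0, gene$start - flank), gene$end + flank)
  else if (window == "up100k") {
    if (gene$strand == "+") c(max(0, gene$start - up), gene$start)
    else c(gene$end, gene$end + up)
  } else {
    if (gene$strand == "+") c(gene$end, gene$end + up)
    else c(max(0, gene$start - up), gene$start)
  }
}

o_dist <- function(pos, s, e) {
  if (pos >= s && pos < e) 0 else min(abs(pos - s), abs(pos - e))
}

# brute-force gene x sample breakpoint matrix via a triple loop
o_build_matrix <- function(genes, svs, window, samples,
                           weighted = FALSE, flank = 1e6) {
  m <- matrix(0, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  for (g in seq_len(nrow(genes))) {
    w <- o_window(genes[g, ], window)
    for (r in seq_len(nrow(svs))) {
      if (!(svs$sample_id[r] %in% samples)) next
      s <- match(svs$sample_id[r], samples)
      for (bp in list(c(svs$chrom1[r], svs$pos1[r]),
                      c(svs$chrom2[r], svs$pos2[r]))) {
        if (bp[1] != genes$chrom[g]) next
        pos <- as.numeric(bp[2])
        if (o_point_in(pos, w[1], w[2])) {
          if (weighted) {
            wt <- 1 - o_dist(pos, genes$start[g], genes$end[g]) / flank
            m[g, s] <- max(m[g, s], wt)
          } else {
            m[g, s] <- 1
          }
        }
      }
    }
  }
  m
}

# brute-force OLS by normal equations
o_ols <- function(X, y, coef_idx) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * solve(xtx)[coef_idx, coef_idx])
  t <- beta[coef_idx] / se
  list(beta = beta[coef_idx], t = t, p = 2 * pt(-abs(t), df), df = df)
}

# brute-force TAD classification
o_classify <- function(sv, tads) {
  find <- function(chrom, pos) {
    hit <- which(tads$chrom == chrom & pos >= tads$start & pos < tads$end)
    if (length(hit) == 0) return(NA_integer_)
    hit[which.min(tads$end[hit] - tads$start[hit])]
  }
  t1 <- find(sv$chrom1, sv$pos1)
  t2 <- find(sv$chrom2, sv$pos2)
  if (is.na(t1) || is.na(t2)) "unassigned"
  else if (t1 == t2) "preserving" else "disrupting"
}

# brute-force hijack evaluation of one distal association
o_hijack <- function(bp_pos, tss, mate_chrom, mate_pos, gene, enhancers,
                     scan = 1e6, max_dist = 5e5) {
  pdist <- function(p, s, e) max(0, s - p, p - e)
  d1 <- abs(bp_pos - tss)
  enh <- enhancers[enhancers$chrom == mate_chrom, , drop = FALSE]
  d2 <- Inf
  if (nrow(enh) > 0) {
    dd <- mapply(pdist, mate_pos, enh$start, enh$end)
    dd <- dd[dd <= scan]
    if (length(dd) > 0) d2 <- min(dd)
  }
  # native upstream scan
  enh_g <- enhancers[enhancers$chrom == gene$chrom, , drop = FALSE]
  d_nat <- Inf
  if (nrow(enh_g) > 0) {
    for (i in seq_len(nrow(enh_g))) {
      s <- enh_g$start[i]; e <- enh_g$end[i]
      upstream <- if (gene$strand == "+") s <= tss && e > tss - scan
                  else e > tss && s < tss + scan
      if (upstream) d_nat <- min(d_nat, pdist(tss, s, e))
    }
  }
  d_new <- d1 + d2
  list(d2 = d2, d_new = d_new, d_native = d_nat,
       is_event = is.finite(d2) && d_new <= max_dist && d_new < d_nat)
}

# random small instances -------------------------------------------------

rand_genes <- function(n, chroms = c("chr1", "chr2"), span = 5e6) {
  start <- floor(runif(n, 1e5, span))
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + floor(runif(n, 5e3, 1e5)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

rand_svs <- function(n, samples, chroms = c("chr1", "chr2"), span = 6e6) {
  data.frame(
    sv_id = sprintf("sv%03d", seq_len(n)),
    sample_id = sample(samples, n, replace = TRUE),
    chrom1 = sample(chroms, n, replace = TRUE),
    pos1 = floor(runif(n, 0, span)),
    chrom2 = sample(chroms, n, replace = TRUE),
    pos2 = floor(runif(n, 0, span)),
    sv_type = NA_character_,
    stringsAsFactors = FALSE
  )
}

rand_bed <- function(n, chroms = c("chr1", "chr2"), span = 6e6,
                     min_w = 1e3, max_w = 5e5) {
  s <- floor(runif(n, 0, span))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + floor(runif(n, min_w, max_w)),
             name = sprintf("iv%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}
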