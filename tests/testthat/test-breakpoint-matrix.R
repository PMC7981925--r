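test_that("window intervals are strand-aware and clipped at the origin", {
  g_plus <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                       end = 20000, strand = "+")
  g_minus <- g_plus; g_minus$strand <- "-"

  up_p <- window_interval(g_plus, "up100k")
  expect_equal(c(up_p$start, up_p$end), c(0, 10000))  # clipped at origin
  up_m <- window_interval(g_minus, "up100k")
  expect_equal(c(up_m$start, up_m$end), c(20000, 120000))  # mirrored
  dn_m <- window_interval(g_minus, "down100k")
  expect_equal(c(dn_m$start, dn_m$end), c(0, 10000))

  g2 <- data.frame(gene_id = "g2", chrom = "chr2", start = 5e6,
                   end = 5.01e6, strand = "+")
  fl <- window_interval(g2, "flank1mb")
  expect_equal(c(fl$start, fl$end), c(4e6, 6.01e6))
})

test_that("distance weights decay linearly and reject out-of-window distances", {
  expect_equal(breakpoint_weight(0, 1e6), 1)
  expect_equal(breakpoint_weight(1e6, 1e6), 0)
  expect_equal(breakpoint_weight(250000, 1e6), 0.75)
  # monotone decrease over a grid
  d <- seq(0, 1e6, length.out = 101)
  expect_true(all(diff(breakpoint_weight(d, 1e6)) < 0))
  expect_error(breakpoint_weight(1e6 + 1, 1e6), "exceeds")
})

test_that("body vs upstream membership follows the half-open windows", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                      end = 20000, strand = "+")
  svs <- data.frame(sv_id = c("a", "b"), sample_id = c("S1", "S2"),
                    chrom1 = "chr1", pos1 = c(15000, 9000),
                    chrom2 = "chr9", pos2 = c(1, 2), sv_type = NA)
  body <- build_bp_matrix(genes, svs, "body", samples = c("S1", "S2"))
  up <- build_bp_matrix(genes, svs, "up100k", samples = c("S1", "S2"))
  expect_equal(unname(body["g1", ]), c(1, 0))
  expect_equal(unname(up["g1", ]), c(0, 1))
})

test_that("matrix construction matches the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:30) {
    genes <- rand_genes(20)
    samples <- sprintf("S%02d", 1:8)
    svs <- rand_svs(60, samples)
    for (window in region_windows) {
      m <- build_bp_matrix(genes, svs, window, samples = samples)
      o <- o_build_matrix(genes, svs, window, samples)
      expect_equal(unclass(m)[, ], o, info = paste("window", window, "rep", rep))
    }
    mw <- build_bp_matrix(genes, svs, "flank1mb", samples = samples,
                          weighted = TRUE)
    ow <- o_build_matrix(genes, svs, "flank1mb", samples, weighted = TRUE)
    expect_equal(unclass(mw)[, ], ow, tolerance = 1e-12)
    # unweighted entry 1 <=> weighted entry > 0, except exact-edge weight 0
    mu <- build_bp_matrix(genes, svs, "flank1mb", samples = samples)
    expect_true(all(mu[mw > 0] == 1))
  }
})

test_that("matrix is invariant to SV row order and nonzero counts grow with window size", {
  set.seed(7)
  genes <- rand_genes(15)
  samples <- sprintf("S%02d", 1:6)
  svs <- rand_svs(40, samples)
  m1 <- build_bp_matrix(genes, svs, "flank1mb", samples = samples)
  m2 <- build_bp_matrix(genes, svs[sample(nrow(svs)), ], "flank1mb",
                        samples = samples)
  expect_equal(m1, m2)

  small <- build_bp_matrix(genes, svs, "flank1mb",
                           config = sv_config(window_flank = 2e5),
                           samples = samples)
  big <- build_bp_matrix(genes, svs, "flank1mb",
                         config = sv_config(window_flank = 1e6),
                         samples = samples)
  expect_true(all(rowSums(big > 0) >= rowSums(small > 0)))
})

test_that("empty gene set or cohort is a hard error; zero-SV samples keep columns", {
  genes <- rand_genes(3)
  svs <- rand_svs(5, "S1")
  expect_error(build_bp_matrix(genes[0, ], svs), "empty gene set")
  expect_error(build_bp_matrix(genes, svs[0, ]), "empty sample cohort")
  m <- build_bp_matrix(genes, svs, samples = c("S1", "S_quiet"))
  expect_true("S_quiet" %in% colnames(m))
  expect_equal(unname(m[, "S_quiet"]), rep(0, 3))
})

test_that("associations pick the breakpoint closest to the TSS and flag distal mates", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1e6,
                      end = 1.02e6, strand = "+")
  # two in-window breakpoints at 5 kb and 80 kb from the TSS (same sample)
  svs <- data.frame(sv_id = c("near", "far"), sample_id = "S1",
                    chrom1 = "chr1", pos1 = c(1e6 - 5e3, 1e6 - 8e4),
                    chrom2 = c("chr1", "chr2"), pos2 = c(1.5e6, 5e5),
                    sv_type = NA)
  a <- gene_sv_associations(genes, svs, "flank1mb", samples = "S1")
  expect_equal(nrow(a), 1)
  expect_equal(a$sv_id, "near")
  expect_equal(a$tss_distance, 5e3)
  # mate at chr1:1.5e6 is inside the gene's 1 Mb flank -> not distal
  expect_false(a$mate_is_distal)

  # translocation mate on another chromosome is distal
  svs2 <- data.frame(sv_id = "t1", sample_id = "S1", chrom1 = "chr1",
                     pos1 = 1e6 - 5e3, chrom2 = "chr7", pos2 = 1e6,
                     sv_type = NA)
  a2 <- gene_sv_associations(genes, svs2, "flank1mb", samples = "S1")
  expect_true(a2$mate_is_distal)
})

test_that("association distances respect the window bound and one row per gene-sample", {
  set.seed(11)
  genes <- rand_genes(12)
  samples <- sprintf("S%02d", 1:5)
  svs <- rand_svs(50, samples)
  a <- gene_sv_associations(genes, svs, "flank1mb", samples = samples)
  expect_true(all(a$distance_to_gene <= 1e6))
  expect_false(any(duplicated(a[c("gene_id", "sample_id")])))
  # every association corresponds to a nonzero matrix entry and vice versa
  m <- build_bp_matrix(genes, svs, "flank1mb", samples = samples)
  nz <- which(m > 0, arr.ind = TRUE)
  keys_m <- paste(rownames(m)[nz[, 1]], colnames(m)[nz[, 2]])
  keys_a <- paste(a$gene_id, a$sample_id)
  expect_setequal(keys_m, keys_a)
})
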