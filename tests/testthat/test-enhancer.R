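test_that("native enhancer distances follow the upstream scan and edge convention", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr3"),
                      start = c(1e6, 2e6, 1e6), end = c(1.1e6, 2.1e6, 1.1e6),
                      strand = c("+", "-", "+"))
  enh <- data.frame(chrom = "chr1",
                    start = c(1e6 - 11e3, 2.2e6), end = c(1e6 - 1e4, 2.201e6),
                    name = c("e1", "e2"))
  d <- native_enhancer_distance(genes, enh)
  expect_equal(unname(d["g1"]), 1e4)        # enhancer ends 10 kb upstream
  expect_equal(unname(d["g2"]), 1e5)        # minus strand: upstream is rightward of TSS at end
  expect_equal(unname(d["g3"]), Inf)        # no enhancer on the chromosome

  # enhancer overlapping the TSS clamps to zero
  enh0 <- data.frame(chrom = "chr1", start = 1e6 - 500, end = 1e6 + 500,
                     name = "e0")
  expect_equal(unname(native_enhancer_distance(genes[1, ], enh0)["g1"]), 0)
})

test_that("hijack calls follow the d_new geometry and native comparison", {
  gene <- data.frame(gene_id = "g1", chrom = "chr1", start = 5e6,
                     end = 5.02e6, strand = "+")
  # bp1 100 kb upstream of the TSS; mate on chr2, enhancer 50 kb away
  svs <- data.frame(sv_id = "sv1", sample_id = "S1", chrom1 = "chr1",
                    pos1 = 5e6 - 1e5, chrom2 = "chr2", pos2 = 3e6,
                    sv_type = NA)
  a <- gene_sv_associations(gene, svs, "flank1mb", samples = "S1")
  enh <- data.frame(chrom = "chr2", start = 3e6 + 5e4, end = 3e6 + 5.1e4,
                    name = "donor")
  calls <- call_hijacks(a, gene, enh)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$d_bp1_to_tss, 1e5)
  expect_equal(calls$d_bp2_to_enh, 5e4)
  expect_equal(calls$d_new, 1.5e5)
  expect_true(calls$is_event)

  # a native enhancer at 80 kb upstream beats d_new = 150 kb
  enh2 <- rbind(enh, data.frame(chrom = "chr1", start = 5e6 - 8.1e4,
                                end = 5e6 - 8e4, name = "native"))
  calls2 <- call_hijacks(a, gene, enh2)
  expect_equal(calls2$d_native, 8e4)
  expect_false(calls2$is_event)

  # non-distal mates emit no call
  svs3 <- data.frame(sv_id = "sv3", sample_id = "S1", chrom1 = "chr1",
                     pos1 = 5e6 - 1e5, chrom2 = "chr1", pos2 = 5.5e6,
                     sv_type = NA)
  a3 <- gene_sv_associations(gene, svs3, "flank1mb", samples = "S1")
  expect_false(a3$mate_is_distal)
  expect_equal(nrow(call_hijacks(a3, gene, enh)), 0)
})

test_that("hijack calls match a brute-force all-pairs scan on random instances", {
  set.seed(21)
  for (rep in 1:25) {
    genes <- rand_genes(10)
    samples <- sprintf("S%02d", 1:5)
    svs <- rand_svs(30, samples)
    enh <- rand_bed(25, min_w = 500, max_w = 2e3)
    a <- gene_sv_associations(genes, svs, "flank1mb", samples = samples)
    calls <- call_hijacks(a, genes, enh)
    dist_rows <- a[a$mate_is_distal, ]
    expect_equal(nrow(calls), nrow(dist_rows))
    tss <- gene_tss(genes)
    for (i in seq_len(nrow(calls))) {
      r <- calls[i, ]
      ar <- dist_rows[i, ]
      g <- genes[genes$gene_id == r$gene_id, ]
      o <- o_hijack(ar$bp_pos, tss[match(r$gene_id, genes$gene_id)],
                    ar$mate_chrom, ar$mate_pos, g, enh)
      expect_equal(r$d_bp2_to_enh, o$d2)
      expect_equal(r$d_native, o$d_native)
      expect_equal(r$is_event, o$is_event)
    }
  }
})

test_that("events are invariant to enhancer order and monotone in hijack_max_dist", {
  set.seed(22)
  genes <- rand_genes(8)
  samples <- sprintf("S%02d", 1:4)
  svs <- rand_svs(25, samples)
  enh <- rand_bed(20, min_w = 500, max_w = 2e3)
  a <- gene_sv_associations(genes, svs, "flank1mb", samples = samples)
  c1 <- call_hijacks(a, genes, enh)
  c2 <- call_hijacks(a, genes, enh[sample(nrow(enh)), ])
  expect_equal(c1$is_event, c2$is_event)
  expect_equal(c1$d_bp2_to_enh, c2$d_bp2_to_enh)
  # every event satisfies its defining predicate
  ev <- c1[c1$is_event, ]
  expect_true(all(ev$d_bp2_to_enh <= 5e5))
  expect_true(all(ev$d_new <= 5e5 & ev$d_new < ev$d_native))
  # shrinking the distance cap never adds events
  tight <- call_hijacks(a, genes, enh, sv_config(hijack_max_dist = 1e5))
  expect_true(all(tight$is_event <= c1$is_event))
})

test_that("hijack enrichment is 1 on balanced groups and detects planted mechanism", {
  calls <- data.frame(is_event = rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 15, 5, 15)))
  over <- rep(c(TRUE, FALSE), each = 20)
  enr <- hijack_enrichment(calls, over)
  expect_equal(enr$p_value, 1)

  co <- simulate_cohort(preset_sim_config("hijack", seed = 606,
                                          n_genes = 200, n_samples = 100))
  scr <- run_association_screen(co$expr, co$bp_matrix, co$sample_annot,
                                co$cna, models = "type_plus_cna")
  sig <- scr$gene_id[scr$significant & scr$t_stat > 0]
  a <- gene_sv_associations(co$genes, co$svs, "flank1mb",
                            samples = co$sample_annot$sample_id)
  calls <- call_hijacks(a, co$genes, co$enhancers)
  enr <- hijack_enrichment(calls, overexpressed_flags(calls, co$expr, sig))
  expect_lt(enr$p_value, 0.01)
})
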