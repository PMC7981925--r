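test_that("per-gene OLS matches an independent normal-equations solver", {
  set.seed(101)
  for (rep in 1:25) {
    n <- 40
    ct <- sample(c("lung", "breast"), n, replace = TRUE)
    sv <- rbinom(n, 1, 0.3)
    cna <- rnorm(n)
    y <- 0.5 + 1.2 * sv + 0.4 * (ct == "lung") + 0.7 * cna + rnorm(n)
    fit <- fit_gene_model(y, sv, ct, cna)
    X <- cbind(1, sv, ct == "lung", cna)
    o <- o_ols(X, y, 2)
    expect_equal(fit$beta_sv, o$beta, tolerance = 1e-8)
    expect_equal(fit$t_stat, o$t, tolerance = 1e-8)
    expect_equal(fit$p_value, o$p, tolerance = 1e-8)
    expect_equal(fit$df, o$df)
  }
})

test_that("planted signal yields a large positive t; degenerate rows are skipped", {
  set.seed(5)
  n <- 60
  sv <- rbinom(n, 1, 0.4)
  y <- 2 * sv + rnorm(n, sd = 1e-4)
  fit <- fit_gene_model(y, sv, rep("one_type", n))
  expect_equal(fit$status, "ok")
  expect_gt(fit$t_stat, 100)
  expect_lt(fit$p_value, 1e-20)

  expect_equal(fit_gene_model(y, rep(0, n), rep("t", n))$status,
               "skipped_constant")
  expect_equal(fit_gene_model(rep(NA_real_, n), sv, rep("t", n))$status,
               "skipped_constant")
  one_alt <- c(1, rep(0, n - 1))
  expect_equal(fit_gene_model(y, one_alt, rep("t", n),
                              min_altered = 3)$status, "skipped_min_alt")
  expect_error(fit_gene_model(y[-1], sv, rep("t", n)), "align")
})

test_that("missing values drop samples for that gene only", {
  set.seed(6)
  n <- 50
  sv <- rbinom(n, 1, 0.5)
  y <- 1.5 * sv + rnorm(n)
  y[1:5] <- NA
  fit <- fit_gene_model(y, sv, rep("t", n))
  keep <- !is.na(y)
  o <- o_ols(cbind(1, sv[keep]), y[keep], 2)
  expect_equal(fit$beta_sv, o$beta, tolerance = 1e-8)
  expect_equal(fit$n_altered, sum(sv[keep] != 0))
})

test_that("Storey q-values: closed forms, BH equivalence, and uniform-p pi0", {
  # all p equal: q = pi0 * p for every gene
  p <- rep(0.02, 10)
  q <- storey_qvalues(p, pi0 = 0.8)
  expect_equal(as.numeric(q), rep(0.8 * 0.02, 10))

  # pi0 forced to 1 reproduces BH exactly
  set.seed(8)
  p <- c(runif(500), rbeta(100, 0.2, 5))
  expect_equal(as.numeric(storey_qvalues(p, pi0 = 1)),
               p.adjust(p, "BH"), tolerance = 1e-12)

  # uniform p: pi0 estimates concentrate near 1 (the smoother evaluated at
  # the top of the lambda grid has a few percent sampling spread)
  set.seed(9)
  pi0s <- replicate(20, attr(storey_qvalues(runif(2000)), "pi0"))
  expect_true(all(pi0s >= 0.85 & pi0s <= 1.0))
  expect_gte(median(pi0s), 0.9)

  # monotone in p, capped at 1
  set.seed(10)
  p <- runif(300)
  q <- as.numeric(storey_qvalues(p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))

  expect_error(storey_qvalues(c(0.5, 0)), "0, 1")
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("overlap_fisher upper tail agrees with direct hypergeometric sums", {
  # complete overlap of a small set: closed-form product of ratios
  p <- overlap_fisher(30, 5, 10, 5)
  direct <- prod((10 - 0:4) / (30 - 0:4))
  expect_equal(p, direct, tolerance = 1e-12)
  # observed equal to expectation: central p-value
  p_mid <- overlap_fisher(100, 50, 50, 25)
  expect_gt(p_mid, 0.4)
  expect_lt(p_mid, 0.65)
  # cross-check against stats::fisher.test one-sided
  ft <- fisher.test(matrix(c(25, 25, 25, 25), 2), alternative = "greater")
  expect_equal(p_mid, ft$p.value, tolerance = 1e-10)
  expect_error(overlap_fisher(100, 50, 50, 51), "inconsistent")
})

test_that("chi-squared 2x2 is Pearson with 1 df and no continuity correction", {
  expect_equal(chisq_2x2(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  res <- chisq_2x2(matrix(c(30, 10, 10, 30), 2))
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE))
  # matches stats::chisq.test without correction on random tables
  set.seed(12)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    mine <- chisq_2x2(tab)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("screen recovers planted effects and the CNA covariate matters", {
  set.seed(13)
  co <- simulate_cohort(preset_sim_config("signal", seed = 303,
                                          n_genes = 150, n_samples = 80))
  scr <- run_association_screen(co$expr, co$bp_matrix, co$sample_annot,
                                co$cna)
  expect_setequal(unique(scr$model), c("type_only", "type_plus_cna"))
  s <- scr[scr$model == "type_plus_cna", ]
  eff <- co$truth$gene_id[co$truth$is_effect]
  rec <- s$gene_id[s$significant & s$t_stat > 0]
  expect_gt(length(intersect(rec, eff)) / length(eff), 0.8)

  # q-values computed within each family over ok genes only
  for (mod in unique(scr$model)) {
    fam <- scr[scr$model == mod & scr$status == "ok", ]
    expect_equal(fam$q_value,
                 as.numeric(storey_qvalues(fam$p_value)), tolerance = 1e-12)
  }
  expect_true(all(is.na(scr$q_value[scr$status != "ok"])))
})

test_that("CNA-confounded cohorts lose significance under the corrected model", {
  co <- simulate_cohort(preset_sim_config("signal", seed = 404,
                                          n_genes = 200, n_samples = 100,
                                          cna_confounding_strength = 1.5))
  scr <- run_association_screen(co$expr, co$bp_matrix, co$sample_annot,
                                co$cna)
  n_un <- sum(scr$significant[scr$model == "type_only"])
  n_corr <- sum(scr$significant[scr$model == "type_plus_cna"])
  expect_gt(n_un, n_corr)
})

test_that("permuting breakpoint sample labels destroys planted significance", {
  co <- simulate_cohort(preset_sim_config("signal", seed = 505,
                                          n_genes = 120, n_samples = 80))
  eff <- co$truth$gene_id[co$truth$is_effect]
  set.seed(99)
  meds <- replicate(5, {
    bp_perm <- co$bp_matrix[, sample(ncol(co$bp_matrix))]
    colnames(bp_perm) <- colnames(co$bp_matrix)
    scr <- run_association_screen(co$expr, bp_perm, co$sample_annot,
                                  models = "type_only")
    median(scr$p_value[scr$gene_id %in% eff & scr$status == "ok"])
  })
  expect_gt(median(meds), 0.3)
})
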