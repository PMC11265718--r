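test_that("CDS summaries pool counts on both strands and ignore intronic sites", {
  ann <- toy_annotation()
  # two CG sites in CDS (one minus-strand), one CG in the intron, one CHG in CDS
  allc <- make_allc("chr1", c(20, 250, 150, 60), c("+", "-", "+", "+"),
                    c("CGA", "CGT", "CGA", "CAG"),
                    mc = c(2, 3, 5, 1), cov = c(4, 6, 5, 5),
                    called = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_gene_cds(allc, ann)
  expect_equal(s$weighted_mCG, (2 + 3) / (4 + 6))  # intronic site not counted
  expect_equal(s$n_sites_CG, 2L)                    # minus-strand site counted
  expect_equal(s$n_meth_CG, 2L)
  expect_equal(s$n_sites_CHG, 1L)
  expect_equal(s$n_meth_CHG, 0L)
  expect_equal(s$n_cg_total, 2L)
  # sub-threshold coverage keeps a site out of n_sites but in n_cg_total
  allc2 <- make_allc("chr1", c(20, 30), "+", "CGA", c(2, 1), c(4, 2),
                     called = c(TRUE, NA))
  s2 <- summarize_gene_cds(allc2, ann)
  expect_equal(s2$n_cg_total, 2L)
  expect_equal(s2$n_cg_covered, 1L)
  expect_equal(s2$n_cg_cov1, 2L)
  expect_equal(s2$n_sites_CG, 1L)
})

test_that("background probability pools methylated over eligible sites across genes", {
  summ <- data.table(gene_id = c("a", "b"),
                     n_sites_CG = c(50L, 50L), n_meth_CG = c(10L, 30L),
                     n_sites_CHG = c(10L, 10L), n_meth_CHG = c(0L, 1L),
                     n_sites_CHH = c(10L, 10L), n_meth_CHH = c(0L, 0L))
  bg <- estimate_background(summ)
  expect_equal(unname(bg$p_bg["CG"]), 0.4)
  expect_equal(unname(bg$p_bg["CHG"]), 0.05)
  # permutation invariance
  bg2 <- estimate_background(summ[2:1])
  expect_equal(bg$p_bg, bg2$p_bg)
  # a context with zero eligible sites is an error
  summ0 <- copy(summ)[, n_sites_CHH := 0L]
  expect_error(estimate_background(summ0), "no eligible CHH")
})

make_summary <- function(gene_id = "g", n_cg_total = 25L, n_cg_cov1 = 25L,
                         n_cg_covered = 25L, cg = c(20L, 25L),
                         chg = c(0L, 20L), chh = c(0L, 40L)) {
  data.table(gene_id = gene_id, n_cg_total = n_cg_total,
             n_cg_cov1 = n_cg_cov1, n_cg_covered = n_cg_covered,
             n_meth_CG = cg[1], n_sites_CG = cg[2],
             n_meth_CHG = chg[1], n_sites_CHG = chg[2],
             n_meth_CHH = chh[1], n_sites_CHH = chh[2],
             weighted_mCG = NA_real_, weighted_mCHG = NA_real_,
             weighted_mCHH = NA_real_)
}

test_that("gbM labels require elevated mCG, quiet non-CG, 20 CG sites and 40% coverage", {
  bg <- structure(list(p_bg = c(CG = 0.15, CHG = 0.01, CHH = 0.01),
                       scope = "CDS"), class = "background_model")
  # 20/25 methylated CG vs background 0.15, no non-CG methylation -> gbM
  cls <- classify_gbm(make_summary(), bg)
  expect_equal(cls$label, "gbM")
  expect_lt(cls$p_CG, 1e-10)
  expect_equal(cls$q_CHG, 1)   # zero methylated -> upper tail = 1
  expect_equal(cls$q_CHH, 1)
  # fewer than 20 covered CG sites: never gbM however methylated
  cls10 <- classify_gbm(make_summary(n_cg_total = 10L, n_cg_cov1 = 10L,
                                     n_cg_covered = 10L, cg = c(10L, 10L)), bg)
  expect_equal(cls10$label, "non-gbM")
  # 39 of 100 CG sites covered at >= 3 reads: below 40% -> unclassified
  cls39 <- classify_gbm(make_summary(n_cg_total = 100L, n_cg_cov1 = 90L,
                                     n_cg_covered = 39L, cg = c(30L, 39L)), bg)
  expect_equal(cls39$label, "unclassified")
  cls40 <- classify_gbm(make_summary(n_cg_total = 100L, n_cg_cov1 = 90L,
                                     n_cg_covered = 40L, cg = c(35L, 40L)), bg)
  expect_equal(cls40$label, "gbM")
  # significant mCHG forfeits gbM and sets the teM-like annotation
  clste <- classify_gbm(make_summary(chg = c(15L, 20L)), bg)
  expect_equal(clste$label, "non-gbM")
  expect_true(clste$tem_like)
})

test_that("gbM ratio excludes unclassified genes from the denominator", {
  labs <- c(rep("gbM", 300), rep("non-gbM", 700), rep("unclassified", 500))
  expect_equal(gbm_ratio(labs), 0.30)
  expect_equal(gbm_ratio(sample(labs)), 0.30)  # order invariant
  expect_true(is.na(gbm_ratio(rep("unclassified", 10))))  # missing, not 0
})

test_that("planted gbM genes are recovered with high sensitivity and low false-positive rate", {
  cfg <- sim_config(seed = 21, n_genes = 600L, gbm_fraction = 0.3)
  sp <- simulate_gbm_species(cfg)
  called <- call_methylome(sp$allc, estimate_nonconversion(sp$allc, "ctrl"))
  summ <- summarize_gene_cds(called, sp$annotation)
  cls <- classify_gbm(summ, estimate_background(summ))
  tt <- merge(cls[, .(gene_id, label)], sp$truth_genes, by = "gene_id")
  expect_gte(tt[compartment == "gbM", mean(label == "gbM")], 0.95)
  expect_lte(tt[compartment == "background", mean(label == "gbM")], 0.01)
  f_hat <- gbm_ratio(cls)
  expect_lt(abs(f_hat - tt[, mean(compartment == "gbM")]), 0.03)
})
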