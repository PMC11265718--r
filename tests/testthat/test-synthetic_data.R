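test_that("generators are pure functions of their config", {
  cfg <- sim_config(seed = 13, seq_n_genes = 15L, n_genes = 50L,
                    n_clean_long_introns = 2L, n_accessions = 4L,
                    n_ibm1_like = 1L, n_ectopic_per_ibm1 = 5L,
                    base_ectopic_max = 3L, n_control_sites = 500L,
                    n_pairs = 100L)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$annotation$exons, g2$annotation$exons)
  m1 <- simulate_methylome(g1); m2 <- simulate_methylome(g2)
  expect_identical(m1$allc, m2$allc)
  p1 <- simulate_panel(cfg); p2 <- simulate_panel(cfg)
  expect_identical(p1$truth_ectopic, p2$truth_ectopic)
  expect_identical(panel_accession_allc(p1, "acc002"),
                   panel_accession_allc(p2, "acc002"))
  expect_identical(simulate_cwg(cfg)$allc, simulate_cwg(cfg)$allc)
  expect_identical(simulate_snp_matrix(cfg)$snp, simulate_snp_matrix(cfg)$snp)
  expect_identical(simulate_abundance(cfg)$abundance,
                   simulate_abundance(cfg)$abundance)
  # generators restore the caller's RNG state
  set.seed(1); before <- .Random.seed
  invisible(simulate_genome(cfg))
  expect_identical(.Random.seed, before)
})

test_that("methylome counts match the configured model moments", {
  cfg <- sim_config(seed = 19, n_genes = 800L, n_control_sites = 60000L)
  sp <- simulate_gbm_species(cfg)
  # unmethylated control: mc rate ~ p0 within 3 standard errors
  ctrl <- sp$allc[chrom == "ctrl"]
  rate <- sum(ctrl$mc) / sum(ctrl$cov)
  se <- sqrt(cfg$p0 * (1 - cfg$p0) / sum(ctrl$cov))
  expect_lt(abs(rate - cfg$p0), 3 * se)
  # mean coverage ~ Poisson depth
  expect_lt(abs(mean(sp$allc$cov) - cfg$depth), 0.1)
  # gbM-gene CG sites near the planted level (plus non-conversion leakage)
  gb <- sp$truth_genes[compartment == "gbM", gene_id]
  idx <- sp$annotation$genes[gene_id %in% gb]
  hitrate <- {
    setkey(idx, chrom, start, end)
    pts <- copy(sp$allc[context == "CG"])[, `:=`(start = pos, end = pos)]
    hits <- data.table::foverlaps(pts, idx[, .(chrom, start, end)],
                                  by.x = c("chrom", "start", "end"),
                                  nomatch = NULL)
    sum(hits$mc) / sum(hits$cov)
  }
  expected <- cfg$level_gbm_cg + (1 - cfg$level_gbm_cg) * cfg$p0
  expect_lt(abs(hitrate - expected), 0.01)
})

test_that("simulated genomes carry the planted structures", {
  cfg <- sim_config(seed = 23, seq_n_genes = 20L, n_te = 0L,
                    n_clean_long_introns = 2L)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$annotation$te), 0L)          # zero TEs honoured
  long <- select_long_introns(sim$annotation)
  expect_equal(nrow(long), 3L)                       # 1 sensor + 2 clean
  expect_true(sim$sensor$gene_id %in% long$gene_id)
  expect_true(all(long$length >= 1000L))
  # the control contig is present and fully unmethylated in truth
  m <- simulate_methylome(sim)
  expect_true(all(m$truth[chrom == "chrC", level] == 0))
  # degenerate depth: nothing is callable downstream
  cfg0 <- sim_config(seed = 23, seq_n_genes = 5L, n_clean_long_introns = 0L,
                     depth = 0)
  m0 <- simulate_methylome(simulate_genome(cfg0))
  expect_true(all(m0$allc$cov == 0L))
})

test_that("panel truth accounts planted ibm1-like accessions and bounds background ectopy", {
  cfg <- sim_config(seed = 29, n_genes = 300L, n_accessions = 10L,
                    n_ibm1_like = 3L, n_ectopic_per_ibm1 = 40L,
                    base_ectopic_max = 5L, n_control_sites = 2000L)
  pan <- simulate_panel(cfg)
  tr <- pan$truth_accessions
  expect_equal(sum(tr$ibm1_like), 3L)
  expect_true(all(tr[ibm1_like == TRUE, n_planted] == 40L))
  expect_true(all(tr[ibm1_like == FALSE, n_planted] <= 5L))
  expect_true(all(tr[ibm1_like == TRUE, sensor_level] == cfg$sensor_mchg_low))
  # infeasible configs rejected
  expect_error(simulate_panel(sim_config(n_accessions = 2L, n_ibm1_like = 3L)),
               "exceeds")
  # zero planted accessions -> no flags at the default threshold
  cfg0 <- sim_config(seed = 31, n_genes = 300L, n_accessions = 6L,
                     n_ibm1_like = 0L, n_ectopic_per_ibm1 = 5L,
                     base_ectopic_max = 5L, n_control_sites = 2000L)
  res0 <- analyze_panel(simulate_panel(cfg0))
  expect_false(any(res0$accessions$ibm1_like))
})

test_that("SNP and abundance generators honour degenerate settings", {
  cfg <- sim_config(seed = 37,
                    snp_rates = c(CDS = 0, methylated_intron = 0,
                                  unmethylated_intron = 0))
  sim <- simulate_snp_matrix(cfg)
  expect_equal(nrow(sim$snp$geno), 0L)
  pg <- popgen_by_region(sim$snp, sim$regions)
  expect_true(all(is.na(pg$D)))                      # S = 0 -> D missing
  expect_true(all(pg$snp_density == 0))
  ab <- simulate_abundance(sim_config(seed = 37, abund_noise_sd = 0,
                                      n_abund_genes = 50L, n_shifted = 5L))
  r <- isoform_ratio(ab$abundance, ab$pairs, ab$conditions)
  tr <- merge(r[condition == "A"], ab$truth, by = "gene_id")
  expect_equal(tr$ratio, tr$ratio_a, tolerance = 1e-12)  # zero noise: exact
})
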