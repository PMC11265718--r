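test_that("per-site level distributions apply the coverage and methylated-read filters", {
  allc <- make_allc("chr1", c(10, 20, 30, 40), "+", "CAG",
                    mc = c(2, 1, 0, 3), cov = c(3, 2, 10, 4),
                    called = c(TRUE, NA, FALSE, FALSE))
  lv <- per_site_levels(allc, context = "CHG")
  expect_setequal(round(lv$level, 4), round(c(2 / 3, 3 / 4), 4))
  # cov 2 excluded; mc 0 excluded under the default mc >= 1 rule
  expect_false(20 %in% lv$pos)
  expect_false(30 %in% lv$pos)
  # called-only mode keeps just positively called sites
  lv2 <- per_site_levels(allc, context = "CHG", inclusion = "called")
  expect_equal(lv2$pos, 10L)
  # bimodal mixture recovers both modes
  set.seed(12)
  n <- 4000L
  cov <- pmax(rpois(2 * n, 30), 3L)
  sim <- make_allc("chr1", seq_len(2 * n) * 3L, "+", "CAG",
                   rbinom(2 * n, cov, rep(c(0.9, 0.05), each = n)), cov)
  lv3 <- per_site_levels(sim)
  d <- density(lv3$level, from = 0, to = 1)
  hi <- d$x[which.max(d$y[d$x > 0.5]) + sum(d$x <= 0.5)]
  expect_lt(abs(hi - 0.9), 0.05)
})

cwg_fixture <- function() {
  # three CAG/CTG palindromic pairs + one CCG site; pair 3 under-covered
  make_allc("chr1",
            c(11, 13, 21, 23, 31, 33, 41),
            c("+", "-", "+", "-", "+", "-", "+"),
            c("CAG", "CTG", "CTG", "CAG", "CAG", "CTG", "CCG"),
            mc = c(5, 6, 5, 0, 1, 1, 5),
            cov = c(6, 8, 6, 8, 5, 2, 6),
            called = c(TRUE, TRUE, TRUE, FALSE, FALSE, NA, TRUE))
}

test_that("CWG pairing excludes CCG and under-covered strands and classifies symmetry", {
  pairs <- pair_cwg_sites(cwg_fixture())
  expect_equal(nrow(pairs), 2L)          # pair at 31 dropped (minus cov 2)
  expect_false(41 %in% pairs$pos)        # CCG never paired
  expect_equal(pairs[pos == 11, symmetry_class], "symmetric")
  expect_equal(pairs[pos == 21, symmetry_class], "plus_only")
  s <- symmetry_summary(pairs)
  expect_equal(sum(s$counts$n), 2L)
  expect_equal(sum(s$counts$fraction), 1)
  # a pair with zero methylated reads is excluded by default
  quiet <- make_allc("chr1", c(51, 53), c("+", "-"), c("CAG", "CTG"),
                     mc = 0L, cov = 10L, called = FALSE)
  expect_equal(nrow(pair_cwg_sites(rbind(cwg_fixture(), quiet))), 2L)
  expect_equal(nrow(pair_cwg_sites(rbind(cwg_fixture(), quiet),
                                   require_meth = FALSE)), 3L)
  # genome verification catches reference mismatches
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 60), collapse = "")))
  expect_error(pair_cwg_sites(cwg_fixture(), genome = genome), "mismatch")
})

test_that("strand-coupled and strand-independent regimes separate cleanly", {
  co <- simulate_cwg(sim_config(seed = 2, n_pairs = 1500L,
                                cwg_regime = "coupled", cwg_meth_prob = 0.8))
  frac <- function(sim) {
    called <- call_methylome(sim$allc, 0.005)
    s <- symmetry_summary(pair_cwg_sites(called))
    s$counts[symmetry_class == "symmetric", fraction]
  }
  expect_gte(frac(co), 0.9)
  ind <- simulate_cwg(sim_config(seed = 2, n_pairs = 1500L,
                                 cwg_regime = "independent",
                                 cwg_meth_prob = 0.3))
  expect_lt(frac(ind), 0.5)
})

test_that("metaplot windows pool correctly, obey orientation, and satisfy the pooling identity", {
  # one plus-strand and one minus-strand feature of 200 bp, flank 100
  feats <- data.table(feature_id = c("fp", "fm"), chrom = "chr1",
                      strand = c("+", "-"),
                      start = c(1001L, 2001L), end = c(1200L, 2200L))
  # fp: two sites in its first window (offsets 0 and 5 of 10-bp windows)
  allc <- make_allc("chr1", c(1001L, 1006L, 2200L, 1101L),
                    "+", "CGA", mc = c(2, 3, 4, 1), cov = c(4, 6, 4, 2))
  mp <- metaplot(allc, feats, context = "CG", n_windows = 20L, flank = 100L)
  w1 <- mp[region == "body" & window == 1]
  # fp window 1 pools (2,4) and (3,6); fm window 1 is the genomic right end
  expect_equal(w1$mc, 2 + 3 + 4)
  expect_equal(w1$weighted_level, (2 + 3 + 4) / (4 + 6 + 4))
  expect_equal(w1$mean_level, mean(c(5 / 10, 1)))
  w11 <- mp[region == "body" & window == 11]
  expect_equal(w11$mc, 1)                # site 1101 -> fp window 11
  # pooling identity: coverage-weighted mean of body windows == body level
  body <- mp[region == "body" & cov > 0]
  expect_equal(sum(body$weighted_level * body$cov) / sum(body$cov),
               sum(allc$mc) / sum(allc$cov))
  # short features are skipped with a message
  tiny <- data.table(feature_id = "t", chrom = "chr1", strand = "+",
                     start = 1L, end = 5L)
  expect_message(metaplot(allc, rbind(feats, tiny), n_windows = 20L),
                 "skipping 1")
})

test_that("metaplots of a uniform methylome are flat at the true level", {
  set.seed(5)
  n_feat <- 300L
  feats <- data.table(feature_id = sprintf("f%03d", 1:n_feat), chrom = "chr1",
                      strand = sample(c("+", "-"), n_feat, TRUE),
                      start = seq(1L, by = 4000L, length.out = n_feat) + 1000L)
  feats[, end := start + 999L]
  pos <- unlist(lapply(seq_len(n_feat), function(i)
    feats$start[i] - 1000L + sort(sample.int(3000L, 150L))))
  cov <- rpois(length(pos), 10)
  allc <- make_allc("chr1", pos, "+", "CGA", rbinom(length(pos), cov, 0.3), cov)
  mp <- metaplot(allc, feats, context = "CG")
  expect_true(all(abs(mp$weighted_level - 0.3) < 0.02, na.rm = TRUE))
  expect_equal(nrow(mp), 60L)
})
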