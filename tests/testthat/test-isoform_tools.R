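truncation_fixture <- function(strand = "+") {
  # exon1 = 40 nt (10 UTR + 30 CDS), long intron, exon2 = 60 nt
  set.seed(101)
  seq <- paste(sample(c("A", "C", "G", "T"), 1300, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  if (strand == "+") {
    exons <- data.table(gene_id = "g1", chrom = "chr1", strand = strand,
                        start = c(101L, 1141L), end = c(140L, 1200L))
    cds <- data.table(gene_id = "g1", chrom = "chr1", strand = strand,
                      start = c(111L, 1141L), end = c(140L, 1190L))
  } else {
    exons <- data.table(gene_id = "g1", chrom = "chr1", strand = strand,
                        start = c(101L, 1161L), end = c(160L, 1200L))
    cds <- data.table(gene_id = "g1", chrom = "chr1", strand = strand,
                      start = c(111L, 1161L), end = c(160L, 1190L))
  }
  ann <- genome_annotation(
    genes = data.table(gene_id = "g1", tx_id = "g1.1", chrom = "chr1",
                       strand = strand, start = 101L, end = 1200L),
    exons = exons, cds = cds)
  list(ann = ann, genome = genome)
}

test_that("truncated transcripts keep only exonic sequence 5' of the target intron", {
  fx <- truncation_fixture("+")
  tp <- make_truncated_transcript(fx$ann, "g1", 1L, fx$genome)
  expect_equal(nchar(tp$short_seq), 40L)
  expect_equal(tp$short_seq,
               as.character(Biostrings::subseq(fx$genome[["chr1"]], 101, 140)))
  expect_equal(nchar(tp$long_seq), 40L + 60L)
  expect_equal(tp$truncation_point, 40L)
  expect_equal(tp$short_tx, "g1.1.short")
  # prefix property
  expect_equal(substr(tp$long_seq, 1, nchar(tp$short_seq)), tp$short_seq)
})

test_that("minus-strand truncation matches a hand-built reverse complement", {
  fx <- truncation_fixture("-")
  tp <- make_truncated_transcript(fx$ann, "g1", 1L, fx$genome)
  # 5'-most exon of a minus-strand gene is the genomic right one (1161-1200)
  hand <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(fx$genome[["chr1"]], 1161, 1200)))
  expect_equal(tp$short_seq, hand)
  hand_long <- paste0(hand, as.character(Biostrings::reverseComplement(
    Biostrings::subseq(fx$genome[["chr1"]], 101, 160))))
  expect_equal(tp$long_seq, hand_long)
  expect_equal(substr(tp$long_seq, 1, nchar(tp$short_seq)), tp$short_seq)
})

test_that("the prefix property holds over random simulated gene models", {
  sim <- simulate_genome(sim_config(seed = 9, seq_n_genes = 50L,
                                    n_clean_long_introns = 5L))
  multi <- unique(sim$annotation$introns$gene_id)
  pairs <- lapply(multi, function(g) {
    ranks <- sim$annotation$introns[gene_id == g, intron_rank]
    make_truncated_transcript(sim$annotation, g, sample(ranks, 1), sim$genome)
  })
  for (tp in pairs) {
    expect_equal(substr(tp$long_seq, 1, nchar(tp$short_seq)), tp$short_seq)
    expect_lt(nchar(tp$short_seq), nchar(tp$long_seq))
  }
  # FASTA export round-trips through Biostrings
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcript_pairs(pairs[1:3], fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), 6L)
  expect_equal(as.character(back[[pairs[[1]]$short_tx]]), pairs[[1]]$short_seq)
})

test_that("isoform ratios average replicates per condition before dividing", {
  abund <- data.table(
    transcript_id = rep(c("t1", "t1.short"), each = 4),
    sample = rep(c("wt1", "wt2", "mu1", "mu2"), 2),
    abundance = c(1, 3, 2, 2,    # long: wt avg 2, mu avg 2
                  2, 2, 5, 7))   # short: wt avg 2, mu avg 6
  pairs <- data.table(gene_id = "g1", long_tx = "t1", short_tx = "t1.short")
  conds <- data.table(sample = c("wt1", "wt2", "mu1", "mu2"),
                      condition = c("wt", "wt", "mu", "mu"))
  r <- isoform_ratio(abund, pairs, conds)
  expect_equal(r[condition == "wt", ratio], 1)
  expect_equal(r[condition == "mu", ratio], 3)
  # zero long abundance gives a missing, not infinite, ratio
  abund0 <- copy(abund)[transcript_id == "t1" & sample %in% c("wt1", "wt2"),
                        abundance := 0]
  r0 <- isoform_ratio(abund0, pairs, conds)
  expect_true(is.na(r0[condition == "wt", ratio]))
  # a missing transcript is skipped with a message
  expect_message(
    isoform_ratio(abund[transcript_id != "t1.short"], pairs, conds),
    "skipped")
})

test_that("ratio-shift detection is strict and recovers planted shifts exactly", {
  a <- data.table(gene_id = c("g1", "g2", "g3", "g4"),
                  ratio = c(0.5, 1.0, 3.0, NA))
  b <- data.table(gene_id = c("g1", "g2", "g3", "g4"),
                  ratio = c(3.0, 3.0, 1.0, 9.0))
  got <- ratio_shift_genes(a, b)
  expect_equal(got$gene_id, "g1")        # +2.5 listed
  expect_false("g2" %in% got$gene_id)    # exactly +2: strict
  expect_false("g3" %in% got$gene_id)    # decreased
  expect_false("g4" %in% got$gene_id)    # missing ratio skipped
  # planted shifts among noisy unshifted genes, several seeds
  hits <- vapply(1:10, function(s) {
    ab <- simulate_abundance(sim_config(seed = s))
    r <- isoform_ratio(ab$abundance, ab$pairs, ab$conditions)
    sh <- ratio_shift_genes(r[condition == "A"], r[condition == "B"])
    setequal(sh$gene_id, ab$truth[shifted == TRUE, gene_id])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
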