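test_that("context classification matches brute-force enumeration of all C-initial trinucleotides", {
  bases <- c("A", "C", "G", "T")
  tris <- as.vector(outer(paste0("C", bases), bases, paste0))
  got <- classify_context(tris)
  brute <- function(t) {
    b2 <- substr(t, 2, 2); b3 <- substr(t, 3, 3)
    if (b2 == "G") c("CG", NA)
    else if (b3 == "G") c("CHG", if (b2 %in% c("A", "T")) "CWG" else "CCG")
    else c("CHH", NA)
  }
  exp <- t(vapply(tris, brute, character(2)))
  expect_equal(got$context, unname(exp[, 1]))
  expect_equal(got$subcontext, unname(exp[, 2]))
  # spec'd cases
  expect_equal(classify_context("CAG")$subcontext, "CWG")
  expect_equal(classify_context("CCG")$subcontext, "CCG")
  expect_error(classify_context("AGG"), "start with C")
  expect_error(classify_context("CNG"), "start with C")
})

test_that("allc read/write round-trip is lossless and validates counts", {
  allc <- random_allc(1000, seed = 42)
  allc[, called := rep(c(TRUE, FALSE, NA), length.out = .N)]
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_allc(allc, f1)
  back <- read_allc(f1)
  write_allc(back, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical body
  setorder(allc, chrom, pos, strand)
  expect_equal(back$mc, allc$mc)
  expect_equal(back$cov, allc$cov)
  expect_equal(back$context, allc$context)
  expect_equal(back$called, allc$called)

  # single line parses to the expected record
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t+\tCGA\t3\t5\t1", f3)
  rec <- read_allc(f3)
  expect_equal(rec$pos, 100L)
  expect_equal(rec$context, "CG")
  expect_equal(rec$mc, 3L)
  expect_true(rec$called)

  # mc > cov rejected with a line number
  writeLines(c("chr1\t100\t+\tCGA\t3\t5\t1", "chr1\t101\t+\tCGA\t6\t5\t1"), f3)
  expect_error(read_allc(f3), "line 2")
  # malformed numeric field rejected
  writeLines("chr1\tabc\t+\tCGA\t3\t5\t1", f3)
  expect_error(read_allc(f3), "malformed|parse")
  # unsorted input comes back sorted
  writeLines(c("chr1\t200\t+\tCGA\t1\t5\t0", "chr1\t100\t+\tCGA\t1\t5\t0"), f3)
  write_allc(read_allc(f3), f3)
  expect_equal(read_allc(f3)$pos, c(100L, 200L))
})

test_that("GFF gene models derive introns as exon gaps and pick the longest mRNA as primary", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=gA.t2",
    "chr1\tsrc\texon\t201\t500\t.\t+\t.\tParent=gA.t2",
    "chr1\tsrc\tgene\t600\t700\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t600\t700\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\texon\t600\t700\t.\t-\t.\tParent=gB.t1"), gff)
  ann <- read_gff(gff)
  # primary = larger spliced length (100 + 300 = 400 beats 100 + 100)
  expect_equal(ann$genes[gene_id == "gA", tx_id], "gA.t2")
  intr <- ann$introns[gene_id == "gA"]
  expect_equal(intr$start, 101L)
  expect_equal(intr$end, 200L)
  # single-exon gene has no introns
  expect_equal(nrow(ann$introns[gene_id == "gB"]), 0L)
})

test_that("exon/intron union tiles the gene span exactly on simulated genomes", {
  sim <- simulate_genome(sim_config(seed = 11, seq_n_genes = 25L, n_te = 3L))
  ann <- sim$annotation
  for (g in ann$genes$gene_id) {
    iv <- rbind(ann$exons[gene_id == g, .(start, end)],
                ann$introns[gene_id == g, .(start, end)])
    setorder(iv, start)
    expect_equal(iv$start[1], ann$genes[gene_id == g, start])
    expect_equal(iv$end[nrow(iv)], ann$genes[gene_id == g, end])
    if (nrow(iv) > 1) expect_equal(iv$start[-1], iv$end[-nrow(iv)] + 1L)
  }
  # round-trip through GFF3 on disk reproduces the same gene models
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_sim_genome(sim, fa, gff)
  back <- read_gff(gff)
  expect_equal(back$genes[order(gene_id), .(gene_id, start, end, strand)],
               ann$genes[order(gene_id), .(gene_id, start, end, strand)])
  expect_equal(back$introns[order(gene_id, start), .(gene_id, start, end, intron_rank)],
               ann$introns[order(gene_id, start), .(gene_id, start, end, intron_rank)])
})

test_that("long-intron selection applies the inclusive 1 kb threshold", {
  # g1 intron: 999 bp; g2 introns: exactly 1000 bp, 1500 bp, 300 bp
  genes <- data.table(gene_id = c("g1", "g2"), tx_id = c("g1.1", "g2.1"),
                      chrom = "chr1", strand = "+",
                      start = c(1L, 10000L), end = c(3000L, 17000L))
  exons <- data.table(
    gene_id = c("g1", "g1", "g2", "g2", "g2", "g2"),
    chrom = "chr1", strand = "+",
    start = c(1L, 1100L, 10000L, 12001L, 14501L, 16301L),
    end = c(100L, 3000L, 11000L, 13000L, 16000L, 17000L))
  ann <- genome_annotation(genes = genes, exons = exons)
  expect_setequal(ann$introns[, end - start + 1L], c(999L, 1000L, 1500L, 300L))
  long <- select_long_introns(ann, min_len = 1000L)
  expect_setequal(long$length, c(1000L, 1500L))   # 999 out, 1000 in
  expect_true(all(long$gene_id == "g2"))
  expect_equal(select_long_introns(ann, min_len = 1000L,
                                   inclusive = FALSE)$length, 1500L)
  # annotation with no multi-exon genes -> empty
  ann1 <- genome_annotation(
    genes = data.table(gene_id = "g3", tx_id = "g3.1", chrom = "chr1",
                       strand = "+", start = 1L, end = 100L),
    exons = data.table(gene_id = "g3", chrom = "chr1", strand = "+",
                       start = 1L, end = 100L))
  expect_equal(nrow(select_long_introns(ann1)), 0L)
})
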