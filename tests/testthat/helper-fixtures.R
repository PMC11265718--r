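library(data.table)

# --- independent oracles -----------------------------------------------------

# brute-force upper-tail binomial: explicit sum of dbinom terms
oracle_binom_tail <- function(mc, cov, p) {
  if (mc == 0) return(1)
  sum(vapply(mc:cov, function(k) stats::dbinom(k, cov, p), numeric(1)))
}

# brute-force Benjamini-Hochberg: sort, scale, cumulative min from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(cummin(rev(p[o] * m / seq_len(m)))[m:1], 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force Tajima's D: explicit loop over haplotype pairs for pi,
# textbook constants recomputed independently
oracle_tajima <- function(geno) {
  n <- ncol(geno)
  pairs <- utils::combn(n, 2)
  d <- 0
  for (j in seq_len(ncol(pairs))) {
    a <- geno[, pairs[1, j]]
    b <- geno[, pairs[2, j]]
    ok <- !is.na(a) & !is.na(b)
    d <- d + sum(a[ok] != b[ok])
  }
  pi <- d / ncol(pairs)
  ones <- rowSums(geno == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(geno))
  S <- sum(ones > 0 & ones < nonmiss)
  if (S == 0) return(list(pi = pi, S = S, D = NA_real_))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  list(pi = pi, S = S, D = (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# --- fixture builders --------------------------------------------------------

# allc table from parallel vectors; context recomputed from trinucleotides
make_allc <- function(chrom, pos, strand, trinuc, mc, cov, called = NA) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                   trinuc = trinuc, mc = as.integer(mc), cov = as.integer(cov),
                   called = called)
  ctx <- classify_context(dt$trinuc)
  dt[, `:=`(context = ctx$context, subcontext = ctx$subcontext)]
  setcolorder(dt, c("chrom", "pos", "strand", "trinuc", "context",
                    "subcontext", "mc", "cov", "called"))
  dt[]
}

# two-exon plus-strand toy gene: exons 1-100 and 201-300, CDS excludes
# a 10 bp UTR at each transcript end
toy_annotation <- function(strand = "+") {
  genes <- data.table(gene_id = "g1", tx_id = "g1.1", chrom = "chr1",
                      strand = strand, start = 1L, end = 300L)
  exons <- data.table(gene_id = "g1", chrom = "chr1", strand = strand,
                      start = c(1L, 201L), end = c(100L, 300L))
  cds <- data.table(gene_id = "g1", chrom = "chr1", strand = strand,
                    start = c(11L, 201L), end = c(100L, 290L))
  genome_annotation(genes = genes, exons = exons, cds = cds)
}

# random uncalled allc over n sites on one chromosome
random_allc <- function(n, seed = 1) {
  set.seed(seed)
  tri <- sample(c("CGA", "CAG", "CCG", "CTA", "CTG"), n, replace = TRUE)
  cov <- rpois(n, 8)
  make_allc("chr1", sample.int(10 * n, n), sample(c("+", "-"), n, TRUE),
            tri, rbinom(n, cov, 0.3), cov)
}
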