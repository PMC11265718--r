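#' Read a biallelic genotype matrix
#'
#' Tab-separated genotype table: a `pos` column (1-based positions on the
#' reference) followed by one 0/1 column per haplotype (inbred accessions
#' treated as haploid); missing genotypes as `NA`.
#'
#' @param path Path to the TSV.
#' @return List with `pos` (integer vector) and `geno` (sites x
#'   haplotypes integer matrix with haplotype ids as column names).
#' @export
read_snp_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"pos" %in% names(dt)) stop("genotype TSV needs a 'pos' column")
  geno <- as.matrix(dt[, !"pos"])
  storage.mode(geno) <- "integer"
  bad <- geno[!is.na(geno)]
  if (any(!bad %in% c(0L, 1L))) stop("genotypes must be 0/1/NA (biallelic)")
  list(pos = dt$pos, geno = geno)
}

# segregating sites: >= 2 alleles among non-missing entries per row
segregating <- function(geno) {
  ones <- rowSums(geno == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(geno))
  ones > 0L & ones < nonmiss
}

#' SNP density within a region class
#'
#' The proportion of sites with a SNP: segregating positions of the
#' class divided by the number of surveyed sites. By default the
#' denominator is the total length of the class's intervals; set
#' `denominator = "genotyped"` to use only genotyped positions.
#'
#' @param snp List with `pos` and `geno` (see [read_snp_tsv()]).
#' @param regions `data.table` with `class`, `start`, `end` (1-based
#'   closed intervals on the same reference as `pos`).
#' @param region_class Class to evaluate (one of `regions$class`).
#' @param denominator `"region_length"` (default) or `"genotyped"`.
#' @return A fraction, or `NA` when the class has zero surveyed length.
#' @export
snp_density <- function(snp, regions, region_class,
                        denominator = c("region_length", "genotyped")) {
  denominator <- match.arg(denominator)
  regions <- data.table::as.data.table(regions)
  reg <- regions[class == region_class]
  if (nrow(reg) == 0L) return(NA_real_)
  inside <- vapply(snp$pos, function(p) any(p >= reg$start & p <= reg$end),
                   logical(1))
  L <- if (denominator == "region_length") {
    sum(reg$end - reg$start + 1)
  } else sum(inside)
  if (L == 0) return(NA_real_)
  S <- sum(segregating(snp$geno[inside, , drop = FALSE]))
  S / L
}

#' Tajima's D and summary population-genetic statistics
#'
#' Computes segregating sites S, mean pairwise diversity (the average
#' number of differences between haplotype pairs, pairwise-complete over
#' missing data), the Watterson/Tajima normalising constants, and
#' Tajima's D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)) for a biallelic
#' genotype matrix. D contrasts pairwise diversity with the
#' Watterson estimate of the mutation parameter: an excess of rare
#' variants pulls D negative, an excess of intermediate-frequency
#' variants pushes it positive.
#'
#' @param geno Sites x haplotypes matrix of 0/1/NA (inbred accessions as
#'   haploids). At least 4 haplotypes.
#' @param L Number of sites surveyed (for `snp_density`; defaults to
#'   `nrow(geno)`).
#' @param region_class Optional label stored on the result.
#' @return A `popgen_stats` list: `region_class`, `n`, `L`, `S`, `pi`,
#'   `snp_density`, the constants `a1, a2, b1, b2, c1, c2, e1, e2`, and
#'   `D` (`NA` when S = 0).
#' @export
tajimas_d <- function(geno, L = nrow(geno), region_class = NA_character_) {
  geno <- as.matrix(geno)
  n <- ncol(geno)
  if (n < 4L) stop("Tajima's D requires at least 4 haplotypes")
  seg <- segregating(geno)
  S <- sum(seg)
  ones <- rowSums(geno == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(geno))
  # sum over sites of pairwise differences = k * (n_i - k); average over all
  # haplotype pairs (pairwise-complete in the numerator)
  pi <- sum(ones * (nonmiss - ones)) / choose(n, 2)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0L) NA_real_ else (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(list(region_class = region_class, n = n, L = L, S = S, pi = pi,
                 snp_density = if (L > 0) S / L else NA_real_,
                 a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                 e1 = e1, e2 = e2, D = D),
            class = "popgen_stats")
}

#' @export
print.popgen_stats <- function(x, ...) {
  cat("Population-genetic summary",
      if (!is.na(x$region_class)) paste0(" [", x$region_class, "]"), "\n",
      "  n = ", x$n, ", L = ", x$L, ", S = ", x$S, "\n",
      "  pi = ", signif(x$pi, 5), ", SNP density = ", signif(x$snp_density, 5),
      "\n  Tajima's D = ", signif(x$D, 5), "\n", sep = "")
  invisible(x)
}

#' Region-stratified population-genetic statistics
#'
#' Splits a genotype matrix by region class (e.g. CDS, methylated
#' intron, unmethylated intron) and computes SNP density and Tajima's D
#' for each class separately.
#'
#' @inheritParams snp_density
#' @return `data.table`, one row per class: `region_class`, `L`, `S`,
#'   `pi`, `snp_density`, `D`.
#' @export
popgen_by_region <- function(snp, regions,
                             denominator = c("region_length", "genotyped")) {
  denominator <- match.arg(denominator)
  regions <- data.table::as.data.table(regions)
  data.table::rbindlist(lapply(unique(regions$class), function(cl) {
    reg <- regions[class == cl]
    inside <- vapply(snp$pos, function(p) any(p >= reg$start & p <= reg$end),
                     logical(1))
    L <- if (denominator == "region_length") {
      sum(reg$end - reg$start + 1)
    } else sum(inside)
    st <- tajimas_d(snp$geno[inside, , drop = FALSE], L = L, region_class = cl)
    data.table::data.table(region_class = cl, L = st$L, S = st$S, pi = st$pi,
                           snp_density = st$snp_density, D = st$D)
  }))
}

#' Per-class nucleotide difference between two aligned sequences
#'
#' For a two-sequence alignment whose columns are assigned to region
#' classes, computes 1 minus the proportion of identical bases per
#' class. Columns with a gap in either sequence are excluded from both
#' numerator and denominator.
#'
#' @param alignment Character vector of two equal-length aligned
#'   sequences (or a `DNAStringSet` of length 2).
#' @param classes Character vector assigning each alignment column to a
#'   region class.
#' @return `data.table` with `region_class`, `compared`, `identical`,
#'   `difference`.
#' @export
pairwise_difference <- function(alignment, classes) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (length(alignment) != 2L) stop("alignment must contain exactly two sequences")
  if (nchar(alignment[1]) != nchar(alignment[2])) {
    stop("aligned sequences differ in length")
  }
  a <- strsplit(toupper(alignment[1]), "")[[1]]
  b <- strsplit(toupper(alignment[2]), "")[[1]]
  if (length(classes) != length(a)) {
    stop("classes must assign every alignment column")
  }
  keep <- a != "-" & b != "-"
  dt <- data.table::data.table(class = classes[keep], same = a[keep] == b[keep])
  out <- dt[, .(compared = .N, identical = sum(same),
                difference = 1 - sum(same) / .N), by = class]
  data.table::setnames(out, "class", "region_class")
  out[]
}
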