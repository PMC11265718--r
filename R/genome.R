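#' Enumerate cytosine sites of a genome
#'
#' Scans every chromosome on both strands and returns one record per
#' cytosine with its trinucleotide (read 5' to 3' on the site's own
#' strand — the reverse complement of the reference for minus-strand
#' sites) and context classification. Cytosines too close to a sequence
#' end to have a full trinucleotide are dropped.
#'
#' @param genome A named `DNAStringSet` (or named character vector of
#'   sequences).
#' @return An allc-skeleton `data.table`: `chrom`, `pos`, `strand`,
#'   `trinuc`, `context`, `subcontext` (no counts).
#' @export
extract_cytosines <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  per_chrom <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    L <- nchar(s)
    if (L < 3L) return(NULL)
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    p_plus <- which(bases == "C")
    p_plus <- p_plus[p_plus <= L - 2L]
    p_minus <- which(bases == "G")
    p_minus <- p_minus[p_minus >= 3L]
    plus <- if (length(p_plus)) data.table::data.table(
      chrom = ch, pos = p_plus, strand = "+",
      trinuc = paste0(bases[p_plus], bases[p_plus + 1L], bases[p_plus + 2L]))
    minus <- if (length(p_minus)) data.table::data.table(
      chrom = ch, pos = p_minus, strand = "-",
      trinuc = paste0("C", comp(bases[p_minus - 1L]), comp(bases[p_minus - 2L])))
    data.table::rbindlist(list(plus, minus))
  })
  dt <- data.table::rbindlist(per_chrom)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), trinuc = character(),
                                  context = character(), subcontext = character()))
  }
  ok <- grepl("^C[ACGT][ACGT]$", dt$trinuc)
  dt <- dt[ok]
  ctx <- classify_context(dt$trinuc)
  dt[, `:=`(context = ctx$context, subcontext = ctx$subcontext)]
  data.table::setorder(dt, chrom, pos, strand)
  dt[]
}
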