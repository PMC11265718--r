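#' Construct a genome annotation from interval tables
#'
#' Assembles the annotation container used throughout the package: one
#' gene model per gene (the primary transcript's exon/CDS/UTR structure),
#' with introns derived as the gaps between consecutive exons. All
#' coordinates are 1-based closed, matching GFF3.
#'
#' @param genes `data.table` with `gene_id`, `tx_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param exons `data.table` with `gene_id`, `chrom`, `strand`, `start`,
#'   `end`; one row per exon of the primary transcript.
#' @param cds,utr5,utr3 Optional interval tables with the same columns.
#' @param te Optional transposable-element intervals (`chrom`, `start`,
#'   `end`, optionally `te_class`).
#' @param chrom_lengths Optional named integer vector of chromosome
#'   lengths; when given, intervals are checked against it.
#' @return An object of class `genome_annotation`: a list of interval
#'   tables (`genes`, `exons`, `cds`, `utr5`, `utr3`, `introns`, `te`)
#'   plus `chrom_lengths`. Exon and intron rows carry a rank numbered
#'   5' to 3' along the transcript (reversed on minus-strand genes).
#' @export
genome_annotation <- function(genes, exons, cds = NULL, utr5 = NULL,
                              utr3 = NULL, te = NULL, chrom_lengths = NULL) {
  empty_iv <- function() data.table::data.table(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer())
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  cds <- if (is.null(cds)) empty_iv() else data.table::as.data.table(cds)
  utr5 <- if (is.null(utr5)) empty_iv() else data.table::as.data.table(utr5)
  utr3 <- if (is.null(utr3)) empty_iv() else data.table::as.data.table(utr3)
  te <- if (is.null(te)) {
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), te_class = character())
  } else data.table::as.data.table(te)

  if (any(exons$end < exons$start)) stop("exon with end < start")
  data.table::setorder(exons, gene_id, chrom, start)
  # exons of one gene must not overlap
  exons[, prev_end := data.table::shift(end), by = gene_id]
  if (any(!is.na(exons$prev_end) & exons$start <= exons$prev_end)) {
    stop("overlapping exons within a gene model")
  }
  exons[, prev_end := NULL]
  # every exon inside its gene span
  chk <- merge(exons, genes[, .(gene_id, gstart = start, gend = end)],
               by = "gene_id")
  if (any(chk$start < chk$gstart | chk$end > chk$gend)) {
    bad <- chk[start < gstart | end > gend]$gene_id[1]
    stop("exon outside gene span for gene ", bad)
  }
  # CDS contained in exons
  if (nrow(cds)) {
    ov <- interval_overlap(cds, exons, by_gene = TRUE)
    cds_w <- cds[, sum(end - start + 1)]
    if (ov < cds_w) stop("CDS interval not contained in any exon")
  }
  if (!is.null(chrom_lengths)) {
    for (tab in list(genes, exons, te)) {
      if (!nrow(tab)) next
      len <- chrom_lengths[tab$chrom]
      if (any(is.na(len)) || any(tab$end > len) || any(tab$start < 1L)) {
        stop("interval outside chromosome bounds")
      }
    }
  }
  rank_5p <- function(tab) {
    if (!nrow(tab)) return(integer())
    tab[, data.table::fifelse(strand == "-",
                              rev(seq_len(.N)), seq_len(.N)), by = gene_id]$V1
  }
  exons[, exon_rank := rank_5p(exons)]
  introns <- derive_introns(exons)
  ann <- structure(list(genes = genes, exons = exons, cds = cds, utr5 = utr5,
                        utr3 = utr3, introns = introns, te = te,
                        chrom_lengths = chrom_lengths),
                   class = "genome_annotation")
  ann
}

# summed overlap (bp) between two interval sets sharing gene_id
interval_overlap <- function(a, b, by_gene = FALSE) {
  a <- data.table::copy(a); b <- data.table::copy(b)
  keys <- if (by_gene) c("gene_id", "start", "end") else c("chrom", "start", "end")
  data.table::setkeyv(b, keys)
  hits <- data.table::foverlaps(a, b, by.x = keys, nomatch = NULL)
  if (!nrow(hits)) return(0)
  hits[, sum(pmin(end, i.end) - pmax(start, i.start) + 1)]
}

# introns = gaps between consecutive exons, ranked 5'->3'
derive_introns <- function(exons) {
  if (!nrow(exons)) {
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer(), intron_rank = integer()))
  }
  ex <- data.table::copy(exons)
  data.table::setorder(ex, gene_id, start)
  introns <- ex[, {
    if (.N < 2L) {
      list(chrom = character(), strand = character(),
           start = integer(), end = integer())
    } else {
      list(chrom = chrom[-1L], strand = strand[-1L],
           start = end[-.N] + 1L, end = start[-1L] - 1L)
    }
  }, by = gene_id]
  if (nrow(introns)) {
    introns[, intron_rank := data.table::fifelse(strand == "-",
                                                 rev(seq_len(.N)),
                                                 seq_len(.N)), by = gene_id]
  } else {
    introns[, intron_rank := integer()]
  }
  introns[]
}

#' Read a GFF3 annotation into gene models
#'
#' Imports gene/mRNA/exon/CDS/UTR features and builds one gene model per
#' gene from its primary transcript, defined as the mRNA with the largest
#' spliced (summed-exon) length, ties broken by lexicographically smallest
#' transcript id. Introns are derived as the gaps between consecutive
#' exons. Features of type `transposable_element` (or whose type contains
#' "transposon") are collected as TE intervals.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A [genome_annotation()] object.
#' @export
read_gff <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1)))

  gene_rows <- dt[type == "gene"]
  mrna <- dt[type == "mRNA"]
  orphan <- mrna[!parent %in% gene_rows$id]
  if (nrow(orphan)) {
    warning("skipping ", nrow(orphan), " mRNA(s) without a gene parent: ",
            paste(utils::head(orphan$id, 3L), collapse = ", "))
    mrna <- mrna[parent %in% gene_rows$id]
  }
  if (!nrow(mrna)) stop("no usable mRNA features in ", path)

  subfeat <- dt[type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
  subfeat <- subfeat[parent %in% mrna$id]
  splen <- subfeat[type == "exon", .(spliced = sum(end - start + 1)), by = parent]
  mrna <- merge(mrna, splen, by.x = "id", by.y = "parent", all.x = TRUE)
  mrna[is.na(spliced), spliced := end - start + 1]  # exon-less mRNA: span
  data.table::setorder(mrna, parent, -spliced, id)
  primary <- mrna[, .SD[1L], by = parent]

  genes <- primary[, .(gene_id = parent, tx_id = id, chrom, strand, start, end)]
  pick <- function(tp) {
    x <- subfeat[type == tp & parent %in% primary$id]
    x <- merge(x, primary[, .(id, gene_id = parent)],
               by.x = "parent", by.y = "id")
    x[, .(gene_id, chrom, strand, start, end)]
  }
  exons <- pick("exon")
  if (!nrow(exons)) {  # annotations without explicit exon rows: use mRNA span
    exons <- genes[, .(gene_id, chrom, strand, start, end)]
  }
  te <- dt[grepl("transposable_element|transposon", type, ignore.case = TRUE),
           .(chrom, start, end, te_class = type)]

  genome_annotation(genes = genes, exons = exons, cds = pick("CDS"),
                    utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"),
                    te = te, chrom_lengths = chrom_lengths)
}

#' Select long introns
#'
#' Returns the introns whose length reaches a threshold (default 1 kb,
#' inclusive), ordered by genomic position. Long introns are the candidate
#' heterochromatin-sensor regions screened for mCHG enrichment.
#'
#' @param annotation A [genome_annotation()].
#' @param min_len Minimum intron length in bp (default 1000).
#' @param inclusive If `TRUE` (default) the comparison is `length >=
#'   min_len`, otherwise strictly greater.
#' @return A `data.table` with `gene_id`, `intron_rank`, `chrom`, `strand`,
#'   `start`, `end`, `length`.
#' @export
select_long_introns <- function(annotation, min_len = 1000L, inclusive = TRUE) {
  introns <- data.table::copy(annotation$introns)
  introns[, length := end - start + 1L]
  out <- if (inclusive) introns[length >= min_len] else introns[length > min_len]
  data.table::setorder(out, chrom, start)
  out[, .(gene_id, intron_rank, chrom, strand, start, end, length)]
}

#' Export intervals as BED
#'
#' Writes a 6-column BED file (0-based half-open, per the BED convention)
#' from a 1-based closed interval table.
#'
#' @param intervals `data.table` with `chrom`, `start`, `end`, and
#'   optionally `gene_id`/`strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  iv <- data.table::as.data.table(intervals)
  name <- if ("gene_id" %in% names(iv)) iv$gene_id else "."
  strand <- if ("strand" %in% names(iv)) iv$strand else "."
  out <- data.table::data.table(chrom = iv$chrom, start = iv$start - 1L,
                                end = iv$end, name = name, score = 0L,
                                strand = strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
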