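#' Spliced transcript sequence of a gene model
#'
#' Concatenates the exon sequences of the primary transcript in 5' to 3'
#' order (reverse-complemented for minus-strand genes).
#'
#' @param annotation A [genome_annotation()].
#' @param gene_id Gene identifier.
#' @param genome A `DNAStringSet` keyed by chromosome name.
#' @param max_exon_rank Optional: use only exons with rank up to this
#'   value (the exonic prefix 5' of intron `max_exon_rank`).
#' @return Character scalar sequence.
#' @export
spliced_sequence <- function(annotation, gene_id, genome,
                             max_exon_rank = Inf) {
  gid <- gene_id
  ex <- annotation$exons[gene_id == gid & exon_rank <= max_exon_rank]
  if (nrow(ex) == 0L) stop("no exons for gene ", gid)
  data.table::setorder(ex, start)
  seqs <- Biostrings::DNAStringSet(Biostrings::subseq(
    genome[ex$chrom], start = ex$start, end = ex$end))
  if (ex$strand[1] == "-") {
    seqs <- rev(Biostrings::reverseComplement(seqs))
  }
  paste(as.character(seqs), collapse = "")
}

#' Build a truncated short-isoform transcript
#'
#' For a gene with a long (typically methylated) intron, constructs the
#' truncated transcript comprising only the exonic sequence (UTR and
#' CDS) 5' of that intron — the reference for quantifying the short
#' isoform that arises when transcription terminates at the
#' heterochromatic intron. The short sequence is by construction a
#' prefix of the full spliced transcript.
#'
#' @param annotation A [genome_annotation()].
#' @param gene_id Gene identifier.
#' @param intron_rank Rank (5' to 3') of the target intron.
#' @param genome A `DNAStringSet`.
#' @return A `transcript_pair` list: `gene_id`, `long_tx`, `short_tx`
#'   ids, `long_seq`, `short_seq`, and `truncation_point` (length of the
#'   short sequence in transcript coordinates).
#' @export
make_truncated_transcript <- function(annotation, gene_id, intron_rank, genome) {
  gid <- gene_id
  gene <- annotation$genes[gene_id == gid]
  if (nrow(gene) != 1L) stop("unknown gene ", gid)
  k <- intron_rank
  if (!nrow(annotation$introns[gene_id == gid & intron_rank == k])) {
    stop("gene ", gid, " has no intron of rank ", k)
  }
  long_seq <- spliced_sequence(annotation, gid, genome)
  short_seq <- spliced_sequence(annotation, gid, genome, max_exon_rank = k)
  # warn when the transcript is cut before any coding sequence
  ex5 <- annotation$exons[gene_id == gid & exon_rank <= k]
  if (nrow(annotation$cds[gene_id == gid])) {
    ov <- interval_overlap(annotation$cds[gene_id == gid], ex5, by_gene = TRUE)
    if (ov == 0) {
      warning("target intron of ", gid,
              " precedes all CDS; short transcript is UTR only")
    }
  }
  structure(list(gene_id = gid, long_tx = gene$tx_id,
                 short_tx = paste0(gene$tx_id, ".short"),
                 long_seq = long_seq, short_seq = short_seq,
                 truncation_point = nchar(short_seq)),
            class = "transcript_pair")
}

#' Write transcript pairs as FASTA
#'
#' Writes the long and truncated short sequences of one or more
#' [make_truncated_transcript()] pairs to a FASTA file, short records
#' named `<tx>.short`.
#'
#' @param pairs A `transcript_pair` or list of them.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcript_pairs <- function(pairs, path) {
  if (inherits(pairs, "transcript_pair")) pairs <- list(pairs)
  seqs <- unlist(lapply(pairs, function(p) {
    stats::setNames(c(p$long_seq, p$short_seq), c(p$long_tx, p$short_tx))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Transcript pairing table
#'
#' @param pairs A `transcript_pair` or list of them.
#' @return `data.table` with `gene_id`, `long_tx`, `short_tx`.
#' @export
transcript_pairs_table <- function(pairs) {
  if (inherits(pairs, "transcript_pair")) pairs <- list(pairs)
  data.table::rbindlist(lapply(pairs, function(p)
    data.table::data.table(gene_id = p$gene_id, long_tx = p$long_tx,
                           short_tx = p$short_tx)))
}

#' Short/long isoform abundance ratios
#'
#' Averages transcript abundances across replicates within each
#' condition, then computes the short/long ratio per gene and condition.
#' The ratio is missing (not infinite) when the long isoform's average
#' abundance is zero.
#'
#' @param abundance `data.table` with `transcript_id`, `sample`,
#'   `abundance` (any unit, e.g. TPM; never recomputed here).
#' @param pairs Pairing table from [transcript_pairs_table()] (columns
#'   `gene_id`, `long_tx`, `short_tx`).
#' @param conditions Optional `data.table` mapping `sample` to
#'   `condition`; all samples form one condition when `NULL`.
#' @return `data.table` with `gene_id`, `condition`, `short_abund`,
#'   `long_abund`, `ratio`.
#' @export
isoform_ratio <- function(abundance, pairs, conditions = NULL) {
  ab <- data.table::as.data.table(abundance)
  if (any(ab$abundance < 0, na.rm = TRUE)) stop("negative abundances")
  if (is.null(conditions)) {
    ab[, condition := "all"]
  } else {
    ab <- merge(ab, data.table::as.data.table(conditions), by = "sample")
  }
  avg <- ab[, .(abund = mean(abundance)), by = .(transcript_id, condition)]
  pairs <- data.table::as.data.table(pairs)
  out <- merge(pairs, avg, by.x = "short_tx", by.y = "transcript_id",
               allow.cartesian = TRUE)
  data.table::setnames(out, "abund", "short_abund")
  out <- merge(out, avg, by.x = c("long_tx", "condition"),
               by.y = c("transcript_id", "condition"))
  data.table::setnames(out, "abund", "long_abund")
  n_missing <- nrow(pairs) * length(unique(avg$condition)) - nrow(out)
  if (n_missing > 0) {
    message(n_missing, " gene x condition pair(s) missing a transcript; skipped")
  }
  out[, ratio := data.table::fifelse(long_abund > 0,
                                     short_abund / long_abund, NA_real_)]
  out[, .(gene_id, condition, short_abund, long_abund, ratio)]
}

#' Genes with shifted short/long isoform ratios
#'
#' Lists genes whose short-to-long isoform ratio increased by strictly
#' more than `delta` from condition A (e.g. wild type) to condition B
#' (e.g. a mutant releasing intron methylation). Genes with a missing
#' ratio in either condition are skipped.
#'
#' @param ratios_a,ratios_b [isoform_ratio()] outputs (or any tables
#'   with `gene_id` and `ratio`).
#' @param delta Minimum ratio difference, strict (default 2).
#' @return `data.table` with `gene_id`, `ratio_a`, `ratio_b`, `diff`.
#' @export
ratio_shift_genes <- function(ratios_a, ratios_b, delta = 2) {
  a <- data.table::as.data.table(ratios_a)[, .(gene_id, ratio_a = ratio)]
  b <- data.table::as.data.table(ratios_b)[, .(gene_id, ratio_b = ratio)]
  joined <- merge(a, b, by = "gene_id")
  joined <- joined[!is.na(ratio_a) & !is.na(ratio_b)]
  joined[, diff := ratio_b - ratio_a]
  out <- joined[diff > delta]
  data.table::setorder(out, -diff)
  out[]
}
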