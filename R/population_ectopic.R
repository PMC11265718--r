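#' Assemble an accession panel from per-accession gene classifications
#'
#' Stacks classified gene summaries (one [classify_gbm()] output per
#' accession) into the long-format panel table used by the population
#' ectopic-methylation scan.
#'
#' @param summaries Named list of classified summary tables; names are
#'   accession ids. Alternatively a long `data.table` that already has an
#'   `accession` column is passed through.
#' @return Long `data.table` with `accession`, `gene_id`, `label`,
#'   `q_CHG`, `q_CHH`, `weighted_mCHG` (plus any other shared columns).
#' @export
accession_panel <- function(summaries) {
  if (is.data.frame(summaries)) {
    dt <- data.table::as.data.table(summaries)
    if (!"accession" %in% names(dt)) stop("long panel table needs an 'accession' column")
    return(dt)
  }
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    stop("per-accession summary list must be named by accession id")
  }
  data.table::rbindlist(summaries, idcol = "accession", fill = TRUE)
}

#' Population gbM frequency per gene
#'
#' Fraction of accessions in which each gene is classified gbM, computed
#' over the accessions where the gene is classifiable (unclassified
#' accessions are excluded from the denominator).
#'
#' @param panel Long panel table from [accession_panel()].
#' @return `data.table` with `gene_id`, `n_classified`, `gbm_freq`.
#' @export
gbm_frequency <- function(panel) {
  panel[label != "unclassified",
        .(n_classified = .N, gbm_freq = mean(label == "gbM")), by = gene_id]
}

#' Call ectopic non-CG genes across an accession panel
#'
#' A gene is ectopic in a given accession when it carries significant
#' non-CG methylation there (mCHG and/or mCHH q-value below `alpha`)
#' while being a gbM gene in more than `freq_min` of all accessions —
#' the signature of a gene-body methylation gain atypical for that gene.
#'
#' @param panel Long panel table from [accession_panel()] with `q_CHG`,
#'   `q_CHH` and `label` columns.
#' @param alpha Non-CG q-value threshold (default 0.05).
#' @param freq_min Population gbM frequency a gene must exceed (strictly)
#'   to be an ectopic candidate (default 0.90).
#' @return List with `calls` (accession x gene table of ectopic calls),
#'   `counts` (`accession`, `n_ectopic`), and `gbm_freq` (per-gene
#'   population frequencies).
#' @export
call_ectopic_genes <- function(panel, alpha = 0.05, freq_min = 0.90) {
  panel <- data.table::as.data.table(panel)
  freq <- gbm_frequency(panel)
  candidates <- freq[gbm_freq > freq_min, gene_id]
  calls <- panel[gene_id %in% candidates & label != "unclassified" &
                   (q_CHG < alpha | q_CHH < alpha),
                 .(accession, gene_id, q_CHG, q_CHH, weighted_mCHG)]
  counts <- panel[, .(n_ectopic = 0L), by = accession]
  if (nrow(calls)) {
    nn <- calls[, .(n = .N), by = accession]
    counts <- merge(counts[, .(accession)], nn, by = "accession", all.x = TRUE)
    counts[is.na(n), n := 0L]
    data.table::setnames(counts, "n", "n_ectopic")
  }
  list(calls = calls, counts = counts[], gbm_freq = freq)
}

#' Flag ibm1-like accessions
#'
#' Accessions whose number of ectopic non-CG genes exceeds a threshold
#' behave like *ibm1* mutants: many normally-gbM genes have gained CHG
#' methylation. The default is the strict reading `n_ectopic >
#' threshold`; set `strict = FALSE` for `>=`.
#'
#' @param counts `data.table` with `accession`, `n_ectopic` (from
#'   [call_ectopic_genes()]).
#' @param threshold Ectopic-gene count threshold (default 120).
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return The counts table with an `ibm1_like` logical column.
#' @export
flag_ibm1_like <- function(counts, threshold = 120L, strict = TRUE) {
  out <- data.table::as.data.table(counts)
  out[, ibm1_like := if (strict) n_ectopic > threshold else n_ectopic >= threshold]
  out[]
}

#' Genes gaining mCHG between paired samples
#'
#' Lists the genes whose coverage-weighted CHG methylation increased by
#' strictly more than `delta` (default 0.02, i.e. 2%) from a reference
#' sample to a comparison sample. By default the candidate set is the
#' reference sample's gbM genes.
#'
#' @param reference,sample Classified summary tables
#'   (see [classify_gbm()]) with `weighted_mCHG` columns.
#' @param delta Minimum mCHG gain, strict (default 0.02).
#' @param candidates `"gbM"` (default: reference gbM genes) or `"all"`.
#' @return `data.table` with `gene_id`, `mchg_reference`, `mchg_sample`,
#'   `gain`, for listed genes only.
#' @export
mchg_gain_genes <- function(reference, sample, delta = 0.02,
                            candidates = c("gbM", "all")) {
  candidates <- match.arg(candidates)
  ref <- data.table::as.data.table(reference)
  if (candidates == "gbM") ref <- ref[label == "gbM"]
  joined <- merge(ref[, .(gene_id, mchg_reference = weighted_mCHG)],
                  data.table::as.data.table(sample)[, .(gene_id, mchg_sample = weighted_mCHG)],
                  by = "gene_id")
  n_missing <- nrow(ref) - nrow(joined)
  if (n_missing > 0) {
    message(n_missing, " candidate gene(s) missing from the comparison sample; skipped")
  }
  joined <- joined[!is.na(mchg_reference) & !is.na(mchg_sample)]
  joined[, gain := mchg_sample - mchg_reference]
  out <- joined[gain > delta]
  data.table::setorder(out, -gain)
  out[]
}

#' Join ectopic counts with sensor-intron methylation and expression
#'
#' Builds the per-accession table relating the heterochromatin-sensor
#' intron's mCHG level to the accession's ectopic-gene count, gene
#' expression, and short/long isoform ratio, and computes Spearman rank
#' correlations of expression (and isoform ratio, when supplied) with
#' intron mCHG on the low-methylation subset (`sensor_mchg <=
#' mchg_max`), where the sensor responds dynamically.
#'
#' @param counts Per-accession ectopic counts ([call_ectopic_genes()] /
#'   [flag_ibm1_like()] output).
#' @param sensor `data.table` with `accession`, `sensor_mchg`.
#' @param expression `data.table` with `accession`, `expression`.
#' @param isoform_ratio Optional `data.table` with `accession`, `ratio`
#'   (short/long).
#' @param mchg_max Upper bound of the correlation subset (default 0.035,
#'   inclusive).
#' @return List with `table` (joined per-accession table), `n_subset`,
#'   `cor_expression` and `cor_isoform` (Spearman rho on the subset;
#'   `NA` when the corresponding column is absent).
#' @export
ectopic_vs_sensor_table <- function(counts, sensor, expression,
                                    isoform_ratio = NULL, mchg_max = 0.035) {
  tab <- merge(data.table::as.data.table(counts),
               data.table::as.data.table(sensor), by = "accession")
  tab <- merge(tab, data.table::as.data.table(expression), by = "accession")
  if (!is.null(isoform_ratio)) {
    tab <- merge(tab, data.table::as.data.table(isoform_ratio), by = "accession",
                 all.x = TRUE)
  }
  n_dropped <- max(nrow(counts), nrow(sensor)) - nrow(tab)
  if (n_dropped > 0) message(n_dropped, " accession(s) missing from a join input; excluded")
  sub <- tab[sensor_mchg <= mchg_max]
  rho <- function(y) {
    if (is.null(y) || nrow(sub) < 3L) return(NA_real_)
    stats::cor(sub$sensor_mchg, y, method = "spearman", use = "complete.obs")
  }
  list(table = tab[], n_subset = nrow(sub),
       cor_expression = rho(sub$expression),
       cor_isoform = if (!is.null(isoform_ratio)) rho(sub$ratio) else NA_real_)
}
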