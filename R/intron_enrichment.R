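#' Pooled background methylation over arbitrary intervals
#'
#' Computes the per-context fraction of called-methylated sites among
#' eligible sites pooled over a set of intervals — the background model
#' for region-level binomial tests.
#'
#' @param allc A called allc table.
#' @param intervals Interval `data.table` (`chrom`, `start`, `end`).
#' @param scope Scope label stored on the model.
#' @param min_cov Minimum coverage for eligibility (default 3).
#' @return A `background_model` (see [estimate_background()]).
#' @export
region_background <- function(allc, intervals, scope = "region", min_cov = 3L) {
  hits <- sites_in_intervals(data.table::as.data.table(allc),
                             data.table::as.data.table(intervals), carry = character())
  p_bg <- vapply(c("CG", "CHG", "CHH"), function(ctx) {
    sub <- hits[context == ctx & cov >= min_cov]
    if (nrow(sub) == 0L) stop("no eligible ", ctx, " sites in ", scope, " scope")
    sum(sub$called %in% TRUE) / nrow(sub)
  }, numeric(1))
  structure(list(p_bg = p_bg, scope = scope), class = "background_model")
}

#' Intron-wide background methylation
#'
#' The species-specific background probability that a single intronic
#' site of each context is methylated, pooled over all introns of the
#' annotation. Serves as the null rate for intron mCHG-enrichment tests.
#'
#' @inheritParams region_background
#' @param annotation A [genome_annotation()] with derived introns.
#' @return A `background_model` with scope `"intron"`.
#' @export
intron_background <- function(allc, annotation, min_cov = 3L) {
  if (nrow(annotation$introns) == 0L) stop("annotation has no introns")
  region_background(allc, annotation$introns, scope = "intron", min_cov = min_cov)
}

#' Test introns for mCHG enrichment
#'
#' For each supplied intron, counts eligible and called-methylated sites
#' per context, computes upper-tail binomial p-values against the
#' intron-wide background, and adjusts them with Benjamini-Hochberg FDR
#' across the set of introns tested in this invocation (per context). An
#' intron is flagged `enriched` — a heterochromatin-sensor candidate —
#' when its mCHG q-value is below `alpha`. The CWG/CCG subcontext
#' breakdown of CHG methylation is reported alongside.
#'
#' @param allc A called allc table.
#' @param introns Interval table with `gene_id`, `intron_rank`, `chrom`,
#'   `start`, `end` (e.g. from [select_long_introns()] or
#'   `annotation$introns`).
#' @param background An intron-scope `background_model`.
#' @param alpha Enrichment q-value threshold (default 0.05).
#' @param min_cov Minimum coverage for site eligibility (default 3).
#' @return `data.table`, one row per intron: per-context counts,
#'   `p_*`/`q_*`, `weighted_mCHG`, `weighted_mCWG`, `weighted_mCCG`,
#'   `testable` (any eligible CHG site) and `enriched`.
#' @export
test_introns <- function(allc, introns, background, alpha = 0.05, min_cov = 3L) {
  stopifnot(inherits(background, "background_model"))
  introns <- data.table::as.data.table(introns)
  if (!"intron_rank" %in% names(introns)) introns[, intron_rank := seq_len(.N)]
  if (nrow(introns) == 0L) {
    return(data.table::data.table(gene_id = character(), intron_rank = integer()))
  }
  introns[, intron_key := paste(gene_id, intron_rank, sep = "#")]
  hits <- sites_in_intervals(data.table::as.data.table(allc), introns,
                             carry = c("gene_id", "intron_rank", "intron_key"))
  per_ctx <- hits[cov >= min_cov,
                  .(n_sites = .N, n_meth = sum(called %in% TRUE)),
                  by = .(intron_key, context)]
  chg_w <- hits[context == "CHG",
                .(weighted_mCHG = weighted_level(mc, cov)), by = intron_key]
  cwg_w <- hits[context == "CHG" & subcontext == "CWG",
                .(weighted_mCWG = weighted_level(mc, cov)), by = intron_key]
  ccg_w <- hits[context == "CHG" & subcontext == "CCG",
                .(weighted_mCCG = weighted_level(mc, cov)), by = intron_key]

  out <- introns[, .(intron_key, gene_id, intron_rank, chrom, strand, start, end)]
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- per_ctx[context == ctx, .(intron_key, n_sites, n_meth)]
    out <- merge(out, sub, by = "intron_key", all.x = TRUE)
    out[is.na(n_sites), `:=`(n_sites = 0L, n_meth = 0L)]
    out[, (paste0("p_", ctx)) := binom_tail(n_meth, n_sites, background$p_bg[[ctx]])]
    out[, (paste0("q_", ctx)) := bh_fdr(get(paste0("p_", ctx)))]
    data.table::setnames(out, c("n_sites", "n_meth"),
                         paste0(c("n_sites_", "n_meth_"), ctx))
  }
  for (w in list(chg_w, cwg_w, ccg_w)) out <- merge(out, w, by = "intron_key", all.x = TRUE)
  out[, testable := n_sites_CHG > 0L]
  out[, enriched := testable & q_CHG < alpha]
  out[, intron_key := NULL]
  out[]
}

#' Screen all long introns for heterochromatin-sensor candidates
#'
#' Genome-wide generalisation of the single-intron test: selects every
#' intron of at least `min_len` bp, tests each against the intron-wide
#' mCHG background (one BH family for the whole screen), and returns the
#' results ranked by mCHG q-value, then by weighted mCHG level.
#'
#' @inheritParams test_introns
#' @param annotation A [genome_annotation()].
#' @param min_len Minimum intron length in bp (default 1000, inclusive).
#' @param background Optional precomputed intron background; estimated
#'   from all introns of the annotation when `NULL`.
#' @return Ranked `data.table` of intron test results (see
#'   [test_introns()]).
#' @export
screen_sensor_candidates <- function(allc, annotation, min_len = 1000L,
                                     alpha = 0.05, min_cov = 3L,
                                     background = NULL) {
  long <- select_long_introns(annotation, min_len = min_len)
  if (nrow(long) == 0L) {
    return(data.table::data.table(gene_id = character(), intron_rank = integer()))
  }
  if (is.null(background)) background <- intron_background(allc, annotation, min_cov)
  res <- test_introns(allc, long, background, alpha = alpha, min_cov = min_cov)
  data.table::setorder(res, q_CHG, -weighted_mCHG, na.last = TRUE)
  res[]
}
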