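#' Intersect cytosine records with a set of intervals
#'
#' Internal workhorse: returns the allc rows falling inside any of the
#' given 1-based closed intervals, carrying the interval's `gene_id`
#' (and any extra id columns) alongside.
#'
#' @noRd
sites_in_intervals <- function(allc, intervals,
                               carry = intersect(c("gene_id", "intron_rank"),
                                                 names(intervals))) {
  if (nrow(intervals) == 0L || nrow(allc) == 0L) {
    out <- allc[0]
    for (cl in carry) out[, (cl) := intervals[[cl]][0]]
    return(out)
  }
  iv <- intervals[, c("chrom", "start", "end", carry), with = FALSE]
  data.table::setkey(iv, chrom, start, end)
  pts <- data.table::copy(allc)
  pts[, `:=`(start = pos, end = pos)]
  hits <- data.table::foverlaps(pts, iv, by.x = c("chrom", "start", "end"),
                                nomatch = NULL)
  hits[, c("start", "end", "i.start", "i.end") := NULL]
  hits[]
}

#' Summarise per-context methylation over a gene's coding sequence
#'
#' For every gene in the annotation, counts eligible (coverage `>=
#' min_cov`) and called-methylated cytosines per context over the CDS
#' intervals of the primary transcript, on both strands, together with
#' coverage-weighted methylation levels and the CG-site coverage
#' statistics needed by the gbM eligibility rules.
#'
#' @param allc A called allc table (from [call_methylome()]).
#' @param annotation A [genome_annotation()].
#' @param min_cov Minimum coverage for a site to count as eligible
#'   (default 3).
#' @return `data.table`, one row per gene: per-context `n_sites_*`
#'   (eligible sites), `n_meth_*` (called methylated), `weighted_m*`
#'   (pooled mc/cov over the CDS), plus `n_cg_total` (all CG sites in the
#'   CDS), `n_cg_cov1` (CG sites with any read) and `n_cg_covered` (CG
#'   sites at coverage `>= min_cov`).
#' @export
summarize_gene_cds <- function(allc, annotation, min_cov = 3L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!"called" %in% names(allc)) stop("allc table lacks call flags; run call_methylome() first")
  hits <- sites_in_intervals(data.table::as.data.table(allc), annotation$cds)
  per_ctx <- hits[, .(
    n_sites = sum(cov >= min_cov),
    n_meth = sum(called %in% TRUE & cov >= min_cov),
    mc_sum = sum(as.numeric(mc)), cov_sum = sum(as.numeric(cov))
  ), by = .(gene_id, context)]
  cgstats <- hits[context == "CG", .(
    n_cg_total = .N,
    n_cg_cov1 = sum(cov >= 1L),
    n_cg_covered = sum(cov >= min_cov)
  ), by = gene_id]

  out <- data.table::data.table(gene_id = annotation$genes$gene_id)
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- per_ctx[context == ctx]
    out <- merge(out, sub[, .(gene_id, n_sites, n_meth,
                              w = data.table::fifelse(cov_sum > 0,
                                                      mc_sum / cov_sum, NA_real_))],
                 by = "gene_id", all.x = TRUE)
    data.table::setnames(out, c("n_sites", "n_meth", "w"),
                         paste0(c("n_sites_", "n_meth_", "weighted_m"), ctx))
  }
  out <- merge(out, cgstats, by = "gene_id", all.x = TRUE)
  for (cl in grep("^n_", names(out), value = TRUE)) {
    data.table::set(out, which(is.na(out[[cl]])), cl, 0L)
  }
  out[]
}

#' Species background methylation probabilities
#'
#' Pools called-methylated and eligible site counts per context over all
#' gene summaries and returns the fraction methylated — the background
#' probability that a single site of that context is methylated, used as
#' the null rate of the gene-level binomial tests.
#'
#' @param summaries Output of [summarize_gene_cds()] (or any table with
#'   `n_sites_*` / `n_meth_*` columns).
#' @param scope Label recording what the background was computed over
#'   (`"CDS"` or `"intron"`).
#' @return A `background_model`: list with `p_bg` (named fractions for
#'   CG/CHG/CHH) and `scope`.
#' @export
estimate_background <- function(summaries, scope = "CDS") {
  p_bg <- vapply(c("CG", "CHG", "CHH"), function(ctx) {
    ns <- sum(summaries[[paste0("n_sites_", ctx)]])
    if (ns == 0) stop("no eligible ", ctx, " sites: cannot estimate background")
    sum(summaries[[paste0("n_meth_", ctx)]]) / ns
  }, numeric(1))
  structure(list(p_bg = p_bg, scope = scope), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("Background methylation model (", x$scope, " scope)\n", sep = "")
  print(signif(x$p_bg, 4))
  invisible(x)
}

#' Classify genes as gene-body methylated (gbM)
#'
#' Tests each gene's per-context methylated-site count against the
#' species background with an upper-tail binomial, adjusts p-values per
#' context across genes (Benjamini-Hochberg), and labels a gene `gbM`
#' when it shows significantly elevated mCG (`q_CG < q_lo`) with no
#' evidence of non-CG methylation (`q_CHG > q_hi` and `q_CHH > q_hi`),
#' provided reads map to at least `min_cg` CG sites. A gene is
#' `unclassified` when coverage eligibility fails: fewer than
#' `min_cov_frac` of its CDS CG sites reach the minimum calling coverage.
#' All remaining genes are `non-gbM`.
#'
#' An auxiliary `tem_like` flag marks genes with significant non-CG
#' methylation (`q_CHG < q_lo` or `q_CHH < q_lo`), the signature of
#' TE-like / ectopic methylation.
#'
#' @param summaries Output of [summarize_gene_cds()].
#' @param background A `background_model` from [estimate_background()].
#' @param q_lo q-value below which a context is called methylated
#'   (default 0.05).
#' @param q_hi q-value above which a context is considered unmethylated
#'   (default 0.95).
#' @param min_cg Minimum number of CG sites with mapped reads (default 20).
#' @param min_cov_frac Minimum fraction of CDS CG sites at calling
#'   coverage for the gene to be classifiable (default 0.40).
#' @param min_cg_cov Coverage defining "reads mapping to" a CG site for
#'   the `min_cg` rule (default 1).
#' @param use_raw_p If `TRUE`, threshold raw binomial p-values instead of
#'   BH q-values (the adjustment column is still reported).
#' @return The summaries with `p_*`, `q_*` per context, `tem_like`, and a
#'   `label` column in `{gbM, non-gbM, unclassified}`.
#' @export
classify_gbm <- function(summaries, background, q_lo = 0.05, q_hi = 0.95,
                         min_cg = 20L, min_cov_frac = 0.40, min_cg_cov = 1L,
                         use_raw_p = FALSE) {
  stopifnot(inherits(background, "background_model"))
  dt <- data.table::as.data.table(summaries)
  for (ctx in c("CG", "CHG", "CHH")) {
    if (is.na(background$p_bg[ctx])) stop("background missing context ", ctx)
    p <- binom_tail(dt[[paste0("n_meth_", ctx)]],
                    dt[[paste0("n_sites_", ctx)]], background$p_bg[[ctx]])
    dt[, (paste0("p_", ctx)) := p]
    dt[, (paste0("q_", ctx)) := bh_fdr(p)]
  }
  qc <- function(ctx) if (use_raw_p) dt[[paste0("p_", ctx)]] else dt[[paste0("q_", ctx)]]
  eligible <- dt$n_cg_total > 0L &
    (dt$n_cg_covered / pmax(dt$n_cg_total, 1L)) >= min_cov_frac
  is_gbm <- eligible & dt$n_cg_cov1 >= min_cg &
    qc("CG") < q_lo & qc("CHG") > q_hi & qc("CHH") > q_hi
  dt[, tem_like := eligible & (qc("CHG") < q_lo | qc("CHH") < q_lo)]
  dt[, label := data.table::fifelse(!eligible, "unclassified",
                 data.table::fifelse(is_gbm, "gbM", "non-gbM"))]
  dt[]
}

#' Genome-wide gbM ratio
#'
#' The fraction of classifiable genes labelled gbM: number of gbM genes
#' divided by the count of genes with adequate coverage (gbM plus
#' non-gbM; unclassified genes are excluded from the denominator).
#'
#' @param labels Character vector of labels, or a classified table with a
#'   `label` column.
#' @return A fraction, or `NA` when no gene is classifiable.
#' @export
gbm_ratio <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  n_elig <- sum(labels %in% c("gbM", "non-gbM"))
  if (n_elig == 0L) return(NA_real_)
  sum(labels == "gbM") / n_elig
}
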