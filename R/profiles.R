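#' Per-site methylation level distribution
#'
#' Site-level methylation ratios (mc/cov) for one context, restricted to
#' sites with at least `min_cov` reads and some evidence of methylation:
#' by default at least one methylated read (`inclusion = "mc1"`), or a
#' positive methylation call (`inclusion = "called"`).
#'
#' @param allc An allc table (called when `inclusion = "called"`).
#' @param context Context class to profile (default `"CHG"`).
#' @param subcontext Optional CHG subcontext filter (`"CWG"` or `"CCG"`).
#' @param min_cov Minimum coverage (default 3).
#' @param inclusion Site-inclusion rule (see above).
#' @return `data.table` with `chrom`, `pos`, `strand`, `level`.
#' @export
per_site_levels <- function(allc, context = "CHG", subcontext = NULL,
                            min_cov = 3L, inclusion = c("mc1", "called")) {
  inclusion <- match.arg(inclusion)
  ctx <- context
  dt <- data.table::as.data.table(allc)[context == ctx & cov >= min_cov]
  if (!is.null(subcontext)) {
    sctx <- subcontext
    dt <- dt[subcontext == sctx]
  }
  dt <- if (inclusion == "mc1") dt[mc >= 1L] else dt[called %in% TRUE]
  dt[, .(chrom, pos, strand, level = mc / cov)]
}

#' Pair CWG cytosines across strands
#'
#' A CWG triplet (W = A or T) is its own reverse complement as a context:
#' the plus-strand cytosine at position p and the minus-strand cytosine
#' at p+2 form a symmetric pair targeted by CMT3. CCG sites are excluded
#' because their methylation additionally depends on MET1. Pairs are
#' retained only when both strands have coverage of at least `min_cov`
#' reads and (by default) the pair shows at least one methylated read.
#'
#' @param allc A called allc table.
#' @param genome Optional `DNAStringSet`; when given, each pair's
#'   plus-strand trinucleotide is verified against the reference and a
#'   mismatch raises an error.
#' @param min_cov Per-strand minimum coverage (default 3).
#' @param require_meth Drop pairs with zero methylated reads on both
#'   strands (default `TRUE`).
#' @return `data.table`, one row per pair: `chrom`, `pos` (plus-strand
#'   C), counts and call flags for both strands, and `symmetry_class` in
#'   `{symmetric, plus_only, minus_only, neither}` (symmetric = both
#'   strands called methylated).
#' @export
pair_cwg_sites <- function(allc, genome = NULL, min_cov = 3L,
                           require_meth = TRUE) {
  dt <- data.table::as.data.table(allc)
  plus <- dt[strand == "+" & subcontext == "CWG",
             .(chrom, pos, trinuc_plus = trinuc, mc_plus = mc, cov_plus = cov,
               called_plus = called)]
  minus <- dt[strand == "-" & subcontext == "CWG",
              .(chrom, pos = pos - 2L, trinuc_minus = trinuc, mc_minus = mc,
                cov_minus = cov, called_minus = called)]
  pairs <- merge(plus, minus, by = c("chrom", "pos"))
  if (nrow(pairs)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(pairs$trinuc_plus)))
    if (any(rc != pairs$trinuc_minus)) {
      stop("strand-inconsistent trinucleotides at ",
           sum(rc != pairs$trinuc_minus), " CWG pair(s)")
    }
    if (!is.null(genome)) {
      ref <- as.character(Biostrings::subseq(
        genome[pairs$chrom], start = pairs$pos, end = pairs$pos + 2L))
      if (any(ref != pairs$trinuc_plus)) {
        stop("reference mismatch at ", sum(ref != pairs$trinuc_plus),
             " CWG pair(s)")
      }
    }
  }
  pairs <- pairs[cov_plus >= min_cov & cov_minus >= min_cov]
  if (require_meth) pairs <- pairs[mc_plus + mc_minus >= 1L]
  pairs[, symmetry_class := data.table::fcase(
    called_plus %in% TRUE & called_minus %in% TRUE, "symmetric",
    called_plus %in% TRUE, "plus_only",
    called_minus %in% TRUE, "minus_only",
    default = "neither")]
  pairs[]
}

#' Summarise CWG strand symmetry
#'
#' Counts and fractions of strand-symmetry classes over paired CWG
#' sites, plus the per-pair strand-level table. A predominantly
#' symmetric pattern indicates active CMT3-type maintenance; asymmetric
#' mCWG is the signature of species or accessions lacking it.
#'
#' @param pairs Output of [pair_cwg_sites()].
#' @return List with `counts` (`data.table` of class/n/fraction) and
#'   `levels` (per-pair plus/minus methylation levels).
#' @export
symmetry_summary <- function(pairs) {
  classes <- c("symmetric", "plus_only", "minus_only", "neither")
  if (nrow(pairs) == 0L) {
    return(list(counts = data.table::data.table(symmetry_class = classes,
                                                n = 0L, fraction = NA_real_),
                levels = data.table::data.table()))
  }
  counts <- pairs[, .(n = .N), by = symmetry_class]
  counts <- merge(data.table::data.table(symmetry_class = classes), counts,
                  by = "symmetry_class", all.x = TRUE)
  counts[is.na(n), n := 0L]
  counts[, fraction := n / sum(n)]
  counts <- counts[match(classes, symmetry_class)]
  levels <- pairs[, .(chrom, pos, level_plus = mc_plus / cov_plus,
                      level_minus = mc_minus / cov_minus, symmetry_class)]
  list(counts = counts[], levels = levels)
}

# window index for offsets in [0, len) split into n equal real-valued bins
window_index <- function(offset, len, n) {
  pmin(as.integer(floor(offset * n / len)) + 1L, n)
}

#' Weighted-methylation metaplot over features
#'
#' Divides each feature body into `n_windows` equal windows and the
#' `flank` bp upstream and downstream into `n_windows` windows each,
#' orients windows 5' to 3' (minus-strand features reversed), and
#' summarises methylation per window: the pooled coverage-weighted level
#' (sum mc / sum cov across all features) and the cross-feature mean of
#' per-feature window levels. The cross-feature mean is the default
#' plotted quantity; the pooled level satisfies the exact identity that
#' its coverage-weighted average over body windows equals the whole-body
#' weighted level.
#'
#' @param allc An allc table.
#' @param features Interval table with `chrom`, `start`, `end`, `strand`
#'   and a feature id column (`gene_id` or `feature_id`).
#' @param context Context class to profile (default `"CG"`).
#' @param n_windows Windows per region (default 20).
#' @param flank Flank span in bp (default 1000).
#' @return `data.table` with `region` (`upstream`, `body`,
#'   `downstream`), `window` (1..n, 5' to 3'), `mc`, `cov`,
#'   `weighted_level` (pooled) and `mean_level` (cross-feature mean).
#'   Features shorter than `n_windows` bp are skipped (with a message).
#' @export
metaplot <- function(allc, features, context = "CG", n_windows = 20L,
                     flank = 1000L) {
  feats <- data.table::as.data.table(features)
  if (!"feature_id" %in% names(feats)) {
    if ("gene_id" %in% names(feats)) {
      feats[, feature_id := gene_id]
    } else feats[, feature_id := paste0("feat", seq_len(.N))]
  }
  short <- feats[end - start + 1L < n_windows]
  if (nrow(short)) {
    message("skipping ", nrow(short), " feature(s) shorter than ", n_windows, " bp")
    feats <- feats[end - start + 1L >= n_windows]
  }
  ctx <- context
  sites <- data.table::as.data.table(allc)[context == ctx,
                                           .(chrom, pos, mc, cov)]
  regions <- data.table::rbindlist(list(
    feats[, .(feature_id, chrom, strand, fstart = start, fend = end,
              start = start - flank, end = start - 1L, region = "left")],
    feats[, .(feature_id, chrom, strand, fstart = start, fend = end,
              start, end, region = "body")],
    feats[, .(feature_id, chrom, strand, fstart = start, fend = end,
              start = end + 1L, end = end + flank, region = "right")]))
  regions <- regions[end >= start]
  data.table::setkey(regions, chrom, start, end)
  pts <- sites[, .(chrom, pos, mc, cov, start = pos, end = pos)]
  hits <- data.table::foverlaps(pts, regions, by.x = c("chrom", "start", "end"),
                                nomatch = NULL)
  if (nrow(hits) == 0L) {
    return(data.table::data.table(region = character(), window = integer(),
                                  mc = numeric(), cov = numeric(),
                                  weighted_level = numeric(),
                                  mean_level = numeric()))
  }
  hits[, len := end - start + 1L]
  hits[, offset := data.table::fifelse(strand == "-", end - pos, pos - start)]
  hits[, window := window_index(offset, len, n_windows)]
  # genomic left/right flanks -> transcriptional up/downstream
  hits[, region := data.table::fcase(
    region == "body", "body",
    (region == "left") == (strand != "-"), "upstream",
    default = "downstream")]
  per_feat <- hits[, .(mc = sum(as.numeric(mc)), cov = sum(as.numeric(cov))),
                   by = .(feature_id, region, window)]
  out <- per_feat[, .(
    mc = sum(mc), cov = sum(cov),
    weighted_level = if (sum(cov) > 0) sum(mc) / sum(cov) else NA_real_,
    mean_level = mean((mc / cov)[cov > 0])
  ), by = .(region, window)]
  grid <- data.table::CJ(region = c("upstream", "body", "downstream"),
                         window = seq_len(n_windows))
  out <- merge(grid, out, by = c("region", "window"), all.x = TRUE)
  out[is.na(mc), `:=`(mc = 0, cov = 0)]
  out[, region := factor(region, levels = c("upstream", "body", "downstream"))]
  data.table::setorder(out, region, window)
  out[]
}
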