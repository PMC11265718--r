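#' Estimate the bisulfite non-conversion rate from an unmethylated control
#'
#' Pools methylated and total read counts over every cytosine of one or
#' more fully unmethylated control sequences (chloroplast or spiked-in
#' lambda DNA) and returns their ratio as the non-conversion rate p0 —
#' the per-read probability that an unmethylated cytosine escapes
#' conversion. Counts are pooled across sequences, not averaged per
#' sequence, so deeply covered controls weigh more.
#'
#' @param allc An allc `data.table` (see [read_allc()]).
#' @param control_seqs Character vector of control sequence names
#'   (matched against `chrom`).
#' @param p0_floor Lower bound applied to p0 (default `1e-4`), so a
#'   finite control that happens to show zero non-conversion never
#'   produces degenerate zero p-values downstream.
#' @return A `conversion_control` object: list with `control_seqs`,
#'   `mc_total`, `cov_total`, `p0`.
#' @export
estimate_nonconversion <- function(allc, control_seqs, p0_floor = 1e-4) {
  ctrl <- allc[allc$chrom %in% control_seqs]
  cov_total <- sum(as.numeric(ctrl$cov))
  if (cov_total == 0) {
    stop("control sequences ", paste(control_seqs, collapse = ","),
         " have zero total coverage")
  }
  mc_total <- sum(as.numeric(ctrl$mc))
  p0 <- max(mc_total / cov_total, p0_floor)
  if (p0 > 0.5) {
    warning("non-conversion rate ", signif(p0, 3),
            " > 0.5: control sequence is likely mislabelled or methylated")
  }
  structure(list(control_seqs = control_seqs, mc_total = mc_total,
                 cov_total = cov_total, p0 = p0),
            class = "conversion_control")
}

#' @export
print.conversion_control <- function(x, ...) {
  cat("Bisulfite non-conversion control\n",
      "  sequences: ", paste(x$control_seqs, collapse = ", "), "\n",
      "  pooled counts: ", x$mc_total, " / ", x$cov_total, "\n",
      "  p0 = ", signif(x$p0, 4), "\n", sep = "")
  invisible(x)
}

#' Upper-tail binomial probability
#'
#' P(X >= mc) for X ~ Binomial(cov, p): the probability of observing at
#' least the given number of methylated reads by chance at background
#' rate `p`. Vectorised over all arguments.
#'
#' @param mc Observed methylated counts.
#' @param cov Total counts.
#' @param p Background success probability in \[0, 1\].
#' @return Numeric vector of upper-tail p-values.
#' @export
binom_tail <- function(mc, cov, p) {
  if (any(p < 0 | p > 1)) stop("background probability outside [0,1]")
  if (any(mc < 0 | mc > cov)) stop("mc must satisfy 0 <= mc <= cov")
  stats::pbinom(mc - 1, cov, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Adjusts p-values with the Benjamini-Hochberg false-discovery-rate
#' procedure; output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Binomial test for one cytosine site
#'
#' Computes the site-level upper-tail binomial p-value against the
#' non-conversion rate and the coverage-eligibility flag. A site is
#' eligible for calling only with coverage of at least `min_cov` reads
#' (default 3).
#'
#' @param mc,cov Methylated and total read counts (vectorised).
#' @param p0 Non-conversion rate (scalar or a `conversion_control`).
#' @param min_cov Minimum coverage for a site to be callable (default 3).
#' @return `data.table` with `p_value` and `eligible`.
#' @export
call_site <- function(mc, cov, p0, min_cov = 3L) {
  if (inherits(p0, "conversion_control")) p0 <- p0$p0
  data.table::data.table(p_value = binom_tail(mc, cov, p0),
                         eligible = cov >= min_cov)
}

#' Call the methylation status of every cytosine
#'
#' For each record, tests whether the methylated-read count exceeds what
#' the bisulfite non-conversion rate alone would produce (upper-tail
#' binomial), adjusts p-values with Benjamini-Hochberg FDR, and flags
#' sites with `q < alpha` as methylated. Only sites with coverage
#' `>= min_cov` are tested; ineligible sites are retained with `called =
#' NA` so downstream coverage-eligibility rules can still see them.
#'
#' By default the FDR correction is stratified by context class (CG, CHG,
#' CHH run as separate families), since the background fraction of
#' methylated sites differs by orders of magnitude between contexts.
#'
#' @param allc An allc `data.table`.
#' @param control A `conversion_control` from [estimate_nonconversion()],
#'   or a numeric non-conversion rate.
#' @param alpha FDR threshold for calling a site methylated (default 0.05).
#' @param min_cov Minimum coverage (default 3).
#' @param stratify_context Run BH separately per context class (default
#'   `TRUE`).
#' @return The input table with `p_value`, `q_value`, `eligible` and
#'   `called` columns added (a modified copy).
#' @export
call_methylome <- function(allc, control, alpha = 0.05, min_cov = 3L,
                           stratify_context = TRUE) {
  p0 <- if (inherits(control, "conversion_control")) control$p0 else control
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop("invalid non-conversion rate")
  dt <- data.table::as.data.table(allc)
  if (nrow(dt) == 0L) {
    dt[, `:=`(p_value = numeric(), q_value = numeric(),
              eligible = logical(), called = logical())]
    return(dt[])
  }
  dt[, p_value := binom_tail(mc, cov, p0)]
  dt[, eligible := cov >= min_cov]
  dt[, q_value := NA_real_]
  if (stratify_context) {
    dt[eligible == TRUE, q_value := bh_fdr(p_value), by = context]
  } else {
    dt[eligible == TRUE, q_value := bh_fdr(p_value)]
  }
  dt[, called := data.table::fifelse(eligible, q_value < alpha, NA)]
  dt[]
}
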