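#' Analyse a simulated accession panel end to end
#'
#' Runs the full single-accession pipeline (non-conversion estimation,
#' site calling, CDS summarisation, background estimation, gbM
#' classification) for every accession of a simulated panel, measures
#' each accession's sensor-intron weighted mCHG, then performs the
#' population ectopic scan and ibm1-like flagging. Accessions are
#' processed one at a time so memory stays flat.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param alpha Site/gene q-value threshold (default 0.05).
#' @param freq_min Population gbM frequency threshold (default 0.90).
#' @param threshold,strict ibm1-like flagging parameters (default
#'   `n_ectopic > 120`).
#' @param min_cov Minimum site coverage (default 3).
#' @return List with `accessions` (per-accession ectopic counts,
#'   `ibm1_like` flag, `sensor_mchg`), `ectopic_calls`, `gbm_freq`, and
#'   `panel_long` (accession x gene labels and q-values).
#' @export
analyze_panel <- function(panel, alpha = 0.05, freq_min = 0.90,
                          threshold = 120L, strict = TRUE, min_cov = 3L) {
  stopifnot(inherits(panel, "sim_panel"))
  sensor_iv <- panel$sensor
  per_acc <- lapply(panel$truth_accessions$accession, function(acc) {
    allc <- panel_accession_allc(panel, acc)
    control <- estimate_nonconversion(allc, panel$control_seqs)
    called <- call_methylome(allc, control, alpha = alpha, min_cov = min_cov)
    summ <- summarize_gene_cds(called, panel$annotation, min_cov = min_cov)
    bg <- estimate_background(summ)
    cls <- classify_gbm(summ, bg)
    sens <- sites_in_intervals(called[context == "CHG"], sensor_iv,
                               carry = character())
    list(cls = cls[, .(accession = acc, gene_id, label, q_CG, q_CHG, q_CHH,
                       weighted_mCHG)],
         sensor = data.table::data.table(
           accession = acc, sensor_mchg = weighted_level(sens$mc, sens$cov)))
  })
  panel_long <- data.table::rbindlist(lapply(per_acc, `[[`, "cls"))
  sensor <- data.table::rbindlist(lapply(per_acc, `[[`, "sensor"))
  scan <- call_ectopic_genes(panel_long, alpha = alpha, freq_min = freq_min)
  flags <- flag_ibm1_like(scan$counts, threshold = threshold, strict = strict)
  accs <- merge(flags, sensor, by = "accession")
  list(accessions = accs[], ectopic_calls = scan$calls,
       gbm_freq = scan$gbm_freq, panel_long = panel_long)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_kv <- function(...) {
  kv <- list(...)
  message(paste(names(kv), vapply(kv, format, character(1)), sep = "=",
                collapse = " "))
}

#' Run the full synthetic-data pipeline
#'
#' Chains every stage on one configuration: simulate genome and
#' methylome, estimate the non-conversion rate, call sites, classify gbM
#' genes and compute the gbM ratio, screen long introns for mCHG
#' enrichment, run the CWG strand-symmetry analysis, compute
#' region-stratified population-genetic statistics, and the isoform
#' ratio-shift analysis. Per-stage TSVs and a versioned summary JSON are
#' written to `outdir`; thresholds in use are logged as key=value lines.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param alpha,q_hi,min_cg,min_cov_frac,min_cov,min_len,delta_shift
#'   Analysis thresholds (defaults: 0.05, 0.95, 20, 0.40, 3, 1000, 2).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir, alpha = 0.05,
                         q_hi = 0.95, min_cg = 20L, min_cov_frac = 0.40,
                         min_cov = 3L, min_len = 1000L, delta_shift = 2) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_kv(seed = cfg$seed, alpha = alpha, q_hi = q_hi, min_cg = min_cg,
         min_cov_frac = min_cov_frac, min_cov = min_cov, min_len = min_len,
         delta_shift = delta_shift)

  sim <- stage("simulate", simulate_genome(cfg))
  meth <- stage("simulate", simulate_methylome(sim))
  control <- stage("call", estimate_nonconversion(meth$allc, "chrC"))
  called <- stage("call", call_methylome(meth$allc, control, alpha = alpha,
                                         min_cov = min_cov))
  write_allc(called[, .(chrom, pos, strand, trinuc, mc, cov, called)],
             file.path(outdir, "called.allc.tsv"))
  log_kv(p0 = signif(control$p0, 4), n_sites = nrow(called))

  summ <- stage("classify", summarize_gene_cds(called, sim$annotation,
                                               min_cov = min_cov))
  bg <- stage("classify", estimate_background(summ))
  cls <- stage("classify", classify_gbm(summ, bg, q_lo = alpha, q_hi = q_hi,
                                        min_cg = min_cg,
                                        min_cov_frac = min_cov_frac))
  data.table::fwrite(cls, file.path(outdir, "genes.tsv"), sep = "\t")
  ratio <- gbm_ratio(cls)

  screen <- stage("intron-test",
                  screen_sensor_candidates(called, sim$annotation,
                                           min_len = min_len, alpha = alpha,
                                           min_cov = min_cov))
  data.table::fwrite(screen, file.path(outdir, "intron_tests.tsv"), sep = "\t")

  meta <- stage("metaplot", metaplot(called, sim$annotation$genes,
                                     context = "CG"))
  data.table::fwrite(meta, file.path(outdir, "metaplot_mCG.tsv"), sep = "\t")

  cwg_sim <- stage("symmetry", simulate_cwg(cfg))
  cwg_called <- stage("symmetry", call_methylome(cwg_sim$allc, control$p0,
                                                 alpha = alpha,
                                                 min_cov = min_cov))
  pairs <- stage("symmetry", pair_cwg_sites(cwg_called))
  symm <- stage("symmetry", symmetry_summary(pairs))
  data.table::fwrite(symm$counts, file.path(outdir, "cwg_symmetry.tsv"),
                     sep = "\t")

  snp_sim <- stage("popgen", simulate_snp_matrix(cfg))
  popgen <- stage("popgen", popgen_by_region(snp_sim$snp, snp_sim$regions))
  data.table::fwrite(popgen, file.path(outdir, "popgen.tsv"), sep = "\t")

  ab <- stage("isoform", simulate_abundance(cfg))
  ratios <- stage("isoform", isoform_ratio(ab$abundance, ab$pairs,
                                           ab$conditions))
  shifts <- stage("isoform",
                  ratio_shift_genes(ratios[condition == "A"],
                                    ratios[condition == "B"],
                                    delta = delta_shift))
  data.table::fwrite(ratios, file.path(outdir, "isoform_ratios.tsv"), sep = "\t")

  summary <- list(
    schema_version = 1L,
    seed = cfg$seed,
    p0 = control$p0,
    gbm_ratio = ratio,
    n_genes = nrow(cls),
    n_gbm = sum(cls$label == "gbM"),
    n_unclassified = sum(cls$label == "unclassified"),
    n_long_introns = nrow(screen),
    n_enriched_introns = if (nrow(screen)) sum(screen$enriched, na.rm = TRUE) else 0L,
    symmetry_fractions = stats::setNames(as.list(symm$counts$fraction),
                                         symm$counts$symmetry_class),
    popgen = popgen,
    n_ratio_shift_genes = nrow(shifts))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}
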