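# Synthetic-data generators: genomes, methylomes, accession panels, CWG
# pairs, SNP matrices and abundance tables with the statistical structure
# the analysis modules assume. Every generator is a pure function of its
# config: the seed fully determines the output and the caller's RNG state
# is restored afterwards.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %% 2147483629 + 1)
}

#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator. Defaults
#' encode the study conditions the analysis is validated under; see the
#' methods vignette for the rationale behind each value.
#'
#' @param seed Integer seed; fully determines every generator's output.
#' @param ... Named overrides of the defaults listed below.
#' @return A `sim_config` list.
#'
#' @section Default parameters:
#' * Methylome: `depth = 10` (Poisson mean coverage), `p0 = 0.005`
#'   (bisulfite non-conversion), levels `level_gbm_cg = 0.8`,
#'   `level_bg_cg = 0.02`, `level_chg = 0.01`, `level_chh = 0.01`,
#'   TE levels `te_cg = 0.9`, `te_chg = 0.7`, `te_chh = 0.1`, planted
#'   sensor-intron `sensor_mchg = 0.4`.
#' * Gene scaffold: `n_genes = 2000`, `gbm_fraction = 0.3`,
#'   `n_cg_per_gene = 30`, `n_chg_per_gene = 30`, `n_chh_per_gene = 60`,
#'   `gene_span = 1000`, `n_control_sites = 20000`.
#' * Sequence genome: `seq_n_genes = 80`, `exon_len = 200`,
#'   `intron_len = 150`, `long_intron_len = 1500`,
#'   `n_long_intron_genes = 1` (methylated sensor introns),
#'   `n_clean_long_introns = 10` (long introns at background methylation),
#'   `utr_len = 10`, `intergenic_len = 200`, `n_te = 10`, `te_len = 800`,
#'   `control_len = 20000`.
#' * Panel: `n_accessions = 50`, `n_ibm1_like = 5`,
#'   `n_ectopic_per_ibm1 = 150`, `ectopic_mchg = 0.3`,
#'   `base_ectopic_max = 20`, `sensor_mchg_high = 0.08`,
#'   `sensor_mchg_low = 0.01`, `n_sensor_chg = 100`.
#' * CWG: `n_pairs = 2000`, `cwg_depth = 20`, `cwg_regime = "coupled"`,
#'   `cwg_meth_prob = 0.8`, `cwg_read_level = 0.8`.
#' * SNPs: `n_hap = 20`, `snp_rates = c(CDS = 0.002,
#'   methylated_intron = 0.006, unmethylated_intron = 0.002)`,
#'   `region_lengths = c(CDS = 3000, methylated_intron = 2000,
#'   unmethylated_intron = 3000)`.
#' * Abundance: `n_abund_genes = 500`, `n_shifted = 10`,
#'   `shift_delta = 5`, `ratio_noise_sd = 0.3`, `abund_reps = 2`,
#'   `abund_noise_sd = 0`.
#' @export
sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    # methylome count model
    depth = 10, p0 = 0.005,
    level_gbm_cg = 0.8, level_bg_cg = 0.02, level_chg = 0.01,
    level_chh = 0.01, te_cg = 0.9, te_chg = 0.7, te_chh = 0.1,
    sensor_mchg = 0.4,
    # site-scaffold genomes (no sequence)
    n_genes = 2000L, gbm_fraction = 0.3, n_cg_per_gene = 30L,
    n_chg_per_gene = 30L, n_chh_per_gene = 60L, gene_span = 1000L,
    n_control_sites = 20000L,
    # sequence-backed genomes
    seq_n_genes = 80L, exon_len = 200L, intron_len = 150L,
    long_intron_len = 1500L, n_long_intron_genes = 1L,
    n_clean_long_introns = 10L, utr_len = 10L,
    intergenic_len = 200L, n_te = 10L, te_len = 800L, control_len = 20000L,
    # accession panel
    n_accessions = 50L, n_ibm1_like = 5L, n_ectopic_per_ibm1 = 150L,
    ectopic_mchg = 0.3, base_ectopic_max = 20L, sensor_mchg_high = 0.08,
    sensor_mchg_low = 0.01, n_sensor_chg = 100L,
    # CWG strand pairs
    n_pairs = 2000L, cwg_depth = 20, cwg_regime = "coupled",
    cwg_meth_prob = 0.8, cwg_read_level = 0.8,
    # SNP matrices
    n_hap = 20L,
    snp_rates = c(CDS = 0.002, methylated_intron = 0.006,
                  unmethylated_intron = 0.002),
    region_lengths = c(CDS = 3000L, methylated_intron = 2000L,
                       unmethylated_intron = 3000L),
    # abundance tables
    n_abund_genes = 500L, n_shifted = 10L, shift_delta = 5,
    ratio_noise_sd = 0.3, abund_reps = 2L, abund_noise_sd = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  probs <- unlist(cfg[c("p0", "level_gbm_cg", "level_bg_cg", "level_chg",
                        "level_chh", "te_cg", "te_chg", "te_chh",
                        "sensor_mchg", "gbm_fraction", "ectopic_mchg",
                        "cwg_meth_prob", "cwg_read_level")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  structure(cfg, class = "sim_config")
}

# cov ~ Poisson(depth); mc ~ Binomial(cov, level + (1 - level) * p0).
# Folding non-conversion into the read-level success probability makes the
# site caller's null exactly correct at level 0.
draw_counts <- function(skeleton, cfg, depth = cfg$depth) {
  dt <- data.table::copy(skeleton)
  n <- nrow(dt)
  dt[, cov := stats::rpois(n, depth)]
  dt[, mc := stats::rbinom(n, cov, level + (1 - level) * cfg$p0)]
  dt
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a sequence-backed genome with annotation
#'
#' Generates a random chromosome carrying multi-exon genes (a configured
#' number of which contain a long, >= 1 kb intron — the planted
#' heterochromatin-sensor candidates), TE intervals, and a fully
#' unmethylated control contig (`chrC`) emulating the chloroplast used
#' for non-conversion estimation.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_genome` list: `genome` (`DNAStringSet`), `annotation`
#'   ([genome_annotation()]), `truth_genes` (`gene_id`, `compartment` in
#'   `{gbM, background}`), `sensor` (gene/rank of planted long introns),
#'   `config`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$seq_n_genes
    n_long <- cfg$n_long_intron_genes + cfg$n_clean_long_introns
    if (n_long > n) stop("more long-intron genes than genes")
    long_genes <- sample.int(n, n_long)
    # methylated sensor introns vs clean (background-level) long introns
    sensor_genes <- sort(long_genes[seq_len(cfg$n_long_intron_genes)])
    clean_genes <- sort(setdiff(long_genes, sensor_genes))
    pieces <- character()
    cursor <- 0L
    genes <- list(); exons <- list(); cds <- list(); utr5 <- list(); utr3 <- list()
    sensor <- list()
    for (i in seq_len(n)) {
      gap <- cfg$intergenic_len + sample.int(100L, 1L)
      pieces <- c(pieces, rand_seq(gap)); cursor <- cursor + gap
      has_long <- i %in% sensor_genes || i %in% clean_genes
      n_ex <- if (has_long) 3L else sample(2:3, 1L)
      ex_lens <- cfg$exon_len + sample.int(100L, n_ex)
      in_lens <- cfg$intron_len + sample.int(80L, max(n_ex - 1L, 0L))
      strand <- sample(c("+", "-"), 1L)
      if (has_long) {
        # plant the long intron as the transcript's first intron
        k_genomic <- if (strand == "-") n_ex - 1L else 1L
        in_lens[k_genomic] <- cfg$long_intron_len
        if (i %in% sensor_genes) {
          sensor[[length(sensor) + 1L]] <- data.table::data.table(
            gene_id = sprintf("g%04d", i), intron_rank = 1L)
        }
      }
      gstart <- cursor + 1L
      ex_start <- gstart
      ex_iv <- list()
      for (j in seq_len(n_ex)) {
        ex_iv[[j]] <- c(ex_start, ex_start + ex_lens[j] - 1L)
        pieces <- c(pieces, rand_seq(ex_lens[j]))
        cursor <- cursor + ex_lens[j]
        if (j < n_ex) {
          pieces <- c(pieces, rand_seq(in_lens[j]))
          cursor <- cursor + in_lens[j]
          ex_start <- cursor + 1L
        }
      }
      gend <- cursor
      gid <- sprintf("g%04d", i)
      genes[[i]] <- data.table::data.table(
        gene_id = gid, tx_id = paste0(gid, ".1"), chrom = "chr1",
        strand = strand, start = gstart, end = gend)
      ex_dt <- data.table::data.table(
        gene_id = gid, chrom = "chr1", strand = strand,
        start = vapply(ex_iv, `[`, integer(1), 1L),
        end = vapply(ex_iv, `[`, integer(1), 2L))
      exons[[i]] <- ex_dt
      # UTRs occupy the transcript's terminal utr_len bases
      u <- cfg$utr_len
      left_utr <- data.table::data.table(gene_id = gid, chrom = "chr1",
        strand = strand, start = gstart, end = gstart + u - 1L)
      right_utr <- data.table::data.table(gene_id = gid, chrom = "chr1",
        strand = strand, start = gend - u + 1L, end = gend)
      utr5[[i]] <- if (strand == "+") left_utr else right_utr
      utr3[[i]] <- if (strand == "+") right_utr else left_utr
      cds_dt <- data.table::copy(ex_dt)
      cds_dt[start == gstart, start := gstart + u]
      cds_dt[end == gend, end := gend - u]
      cds[[i]] <- cds_dt[start <= end]
    }
    te <- NULL
    if (cfg$n_te > 0) {
      te_start <- integer(cfg$n_te)
      for (k in seq_len(cfg$n_te)) {
        gap <- 100L + sample.int(100L, 1L)
        pieces <- c(pieces, rand_seq(gap)); cursor <- cursor + gap
        te_start[k] <- cursor + 1L
        pieces <- c(pieces, rand_seq(cfg$te_len)); cursor <- cursor + cfg$te_len
      }
      te <- data.table::data.table(chrom = "chr1", start = te_start,
                                   end = te_start + cfg$te_len - 1L,
                                   te_class = "TE")
    }
    pieces <- c(pieces, rand_seq(100L)); cursor <- cursor + 100L
    chr1 <- paste(pieces, collapse = "")
    genome <- Biostrings::DNAStringSet(c(chr1 = chr1,
                                         chrC = rand_seq(cfg$control_len)))
    ann <- genome_annotation(
      genes = data.table::rbindlist(genes), exons = data.table::rbindlist(exons),
      cds = data.table::rbindlist(cds), utr5 = data.table::rbindlist(utr5),
      utr3 = data.table::rbindlist(utr3), te = te,
      chrom_lengths = c(chr1 = nchar(chr1), chrC = cfg$control_len))
    gbm <- sample(c(TRUE, FALSE), n, replace = TRUE,
                  prob = c(cfg$gbm_fraction, 1 - cfg$gbm_fraction))
    truth_genes <- data.table::data.table(
      gene_id = sprintf("g%04d", seq_len(n)),
      compartment = data.table::fifelse(gbm, "gbM", "background"))
    structure(list(genome = genome, annotation = ann,
                   truth_genes = truth_genes,
                   sensor = data.table::rbindlist(sensor), config = cfg),
              class = "sim_genome")
  })
}

# assign per-site true methylation levels on an extracted cytosine skeleton
assign_levels <- function(skeleton, sim, cfg) {
  dt <- data.table::copy(skeleton)
  dt[, level := 0]
  # baseline: nuclear chromosome gets context backgrounds
  nuclear <- dt$chrom != "chrC"
  dt[nuclear & context == "CG", level := cfg$level_bg_cg]
  dt[nuclear & context == "CHG", level := cfg$level_chg]
  dt[nuclear & context == "CHH", level := cfg$level_chh]
  tag <- function(intervals) {
    if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, nrow(dt)))
    hits <- sites_in_intervals(dt[, .(chrom, pos, strand)],
                               data.table::as.data.table(intervals),
                               carry = character())
    paste(dt$chrom, dt$pos, dt$strand) %in% paste(hits$chrom, hits$pos, hits$strand)
  }
  gbm_ids <- sim$truth_genes[compartment == "gbM", gene_id]
  in_gbm <- tag(sim$annotation$genes[gene_id %in% gbm_ids])
  dt[in_gbm & context == "CG", level := cfg$level_gbm_cg]
  in_te <- tag(sim$annotation$te)
  dt[in_te & context == "CG", level := cfg$te_cg]
  dt[in_te & context == "CHG", level := cfg$te_chg]
  dt[in_te & context == "CHH", level := cfg$te_chh]
  if (nrow(sim$sensor)) {
    sens_iv <- merge(sim$sensor, sim$annotation$introns,
                     by = c("gene_id", "intron_rank"))
    in_sens <- tag(sens_iv)
    dt[in_sens & context == "CHG", level := cfg$sensor_mchg]
  }
  dt
}

#' Simulate a per-cytosine methylome from a simulated genome
#'
#' Assigns every cytosine of the simulated genome a true methylation
#' level by compartment (gbM gene bodies, TEs, the planted sensor
#' intron, background; the control contig is fully unmethylated), then
#' draws coverage ~ Poisson(depth) and methylated reads ~ Binomial(cov,
#' level + (1 - level) p0).
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param cfg Config (defaults to the one stored in `sim`).
#' @return List with `allc` (uncalled allc table) and `truth` (the same
#'   table's per-site true levels).
#' @export
simulate_methylome <- function(sim, cfg = sim$config) {
  stopifnot(inherits(sim, "sim_genome"))
  skeleton <- extract_cytosines(sim$genome)
  skeleton <- assign_levels(skeleton, sim, cfg)
  allc <- with_seed(derive_seed(cfg$seed, 2L), draw_counts(skeleton, cfg))
  truth <- allc[, .(chrom, pos, strand, context, level)]
  allc[, level := NULL]
  allc[, called := NA]
  list(allc = allc[], truth = truth)
}

# site scaffold without sequence: genes tiled on contig "sim1", each with a
# fixed complement of CG/CHG/CHH sites; control sites on contig "ctrl"
gene_site_scaffold <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 3L), {
    n <- cfg$n_genes
    per_gene <- cfg$n_cg_per_gene + cfg$n_chg_per_gene + cfg$n_chh_per_gene
    if (per_gene > cfg$gene_span) stop("gene_span too small for site counts")
    gid <- rep(sprintf("g%04d", seq_len(n)), each = per_gene)
    offs <- as.vector(vapply(seq_len(n), function(i)
      sort(sample.int(cfg$gene_span, per_gene)), integer(per_gene)))
    pos <- rep((seq_len(n) - 1L) * cfg$gene_span, each = per_gene) + offs
    ctx <- rep(c(rep("CG", cfg$n_cg_per_gene), rep("CHG", cfg$n_chg_per_gene),
                 rep("CHH", cfg$n_chh_per_gene)), n)
    trinuc <- data.table::fcase(
      ctx == "CG", "CGA",
      ctx == "CHG", sample(c("CAG", "CTG", "CCG"), n * per_gene, replace = TRUE),
      default = "CTA")
    genes <- data.table::data.table(
      gene_id = sprintf("g%04d", seq_len(n)),
      tx_id = sprintf("g%04d.1", seq_len(n)), chrom = "sim1", strand = "+",
      start = (seq_len(n) - 1L) * cfg$gene_span + 1L,
      end = seq_len(n) * cfg$gene_span)
    ann <- genome_annotation(genes = genes,
                             exons = genes[, .(gene_id, chrom, strand, start, end)],
                             cds = genes[, .(gene_id, chrom, strand, start, end)])
    gbm <- sample(c(TRUE, FALSE), n, replace = TRUE,
                  prob = c(cfg$gbm_fraction, 1 - cfg$gbm_fraction))
    truth <- data.table::data.table(
      gene_id = genes$gene_id,
      compartment = data.table::fifelse(gbm, "gbM", "background"))
    skel <- data.table::data.table(
      chrom = "sim1", pos = pos,
      strand = sample(c("+", "-"), length(pos), replace = TRUE),
      trinuc = trinuc, gene_id = gid)
    cc <- classify_context(skel$trinuc)
    skel[, `:=`(context = cc$context, subcontext = cc$subcontext)]
    skel[, level := data.table::fcase(
      context == "CG" & gene_id %in% truth[compartment == "gbM", gene_id],
      cfg$level_gbm_cg,
      context == "CG", cfg$level_bg_cg,
      context == "CHG", cfg$level_chg,
      default = cfg$level_chh)]
    nc <- cfg$n_control_sites
    ctrl <- data.table::data.table(
      chrom = "ctrl", pos = seq_len(nc) * 3L, strand = "+",
      trinuc = sample(c("CGA", "CAG", "CTA"), nc, replace = TRUE),
      gene_id = NA_character_)
    cc <- classify_context(ctrl$trinuc)
    ctrl[, `:=`(context = cc$context, subcontext = cc$subcontext, level = 0)]
    list(skeleton = data.table::rbindlist(list(skel, ctrl), use.names = TRUE),
         annotation = ann, truth_genes = truth)
  })
}

#' Simulate a single-accession gene methylome (site scaffold)
#'
#' Fast, sequence-free companion to [simulate_methylome()]: tiles
#' `n_genes` single-exon gene models on an abstract contig, plants a
#' `gbm_fraction` of them as gbM (CG level `level_gbm_cg`, others
#' `level_bg_cg`; CHG/CHH at background), adds an unmethylated control
#' contig, and draws counts. This is the generator behind the
#' planted-gbM recovery analyses.
#'
#' @param cfg A [sim_config()].
#' @return List with `allc`, `annotation`, `truth_genes`, `control_seqs`.
#' @export
simulate_gbm_species <- function(cfg = sim_config()) {
  sc <- gene_site_scaffold(cfg)
  allc <- with_seed(derive_seed(cfg$seed, 4L),
                    draw_counts(sc$skeleton, cfg))
  allc[, c("level", "gene_id") := NULL]
  allc[, called := NA]
  list(allc = allc[], annotation = sc$annotation,
       truth_genes = sc$truth_genes, control_seqs = "ctrl")
}

#' Simulate an accession panel with planted ibm1-like accessions
#'
#' Builds one shared site scaffold (see [simulate_gbm_species()]) plus a
#' sensor gene carrying a long intron of CHG sites, then plants
#' `n_ibm1_like` accessions that (i) carry ectopic mCHG (level
#' `ectopic_mchg`) in `n_ectopic_per_ibm1` randomly chosen gbM genes and
#' (ii) have the sensor intron's mCHG reduced to `sensor_mchg_low`
#' (other accessions: `sensor_mchg_high`), coupling ectopic methylation
#' to sensor hypomethylation. Non-planted accessions carry a small
#' background number (0 to `base_ectopic_max`) of ectopic genes.
#' Per-accession methylomes are drawn on demand with
#' [panel_accession_allc()].
#'
#' @param cfg A [sim_config()].
#' @return A `sim_panel` list: `scaffold`, `annotation` (genes plus the
#'   sensor gene), `sensor` (gene id/intron interval), `truth_accessions`
#'   (`accession`, `ibm1_like`, `sensor_level`, `n_planted`),
#'   `truth_ectopic` (accession x gene), `control_seqs`, `config`.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  if (cfg$n_ibm1_like > cfg$n_accessions) {
    stop("n_ibm1_like exceeds n_accessions")
  }
  sc <- gene_site_scaffold(cfg)
  with_seed(derive_seed(cfg$seed, 5L), {
    # sensor gene: one long intron of CHG sites appended after the gene tile
    base_end <- cfg$n_genes * cfg$gene_span
    intron_len <- max(cfg$long_intron_len, 1000L)
    sensor_gene <- data.table::data.table(
      gene_id = "sensor", tx_id = "sensor.1", chrom = "sim1", strand = "+",
      start = base_end + 1L, end = base_end + 200L + intron_len + 200L)
    sensor_exons <- data.table::data.table(
      gene_id = "sensor", chrom = "sim1", strand = "+",
      start = c(sensor_gene$start, base_end + 200L + intron_len + 1L),
      end = c(base_end + 200L, sensor_gene$end))
    intron_iv <- c(base_end + 201L, base_end + 200L + intron_len)
    sens_pos <- sort(sample(seq(intron_iv[1], intron_iv[2]), cfg$n_sensor_chg))
    sens_sites <- data.table::data.table(
      chrom = "sim1", pos = sens_pos, strand = "+",
      trinuc = sample(c("CAG", "CTG"), cfg$n_sensor_chg, replace = TRUE),
      gene_id = "sensor", context = "CHG", subcontext = "CWG", level = NA_real_)
    ann <- genome_annotation(
      genes = rbind(sc$annotation$genes, sensor_gene),
      exons = rbind(sc$annotation$exons[, .(gene_id, chrom, strand, start, end)],
                    sensor_exons),
      cds = rbind(sc$annotation$cds, sensor_exons))
    accs <- sprintf("acc%03d", seq_len(cfg$n_accessions))
    ibm1 <- sort(sample.int(cfg$n_accessions, cfg$n_ibm1_like))
    gbm_ids <- sc$truth_genes[compartment == "gbM", gene_id]
    if (cfg$n_ibm1_like > 0 && cfg$n_ectopic_per_ibm1 > length(gbm_ids)) {
      stop("n_ectopic_per_ibm1 exceeds the number of planted gbM genes")
    }
    ect <- lapply(seq_len(cfg$n_accessions), function(i) {
      k <- if (i %in% ibm1) cfg$n_ectopic_per_ibm1
           else min(sample.int(cfg$base_ectopic_max + 1L, 1L) - 1L,
                    length(gbm_ids))
      if (k == 0L) return(NULL)
      data.table::data.table(accession = accs[i], gene_id = sample(gbm_ids, k))
    })
    truth_acc <- data.table::data.table(
      accession = accs, ibm1_like = seq_len(cfg$n_accessions) %in% ibm1)
    truth_acc[, sensor_level := data.table::fifelse(
      ibm1_like, cfg$sensor_mchg_low, cfg$sensor_mchg_high)]
    truth_ect <- data.table::rbindlist(ect)
    truth_acc <- merge(truth_acc,
                       truth_ect[, .(n_planted = .N), by = accession],
                       by = "accession", all.x = TRUE)
    truth_acc[is.na(n_planted), n_planted := 0L]
    structure(list(
      scaffold = data.table::rbindlist(list(sc$skeleton, sens_sites),
                                       use.names = TRUE),
      annotation = ann,
      sensor = data.table::data.table(gene_id = "sensor", intron_rank = 1L,
                                      chrom = "sim1", strand = "+",
                                      start = intron_iv[1], end = intron_iv[2]),
      truth_accessions = truth_acc[], truth_ectopic = truth_ect,
      control_seqs = "ctrl", config = cfg), class = "sim_panel")
  })
}

#' Draw one accession's methylome from a simulated panel
#'
#' Deterministically derives the accession's seed from the panel config
#' and draws its per-cytosine counts: planted ectopic genes get CHG
#' level `ectopic_mchg`, the sensor intron gets the accession's sensor
#' level, everything else follows the shared scaffold.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param accession Accession id (e.g. `"acc003"`).
#' @return An uncalled allc `data.table`.
#' @export
panel_accession_allc <- function(panel, accession) {
  stopifnot(inherits(panel, "sim_panel"))
  acc <- accession
  info <- panel$truth_accessions[accession == acc]
  if (nrow(info) != 1L) stop("unknown accession ", acc)
  cfg <- panel$config
  skel <- data.table::copy(panel$scaffold)
  skel[gene_id == "sensor", level := info$sensor_level]
  ect_genes <- panel$truth_ectopic[accession == acc, gene_id]
  if (length(ect_genes)) {
    skel[gene_id %in% ect_genes & context == "CHG", level := cfg$ectopic_mchg]
  }
  i <- which(panel$truth_accessions$accession == acc)
  allc <- with_seed(derive_seed(cfg$seed, 100L + i),
                    draw_counts(skel, cfg))
  allc[, c("level", "gene_id") := NULL]
  allc[, called := NA]
  allc[]
}

#' Simulate strand-paired CWG methylation data
#'
#' Generates CWG palindromic pairs under one of two regimes: `"coupled"`
#' (one methylation state per site, shared by both strands — the CMT3
#' maintenance pattern) or `"independent"` (each strand draws its own
#' state — the pattern expected without symmetric maintenance). A
#' methylated strand is sequenced at per-read level `cwg_read_level`, an
#' unmethylated one at the non-conversion rate; `cwg_meth_prob` is the
#' probability of the methylated state.
#'
#' @param cfg A [sim_config()].
#' @return List with `allc` (two records per pair, plus/minus) and
#'   `truth` (`pos`, per-strand true states, regime).
#' @export
simulate_cwg <- function(cfg = sim_config()) {
  stopifnot(cfg$cwg_regime %in% c("coupled", "independent"))
  with_seed(derive_seed(cfg$seed, 6L), {
    n <- cfg$n_pairs
    pos <- seq_len(n) * 10L
    if (cfg$cwg_regime == "coupled") {
      st <- stats::rbinom(n, 1L, cfg$cwg_meth_prob)
      st_plus <- st; st_minus <- st
    } else {
      st_plus <- stats::rbinom(n, 1L, cfg$cwg_meth_prob)
      st_minus <- stats::rbinom(n, 1L, cfg$cwg_meth_prob)
    }
    tri_plus <- sample(c("CAG", "CTG"), n, replace = TRUE)
    tri_minus <- data.table::fifelse(tri_plus == "CAG", "CTG", "CAG")
    lvl <- function(st) data.table::fifelse(st == 1L, cfg$cwg_read_level, 0)
    mk <- function(p, strand, tri, st) {
      dt <- data.table::data.table(chrom = "chr1", pos = p, strand = strand,
                                   trinuc = tri, level = lvl(st))
      cc <- classify_context(dt$trinuc)
      dt[, `:=`(context = cc$context, subcontext = cc$subcontext)]
      dt
    }
    allc <- data.table::rbindlist(list(
      mk(pos, "+", tri_plus, st_plus),
      mk(pos + 2L, "-", tri_minus, st_minus)))
    allc <- draw_counts(allc, cfg, depth = cfg$cwg_depth)
    allc[, level := NULL]
    allc[, called := NA]
    data.table::setorder(allc, chrom, pos, strand)
    list(allc = allc[],
         truth = data.table::data.table(pos = pos, state_plus = st_plus,
                                        state_minus = st_minus,
                                        regime = cfg$cwg_regime))
  })
}

#' Simulate a region-stratified SNP genotype matrix
#'
#' Lays the region classes end to end on one reference, makes each
#' position polymorphic with its class's Bernoulli rate, and draws the
#' derived-allele count of each polymorphic site from the neutral-like
#' frequency spectrum P(i) proportional to 1/i (i = 1 .. n-1), which
#' keeps Tajima's D near zero in expectation.
#'
#' @param cfg A [sim_config()].
#' @return List with `snp` (`pos`, `geno` for polymorphic sites),
#'   `regions` (`class`, `start`, `end`), `truth` (per-class planted
#'   rates).
#' @export
simulate_snp_matrix <- function(cfg = sim_config()) {
  if (cfg$n_hap < 4L) stop("need at least 4 haplotypes")
  with_seed(derive_seed(cfg$seed, 7L), {
    lens <- cfg$region_lengths
    ends <- cumsum(lens)
    regions <- data.table::data.table(
      class = names(lens),
      start = as.integer(c(1L, utils::head(ends, -1) + 1L)),
      end = as.integer(ends))
    n <- cfg$n_hap
    sfs <- (1 / seq_len(n - 1L)); sfs <- sfs / sum(sfs)
    out_pos <- integer(); out_geno <- list()
    for (r in seq_len(nrow(regions))) {
      span <- regions$start[r]:regions$end[r]
      poly <- span[stats::runif(length(span)) < cfg$snp_rates[[regions$class[r]]]]
      for (p in poly) {
        k <- sample.int(n - 1L, 1L, prob = sfs)
        g <- integer(n); g[sample.int(n, k)] <- 1L
        out_pos <- c(out_pos, p); out_geno[[length(out_geno) + 1L]] <- g
      }
    }
    geno <- if (length(out_geno)) do.call(rbind, out_geno) else
      matrix(integer(), ncol = n)
    colnames(geno) <- sprintf("hap%03d", seq_len(n))
    list(snp = list(pos = out_pos, geno = geno), regions = regions,
         truth = data.table::data.table(class = names(cfg$snp_rates),
                                        rate = unname(cfg$snp_rates)))
  })
}

#' Simulate a transcript-abundance table with planted ratio shifts
#'
#' Generates per-gene short/long transcript abundances for two
#' conditions (`A` = reference, `B` = shifted), with `n_shifted` planted
#' genes whose short-to-long ratio increases by `shift_delta` in
#' condition B while the remainder drift by Normal(0, `ratio_noise_sd`).
#' Replicate-level abundances optionally carry multiplicative lognormal
#' noise (`abund_noise_sd`).
#'
#' @param cfg A [sim_config()].
#' @return List with `abundance` (`transcript_id`, `sample`,
#'   `abundance`), `conditions` (`sample`, `condition`), `pairs`
#'   (`gene_id`, `long_tx`, `short_tx`) and `truth` (shifted gene ids
#'   and per-gene true ratios).
#' @export
simulate_abundance <- function(cfg = sim_config()) {
  with_seed(derive_seed(cfg$seed, 8L), {
    n <- cfg$n_abund_genes
    gid <- sprintf("ag%04d", seq_len(n))
    shifted <- sort(sample.int(n, cfg$n_shifted))
    long_tpm <- stats::rlnorm(n, meanlog = 2, sdlog = 0.5)
    ratio_a <- stats::runif(n, 0.2, 1.0)
    drift <- stats::rnorm(n, 0, cfg$ratio_noise_sd)
    drift[shifted] <- cfg$shift_delta
    ratio_b <- pmax(ratio_a + drift, 0)
    pairs <- data.table::data.table(gene_id = gid,
                                    long_tx = paste0(gid, ".1"),
                                    short_tx = paste0(gid, ".1.short"))
    rows <- list()
    for (cond in c("A", "B")) {
      ratio <- if (cond == "A") ratio_a else ratio_b
      for (r in seq_len(cfg$abund_reps)) {
        noise <- function() if (cfg$abund_noise_sd > 0)
          stats::rlnorm(n, 0, cfg$abund_noise_sd) else 1
        samp <- paste0(cond, r)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          transcript_id = c(pairs$long_tx, pairs$short_tx),
          sample = samp,
          abundance = c(long_tpm * noise(), long_tpm * ratio * noise()))
      }
    }
    abund <- data.table::rbindlist(rows)
    conditions <- data.table::data.table(
      sample = unique(abund$sample),
      condition = substr(unique(abund$sample), 1L, 1L))
    list(abundance = abund, conditions = conditions, pairs = pairs,
         truth = data.table::data.table(gene_id = gid, ratio_a = ratio_a,
                                        ratio_b = ratio_b,
                                        shifted = seq_len(n) %in% shifted))
  })
}

#' Write a simulated genome to FASTA and GFF3
#'
#' @param sim A `sim_genome`.
#' @param fasta,gff Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_sim_genome <- function(sim, fasta, gff) {
  Biostrings::writeXStringSet(sim$genome, fasta)
  ann <- sim$annotation
  rows <- list(
    ann$genes[, .(chrom, source = "methylsensor", type = "gene", start, end,
                  score = ".", strand, phase = ".",
                  attr = paste0("ID=", gene_id))],
    ann$genes[, .(chrom, source = "methylsensor", type = "mRNA", start, end,
                  score = ".", strand, phase = ".",
                  attr = paste0("ID=", tx_id, ";Parent=", gene_id))],
    merge(ann$exons, ann$genes[, .(gene_id, tx_id)], by = "gene_id")[,
      .(chrom, source = "methylsensor", type = "exon", start, end,
        score = ".", strand, phase = ".", attr = paste0("Parent=", tx_id))],
    merge(ann$cds, ann$genes[, .(gene_id, tx_id)], by = "gene_id")[,
      .(chrom, source = "methylsensor", type = "CDS", start, end,
        score = ".", strand, phase = "0", attr = paste0("Parent=", tx_id))],
    merge(ann$utr5, ann$genes[, .(gene_id, tx_id)], by = "gene_id")[,
      .(chrom, source = "methylsensor", type = "five_prime_UTR", start, end,
        score = ".", strand, phase = ".", attr = paste0("Parent=", tx_id))],
    merge(ann$utr3, ann$genes[, .(gene_id, tx_id)], by = "gene_id")[,
      .(chrom, source = "methylsensor", type = "three_prime_UTR", start, end,
        score = ".", strand, phase = ".", attr = paste0("Parent=", tx_id))])
  if (nrow(ann$te)) {
    rows <- c(rows, list(ann$te[, .(chrom, source = "methylsensor",
      type = "transposable_element", start, end, score = ".", strand = "+",
      phase = ".", attr = paste0("ID=te", .I))]))
  }
  gff_dt <- data.table::rbindlist(rows)
  data.table::setorder(gff_dt, chrom, start)
  writeLines("##gff-version 3", gff)
  data.table::fwrite(gff_dt, gff, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE)
  invisible(list(fasta = fasta, gff = gff))
}
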