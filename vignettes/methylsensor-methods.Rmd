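---
title: "Models and methods behind methylsensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylsensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsensor)
library(data.table)
```

# Overview

Plant genomes carry cytosine methylation in three sequence contexts —
CG, CHG and CHH (H = A, C or T). Most protein-coding genes that are
methylated at all carry *gene-body methylation* (gbM): CG-only
methylation over the coding region, with no CHG/CHH signal. CHG
methylation is maintained by CMT3 together with the H3K9
methyltransferase KYP in a self-reinforcing loop; the histone
demethylase IBM1 protects genes from this loop. IBM1 itself carries a
long, heavily mCHG-methylated intron that behaves as a *heterochromatin
sensor*: its methylation state controls whether the functional
full-length isoform (IBM1-L) or a truncated short isoform (IBM1-S) is
produced. Accessions in which the sensor intron loses mCHG produce less
functional IBM1 and accumulate ectopic CHG methylation in hundreds of
normally-gbM genes, phenocopying *ibm1* mutants.

`methylsensor` implements the analysis layer of this biology as a
tested pipeline over per-cytosine methylation call tables ("allc"
dialect): binomial site calling, gbM classification, intron
mCHG-enrichment testing, population-scale ectopic scans, CWG strand
symmetry, weighted-methylation metaplots, region-stratified
population-genetic statistics, and short/long isoform-ratio analysis.
A synthetic-data generator reproduces the statistical structure of all
inputs so that every stage can be validated without external data.

# Site-level methylation calling

Bisulfite conversion leaves a small fraction of unmethylated cytosines
unconverted. That *non-conversion rate* p0 is estimated by pooling read
counts over a fully unmethylated control sequence (chloroplast or
spiked-in lambda): `estimate_nonconversion()` returns
p0 = sum(mc)/sum(cov), pooled rather than averaged per sequence so that
deeply covered controls dominate. When a finite control shows zero
non-conversion, p0 is floored at a configurable epsilon (default 1e-4)
so downstream p-values are never a degenerate 0.

Each cytosine with coverage of at least 3 reads is then tested with an
upper-tail binomial: p = P(X >= mc | n = cov, p0). P-values are
adjusted with Benjamini–Hochberg FDR and a site is called methylated at
q < 0.05. Two decisions here were genuinely open:

* **FDR family.** We stratify the BH correction by context class (CG,
  CHG, CHH as separate families) because background methylation rates
  differ by orders of magnitude between contexts; pooling them would
  let the abundant CG signal drag CHH q-values down. The un-stratified
  behaviour is available via `stratify_context = FALSE`.
* **Thresholding raw p versus q.** Whether site calls should use raw
  binomial p-values or BH q-values is not dictated by the model; we use
  q-values (the conservative choice) and expose the machinery so either
  is reproducible.

Sites below the coverage floor are retained with `called = NA` rather
than dropped, because the gene-eligibility rules downstream need to see
them.

# Gene-body methylation classification

For each gene, `summarize_gene_cds()` counts eligible (cov >= 3) and
called-methylated sites per context over the CDS of the *primary
transcript*, on both strands. The primary transcript is the mRNA with
the largest spliced (summed-exon) length, ties broken by smallest
transcript id — a deliberate, recorded convention since "primary" has
no universal definition.

The species-wide fraction of methylated sites per context
(`estimate_background()`) is the null probability for a gene-level
upper-tail binomial on (methylated, eligible) counts; BH runs per
context across all genes. A gene is **gbM** when

* reads map to at least 20 CG sites (coverage >= 1; the separate
  40%-at-cov>=3 rule below governs eligibility),
* q(CG) < 0.05, and
* q(CHG) > 0.95 and q(CHH) > 0.95 (no evidence of non-CG methylation).

A gene is **unclassified** when fewer than 40% of its CDS CG sites
reach calling coverage; everything else is **non-gbM**. The genome-wide
`gbm_ratio()` is #gbM / (#gbM + #non-gbM) — unclassified genes are
excluded from the denominator, and an all-unclassified input yields a
missing value, not zero. An auxiliary `tem_like` flag (significant
q(CHG) or q(CHH)) annotates TE-like methylated genes without entering
the gbM rules.

Note one subtlety: BH can only raise p-values, so "q > 0.95" is mostly
satisfied by genes whose non-CG tail probability is 1 (zero methylated
sites), which is exactly the intended reading of "no non-CG signal".

# Intron mCHG enrichment — the sensor detector

`intron_background()` pools called/eligible counts over *all introns*
(never CDS) to form the intron-scope null; `test_introns()` then tests
each supplied intron per context and flags mCHG enrichment at
q(CHG) < 0.05, with the BH family being the set of introns tested in
one invocation. `screen_sensor_candidates()` generalises the single
named-intron test to every intron of at least 1 kb, ranking by q(CHG)
and weighted mCHG. The CWG/CCG subcontext breakdown is reported
alongside because CCG methylation additionally depends on MET1 and is
depleted relative to CWG.

The length threshold is inclusive (>= 1000 bp) with both the value and
the comparison configurable, since "long intron" is conventionally
quoted both as "> 1 kb" and ">= 1 kb".

# Population ectopic scan

Across an accession panel, a gene is *ectopic non-CG* in accession A
when it shows significant non-CG methylation there (q(CHG) < 0.05
and/or q(CHH) < 0.05) while being gbM in **more than 90%** of
accessions. The frequency denominator excludes accessions where the
gene is unclassified — a deliberate choice, since coverage failures
carry no information about the gene's typical state. Accessions with
**more than 120** ectopic genes are flagged *ibm1-like*; the strict
`>` reading is the default, with `strict = FALSE` giving `>=`.

`mchg_gain_genes()` supports the paired-sample comparison (e.g. a wild
type versus an IBM1-overexpression line): a gene is listed when its
coverage-weighted mCHG increases by strictly more than 0.02, by default
over the reference sample's gbM genes. `ectopic_vs_sensor_table()`
joins per-accession ectopic counts with sensor-intron mCHG, expression
and isoform ratios, computing Spearman correlations on the subset with
sensor mCHG <= 0.035 — the regime in which the sensor responds
dynamically rather than saturating.

# Per-site levels, CWG symmetry and metaplots

Per-site level distributions (`per_site_levels()`) include sites with
coverage >= 3 and at least one methylated read; "at least one
methylated read" versus "called methylated" is ambiguous in common
usage, so both inclusion rules are implemented (`inclusion = "mc1"`
default, `"called"` optional).

CWG triplets (W = A or T) are palindromic: the plus-strand C at
position p pairs with the minus-strand C at p+2.
`pair_cwg_sites()` forms these pairs (CCG excluded to remove MET1's
influence), requires coverage >= 3 on *both* strands and at least one
methylated read on the pair, and classifies each pair as symmetric
(both strands called), plus_only, minus_only or neither. A
predominantly symmetric pattern indicates CMT3-type maintenance.

`metaplot()` divides each feature body into 20 equal real-valued
windows and 1,000 bp flanks into 20 windows each, oriented 5'→3'
(minus-strand features reversed; their window 1 is the genomic right
end). A site belongs to the half-open window containing its position.
Two summaries are returned: the pooled coverage-weighted level per
window (which satisfies the exact identity that its coverage-weighted
average over body windows equals the whole-body weighted level) and
the cross-feature mean of per-feature window levels, which is the
conventional plotted quantity.

# Population-genetic statistics

For region-stratified variation analysis, a biallelic genotype matrix
(inbred accessions treated as haploids) is split into CDS, methylated
intron and unmethylated intron classes. SNP density is the proportion
of segregating sites; the denominator defaults to the full region
length (switchable to genotyped positions only). Tajima's D is
computed from the standard estimator,
D = (pi − S/a1) / sqrt(e1·S + e2·S(S−1)), with pi the mean number of
pairwise differences. Missing genotypes are handled pairwise-complete
in pi and a site counts as segregating when at least two alleles occur
among non-missing entries; D is reported missing when S = 0 and n >= 4
haplotypes are required. Cross-species divergence
(`pairwise_difference()`) is 1 minus the proportion of identical bases
per class, with gap columns excluded from both numerator and
denominator.

# Isoform tools

For a gene with a long methylated intron, the short isoform is modelled
by a truncated reference transcript containing only the exonic (UTR +
CDS) sequence 5' of that intron (`make_truncated_transcript()`); by
construction the short sequence is a prefix of the full spliced
transcript, and the construction is strand-aware. Exonic sequence 3'
of the stop codon but 5' of the target intron is included — the
truncation is positional, not reading-frame aware. Abundances (any
unit; never recomputed here) are averaged across replicates within
condition before the short/long ratio is formed; a zero long-isoform
abundance yields a missing, not infinite, ratio. `ratio_shift_genes()`
lists genes whose ratio increases by strictly more than 2 between
conditions — an arithmetic difference of ratios, not a fold change.

# The synthetic-data generator

Every generator is a pure function of its `sim_config()`: the seed
fully determines the output and the caller's RNG state is restored.
The count model is cov ~ Poisson(depth) and
mc ~ Binomial(cov, level + (1−level)·p0), folding non-conversion into
the read-level success probability so that the site caller's null is
exactly correct at level 0.

Defaults encode the validation conditions: sequencing depth 10
(typical WGBS), p0 = 0.005 (a realistic chloroplast-derived rate), gbM
genes at per-site CG level 0.8 versus 0.02 background, CHG/CHH
backgrounds at 0.01, TEs at 0.9/0.7/0.1, 2,000 genes with 30 CG sites
each, planted gbM fraction 0.3 (the order observed in A. thaliana),
and a planted sensor intron at CHG level 0.4. The accession panel
plants 5 of 50 accessions as ibm1-like, each with 150 ectopic genes at
mCHG 0.3 and a hypomethylated sensor intron (0.01 versus 0.08),
while other accessions carry 0–20 background ectopic genes. SNP
matrices use per-class polymorphism rates (0.002 CDS, 0.006 methylated
intron, 0.002 unmethylated intron) with derived-allele counts drawn
from the neutral-like spectrum P(i) ∝ 1/i, which keeps Tajima's D near
zero in expectation and so provides a sanity anchor.

The CWG generator needs one interpretive choice: the "level" of a
regime is the probability of the *methylated state* (shared per site
in the coupled regime, independent per strand otherwise), with
methylated strands sequenced at a fixed high per-read level. A
constant per-strand read-level of 0.3 at depth 20 would make both
strands callable and could never produce an asymmetric pattern, so the
Bernoulli-state reading is the only one that reproduces the intended
coupled/independent contrast.

What the generator deliberately does **not** emulate: read-level
bisulfite errors and mapping bias, linkage between neighbouring sites,
sequence-composition effects on methylation, TE sequence evolution,
and coalescent genealogies (SNP sites are independent). Passing the
recovery tests therefore demonstrates the correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real WGBS data.

# Numerical and design notes

* Internal intervals are 1-based closed throughout, matching both GFF3
  and the allc dialect; conversion happens only at the BED boundary.
  With both input formats 1-based, a 0-based internal convention would
  add a conversion layer without removing one.
* Upper-tail binomials use `pbinom(mc - 1, cov, p, lower.tail = FALSE)`;
  P(X >= 0) is exactly 1, so empty regions get p = 1 and can never be
  called enriched.
* BH q-values come from `stats::p.adjust`; the test suite pins them
  against an independent brute-force implementation, as it does the
  binomial tails (explicit summation, n <= 500, 1e-10) and Tajima's D
  (explicit pair loop, 1e-9).
* Ties in the sensor screen are broken by weighted mCHG after q(CHG).
* Degenerate inputs have defined behaviour: empty record streams pass
  through, zero-coverage controls raise errors, untestable introns are
  flagged rather than silently dropped, and an all-unclassified
  genome yields a missing gbM ratio.

# Validation scale

The shipped tests run the full study conditions where they are cheap
(2,000-gene methylomes, 50-accession panels, 1e5-site null
calibrations) and scaled-down versions (hundreds of genes, 10–20
replicates) where a property is being exercised rather than measured;
each test states its own problem size. The end-to-end `run_pipeline()`
example below uses a small genome so the vignette builds quickly.

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1, seq_n_genes = 25L, n_clean_long_introns = 3L)
summary <- run_pipeline(cfg, outdir = tempfile("msrun"))
str(summary)
```

# Known limitations

* No beta-binomial overdispersion at the site level; biological
  replicates are not modelled.
* No differential methylation testing between samples at site level;
  sample comparisons happen at the gene level (mCHG gain) only.
* The ectopic scan assumes accessions share one gene set; no
  genotype-aware exclusion of deleted regions.
* Isoform quantification itself (pseudoalignment) is out of scope: the
  package builds truncated references and consumes abundance tables.
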