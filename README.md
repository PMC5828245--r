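# ocrenrich

Are a disease's GWAS risk variants preferentially located in open
chromatin of particular cell types, and do motif-defined subsets of those
open-chromatin regions carry a disproportionate share of the trait's SNP
heritability? `ocrenrich` implements the full analysis path for both
questions — for statistical geneticists and regulatory genomicists who
want the machinery as tested, reusable R functions rather than a chain of
shell tools — together with a synthetic-data generator that produces every
input with recorded ground truth.

## The statistics

**Matched-background enrichment.** Each index SNP is expanded to a *locus*
(itself plus all panel SNPs with r² > 0.8 within 1 Mb). For the index set
and each of N matched background sets (SNPs matched on MAF, LD-buddy
count, distance to nearest gene and gene density), the number of loci with
at least one SNP inside the open-chromatin set is counted. With observed
count O and background counts B₁…B_N:

    z      = (O − mean(B)) / sd(B)
    P_emp  = max(#{Bᵢ ≥ O}, 1) / N        # minimum 1/N; 1e-4 at N = 10,000

Ties count against significance; annotations where fewer than 1,000 of
10,000 background sets show any overlap are dropped as under-powered; BH
or Bonferroni correction (with an explicit test count m) follows.

**Motif partitioning.** Open-chromatin regions are scanned with position
weight matrices (HOMER-style `.motif` files, both strands, log-odds score
against the motif's own threshold) and grouped into one subset per motif
plus a `no_motif` negative-control subset.

**Partitioned heritability.** Stratified LD-score regression, simplified:
E[χ²ⱼ] = 1 + n·Σ_c τ_c·ℓ(j,c) with annotation-specific LD scores
ℓ(j,c) = Σ_k r²ⱼₖ·a(k,c), fitted by WLS with the intercept fixed at 1;
per-category heritability shares, enrichment = h² share / SNP share, and
delete-one-block jackknife SEs. Each focal annotation (e.g. each motif
subset, extended ±500 bp) is added to the baseline one at a time, with
Bonferroni correction across focal fits. MHC (chr6:26.0–34.0 Mb) and APOE
(chr19:44.4–46.5 Mb) regions ship as packaged default exclusions.

## Worked example

```r
library(ocrenrich)

cfg <- sim_config(seed = 42)           # 18 index SNPs, planted 0.7 vs 0.2
bundle <- simulate_bundle(cfg, "demo/inputs")

run <- run_config(
  inputs = list(hap = bundle$paths$hap, genes = bundle$paths$genes,
                peaks = bundle$paths$ocrs, index = bundle$paths$index,
                motifs = bundle$paths$motifs, genome = bundle$paths$genome,
                sumstats = bundle$paths$sumstats),
  out_dir = "demo/run", n_sets = 1000, seed = 42, exclude = "none",
  min_nonzero = 100, n_blocks = 20)
run_pipeline(run)
read.delim("demo/run/enrichment.tsv")
```

Output (abridged):

```
  annotation_label n_loci observed bg_mean bg_sd    z p_empirical p_corrected
1            peaks     18       10    4.62  1.60 3.37       0.001      0.0015
2             SPI1     18        6    3.43  1.50 1.72       0.091      0.0910
3         no_motif     18       10    4.50  1.58 3.48       0.001      0.0015
```

Ten of the 18 planted index loci overlap a peak against a background
expectation of 4.6, giving z = 3.37 and empirical P = 0.001 — the planted
excess is detected. The heritability stage of the same run
(`demo/run/h2_partition.tsv`) recovers the 5× effect planted on the SPI1
subset:

```
  category n_snps snp_share h2_share enrichment enrichment_se p_enrichment
1     SPI1    190     0.095    0.374       3.93         1.048      0.00515
2 no_motif    373     0.186    0.493       2.64         0.599      0.00611
```

The SPI1 estimate (3.93 ± 1.05) covers the planted truth; `no_motif`
inherits some signal because extended no-motif peaks share LD blocks with
planted SPI1 peaks — the kind of annotation bleed-through real analyses
also face.

A thin command-line wrapper with `simulate`, `enrich`, `motif-partition`,
`partition-h2` and `run-all` subcommands lives at
`inst/scripts/ocrenrich`.

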