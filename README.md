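# metaexpress

Integrating paired metagenomes (DNA) and metatranscriptomes (RNA) from
microbial communities into **gene expression profiles**.

A community's transcript pool shifts for two reasons: genes change their
expression, or the organisms carrying them change in abundance (*community
turnover*). Dividing normalized transcript abundance by normalized gene
abundance, per gene and sample, separates the two. For gene *i* with count
*nᵢ* and length *lᵢ*:

```
TPM(i) = (nᵢ/lᵢ) / Σⱼ(nⱼ/lⱼ) × 10⁶
MG(i)  = (nᵢ/lᵢ) / median(rates of the genome's 10 single-copy marker COGs) × 10⁶
gene expression(i) = RNA profile(i) / DNA profile(i)
```

`metaexpress` implements these normalizations and the computational stages
around them, for analysts who run external trimmers / aligners / binners /
annotators and need the derived quantities:

* read-QC estimators: read-length histogram, minimum-length cutoff
  retaining ≥ 95% of reads (50 bp floor), adapter-index detection from the
  first 10,000 FASTQ headers;
* MAG dereplication: quality filter (completeness > 90%, contamination
  < 5%), `final = 0.1 × (completeness − 2·contamination) +
  log₁₀(longest/#contigs) + log₁₀(N50/L50)` scoring, and per-ANI-cluster
  representative selection;
* TPM and marker-gene (MG) normalization, minimum-mapped-reads filter,
  gene lengths from GFF3, mappability;
* DNA/RNA integration into gene- and function-level expression profiles
  with explicit zero/missing semantics, plus feature-overlap summaries;
* community summaries: relative abundance, top-genus tables, Bray–Curtis
  dissimilarity, PCoA;
* a synthetic fixture generator with known ground truth (planted
  expression fold changes, marker placements, read-length distributions),
  so every stage is testable without downloads.

## Worked example

Simulate two genomes × 20 genes over 4 paired DNA/RNA samples at a mean
depth of 50 reads per gene, planting a 3× induction on one gene and a 4×
repression on another, then recover expression via MG normalization:

```r
library(metaexpress)

spec <- fixture_spec(seed = 42, n_genomes = 2, genes_per_genome = 20,
                     n_samples = 4, mean_depth = 50,
                     expression_fold_changes = c(genome01_g0015 = 3,
                                                 genome02_g0015 = 0.25))
ft <- make_count_tables(spec)
e <- gene_expression(mg_normalize(ft$dna, ft$markers),
                     mg_normalize(ft$rna, ft$markers))
e
#> <expression_profile> MG-ratio: 40 genes x 4 samples (0 missing cells)
#>   from: MG RNA profile / MG DNA profile
round(e$values[c("genome01_g0015", "genome02_g0015", "genome01_g0011"), ], 2)
#>                sample01 sample02 sample03 sample04
#> genome01_g0015     2.81     2.80     2.94     2.77
#> genome02_g0015     0.20     0.19     0.36     0.07
#> genome01_g0011     1.00     0.91     1.02     1.09
```

The induced gene sits near its planted fold change of 3, the repressed
gene near 0.25, and an untouched gene near 1 (expression relative to the
genome's housekeeping markers); the spread is Poisson counting noise at
depth 50. Ordination of the expression profiles:

```r
d <- bray_curtis(e)
round(d[1:2, 1:2], 3)
#>          sample01 sample02
#> sample01    0.000    0.084
#> sample02    0.084    0.000
pcoa(d)
#> <pcoa_result> 4 samples, 2 axes
#>   variance explained: 46.7%, 32.6%
```

Read-QC and overlap reporting work the same way:

```r
estimate_min_length_cutoff(c("40" = 5, "100" = 95))  # retain >= 95% of reads
#> [1] 100
overlap_percent(4651, 7217)  # shared KOs as a percent of the feature union
#> [1] 64.4
```

A thin command-line wrapper over the same functions ships at
`system.file("scripts", "metaexpress", package = "metaexpress")`, with
subcommands `simulate`, `minlen`, `adapters`, `mag-select`, `normalize`,
`integrate`, `funcprofile`, `overlap` and `taxa-summary`.

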