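---
title: "Integrating metagenomes and metatranscriptomes: methods and design notes"
author: "metaexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating metagenomes and metatranscriptomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaexpress)
```

## The problem

A microbial community's transcript pool changes for two distinct reasons:
individual genes are up- or down-regulated, or the organisms carrying those
genes change in abundance (*community turnover*). A metatranscriptome alone
cannot distinguish them. Pairing each RNA sample with a DNA sample from the
same community and dividing normalized transcript abundance by normalized
gene abundance, per gene and per sample, yields a *gene expression profile*
— the relative number of RNA molecules per DNA copy of a gene — in which
turnover has been divided out. `metaexpress` implements that integration
and the computational stages around it: read-QC estimators, selection of
non-redundant metagenome-assembled genomes (MAGs), count normalization,
functional aggregation and community ordination. External tools (trimmers,
aligners, assemblers, binners, annotators) stay external; this package
consumes their tabular outputs and produces the derived quantities.

## Normalization models

**TPM.** For gene $i$ with mapped-read count $n_i$ and length $l_i$ (bp),

$$\mathrm{TPM}(i) = \frac{n_i / l_i}{\sum_j n_j / l_j} \times 10^6,$$

with $j$ ranging over the genes of the sample. Columns with any signal sum
to $10^6$ by construction; `tpm_normalize()` keeps all-zero sample columns
at zero rather than missing, distinguishing "nothing detected" from "no
data". Counts may be fractional so that proportionally shared multi-mapper
counts from external profilers can be consumed unchanged.

**Marker genes (MG).** Ten universal single-copy phylogenetic marker COGs
(`marker_cogs()`: COG0012, COG0016, COG0018, COG0172, COG0215, COG0495,
COG0525, COG0533, COG0541, COG0552) occur once per genome and are
constitutively expressed, so the median of their length-normalized rates
estimates the genome's per-cell abundance. `mg_normalize()` computes

$$\mathrm{MG}(i) = \frac{n_i / l_i}{M(\mathrm{MGs})} \times 10^6,$$

where $M(\mathrm{MGs})$ is the median marker rate of gene $i$'s genome in
that sample. The result reads as gene abundance relative to housekeeping
abundance. Median convention: `stats::median` (middle element for odd
counts, mean of the two middle elements for even counts); if fewer than
ten markers are present in the table, the median is taken over those
available. If *all* of a genome's marker rates are zero in a sample, every
value of that genome is `NA` for that sample — the denominator carries no
information, and reporting zeros or infinities would fabricate signal.

## Integration

`gene_expression()` divides the RNA profile by the DNA profile entrywise,
on *normalized* profiles (both TPM or both MG). Zeros need explicit
semantics the ratio alone does not give:

* DNA $= 0$, any RNA: the gene is absent from the metagenome; a ratio
  would be infinite or $0/0$, so the entry is **missing**.
* DNA $> 0$, RNA $= 0$: present but silent — expression **0**.
* A missing input propagates to a missing output.

A subtlety worth stating plainly: because TPM renormalizes each layer to
$10^6$ separately, TPM-ratio expression recovers a planted per-gene fold
change only up to a per-sample compositional constant
($\sum_j d_j/l_j \,/\, \sum_j f_j d_j/l_j$). MG-ratio expression does not
suffer this: the marker genes are constitutively expressed (fold change 1),
so the marker-median denominator is identical in both layers and cancels,
and planted fold changes are recovered *exactly* on noiseless fixtures.
The test suite exercises both behaviors. `mg_normalized_expression()`
follows the two-step order: compute TPM-ratio expression first, then
divide by the genome's median marker expression per sample (median over
markers with defined expression; no marker expression, or a marker median
of exactly 0, leaves the genome missing in that sample — a zero median
means the housekeeping denominator is uninformative).

"Gene copy number" in the expression ratio is interpreted as the
normalized DNA abundance of the gene, not an integer copy estimate; the
ratio is what separates expression change from turnover, and any common
scale cancels.

## Read-QC estimators

`estimate_min_length_cutoff()` returns the largest length $L$ such that at
least a fraction `retain_fraction` (default 0.95) of reads are $\geq L$ —
the most stringent MINLEN an external trimmer can use while keeping the
predefined percentage of reads. Retained fraction only changes at observed
lengths, so those are the only candidates; the minimum observed length
retains 100%, so a solution always exists. Estimates below `floor_bp`
(default 50 bp) are raised to the floor. The estimator operates on
whatever histogram it is given — typically reads after a first
quality-trimming pass.

`detect_adapter_index()` scans the first 10,000 headers (configurable) and
reports the modal index, taken as the final colon-separated field of the
header comment under the Illumina CASAVA ≥ 1.8 convention
(`1:N:0:ACGTACGT`). Ties break to the lexicographically smallest sequence
so the call is deterministic. Translating the index into trimmer adapter
FASTA files is deliberately out of scope — the adapter template depends on
the library kit — so the call is emitted as a report.

## MAG scoring and dereplication

After external binning, quality estimation and ANI clustering (consumed as
a `cluster_id` column, typically at 99% identity), genomes are filtered
with *strict* inequalities — completeness > 90% and contamination < 5% by
default; the stricter completeness > 95% screen used in some analyses is
reachable via `completeness_min = 95` — then scored:

```
assembly_score = log10(longest_contig / n_contigs) + log10(N50 / L50)
genome_score   = completeness − 2 × contamination
final_score    = 0.1 × genome_score + assembly_score
```

and `select_representatives()` keeps the highest-scoring genome per
cluster, ties broken by smallest `mag_id`. The 0.1 weight makes a
10-point completeness gain worth one log-unit of contiguity.

## Functional profiles and overlap summaries

`aggregate_functions()` sums gene values into functions per annotation
database (eggNOG, KEGG KO/Pathway/Module, dbCAN, Pfam). A gene with
several annotations contributes its full value to each function — no
fractional splitting, matching common KO-profile practice; the aggregate
is therefore not mass-conserving under multi-label maps (it is, exactly,
under partition maps, and the tests assert this). Function-level
expression aggregates the gene expression ratios (sum of ratios); a
ratio-of-sums definition would weight genes by abundance and is a
different statistic — the choice is documented rather than hidden.
`overlap_summary()` reports set cardinalities and percentages of the union
rounded half-up to one decimal, matching how such tables are printed.

## Community summaries

`bray_curtis()` computes
$d(u,v) = 1 - 2\sum_i \min(u_i, v_i) / (\sum_i u_i + \sum_i v_i)$,
treating missing entries as 0 (the dissimilarity is undefined on missing
data and ordination needs a complete matrix) and defining $d = 0$ for two
all-zero samples. `pcoa()` is classical scaling via `stats::cmdscale`:
negative eigenvalues — expected for non-Euclidean dissimilarities like
Bray–Curtis — are simply truncated (no Cailliez/Lingoes correction) and
excluded from the variance-explained denominator; each axis's sign is
fixed so its largest-magnitude coordinate is positive, making ordinations
reproducible. `top_taxa()` ranks genera by *mean* relative abundance
across samples (median and max are available but mean is the default) and
adds an `"other"` row so columns still sum to 1 exactly.

## The synthetic fixture generator

`fixture_spec()` + `make_fastq()`/`make_count_tables()` generate every
input the package consumes, with known ground truth:

* reads with lengths drawn from a stated distribution under Illumina-style
  headers (index configurable), byte-deterministic under a seed;
* a gene universe of `n_genomes × genes_per_genome` genes with uniform
  random lengths in 300–1500 bp (typical bacterial CDS scale), DNA counts
  Poisson with mean `mean_depth` (default 50 mapped reads per gene — a
  realistic per-gene depth for stool metagenomes sequenced at ~10 M read
  pairs), and RNA counts equal to `fold × DNA`, Poisson-resampled unless
  noise is disabled. Poisson is the simplest generative model whose
  variance the recovery tests can bound analytically; the integration
  arithmetic itself assumes no particular noise model.
* the first ten genes of each genome registered as its marker COGs with
  fold change forced to 1 (housekeeping behavior), and at least one KEGG
  KO annotation per gene.

The generator emulates count structure, not sequencing: no base errors,
adapters, host or rRNA contamination, overdispersion beyond Poisson, or
correlated gene abundances. Passing tests therefore demonstrate the
*arithmetic* of the pipeline stages — normalization identities, recovery
of planted signals, invariances — not robustness to the full messiness of
real libraries, where count overdispersion and mapping artifacts add
error the fixtures do not model.

## Problem sizes and tolerances

The test suite runs at desk scale by design: count tables of 1–50 genes
and up to 6 samples for exact identities; 100 random tables for the TPM
column-sum property (relative tolerance 1e-6, brute-force double-loop
comparison at 1e-12 for tables of ≤ 20 genes); 1,000 randomized
histograms against an exhaustive-scan oracle; 200 random MAG records
including planted ties; and fold-change recovery on 1,000 genes × 2
samples at mean depth 50 over 10 seeds, where the median absolute
relative error of MG-ratio expression is required to stay under 0.2
(Poisson theory predicts ≈ 0.1–0.17 across the planted folds 0.5–2).
PCoA must reconstruct planted 2-D Euclidean configurations to 1e-9.

## Known limitations

* Alignment, binning, quality estimation and annotation quality are
  upstream concerns; garbage tables in, garbage profiles out.
* MG normalization requires markers detectable in the sample; shallow
  samples yield missing values for whole genomes, by design.
* TPM-ratio expression is compositional per sample (see above); prefer
  MG-ratio when marker maps are available.
* Mappability takes numerator and denominator from the caller and cannot
  verify they share a unit (reads vs read pairs); it only checks
  mapped ≤ total.
* Bray–Curtis on expression profiles treats missing entries as zeros,
  which conflates "undefined" with "silent" for ordination purposes.
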