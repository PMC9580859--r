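#' Specify a synthetic meta-omics fixture
#'
#' Bundles the parameters of the synthetic data generator: a read-length
#' distribution for FASTQ simulation and a paired DNA/RNA count model over
#' `n_genomes` genomes with `genes_per_genome` genes each. The RNA table is
#' the DNA table scaled per gene by `expression_fold_changes`, optionally
#' resampled with Poisson noise, so the planted fold change is the ground
#' truth every integration test can check against.
#'
#' @param seed Integer seed; identical specs (including seed) reproduce
#'   byte-identical outputs.
#' @param n_reads Number of reads for [make_fastq()].
#' @param length_distribution Named numeric vector: names are read lengths
#'   (bp), values are probabilities summing to 1 (tolerance 1e-9).
#' @param n_genomes,genes_per_genome Shape of the synthetic gene universe.
#'   `genes_per_genome` must be at least 10 so each genome can carry the ten
#'   marker COGs.
#' @param n_samples Number of paired DNA/RNA samples.
#' @param mean_depth Mean mapped reads per gene per sample (Poisson mean of
#'   the DNA counts).
#' @param expression_fold_changes Per-gene RNA/DNA multiplier: `NULL` (all
#'   1), a single number, an unnamed vector of length
#'   `n_genomes * genes_per_genome` (matched by gene position), or a named
#'   vector matched to generated gene ids (unnamed genes get 1). Must be
#'   positive.
#' @param rna_noise If `TRUE` (default), RNA counts are Poisson-resampled
#'   around `fold * DNA`; if `FALSE`, RNA equals `fold * DNA` exactly.
#' @return An object of class `fixture_spec`.
#' @seealso [make_fastq()], [make_count_tables()], [make_gff()]
#' @export
fixture_spec <- function(seed = 1L,
                         n_reads = 1000L,
                         length_distribution = c("100" = 1),
                         n_genomes = 3L,
                         genes_per_genome = 20L,
                         n_samples = 4L,
                         mean_depth = 50,
                         expression_fold_changes = NULL,
                         rna_noise = TRUE) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_reads, "n_reads", min = 1)
  assert_scalar_number(n_genomes, "n_genomes", min = 1)
  assert_scalar_number(genes_per_genome, "genes_per_genome", min = 1)
  assert_scalar_number(n_samples, "n_samples", min = 1)
  assert_scalar_number(mean_depth, "mean_depth", min = 0)
  if (!length(length_distribution)) stopf("length_distribution must be non-empty")
  lens <- suppressWarnings(as.integer(names(length_distribution)))
  if (anyNA(lens) || any(lens <= 0))
    stopf("length_distribution names must be positive integer read lengths")
  if (abs(sum(length_distribution) - 1) > 1e-9)
    stopf("length_distribution probabilities must sum to 1 (got %.12f)",
          sum(length_distribution))
  if (!is.null(expression_fold_changes) &&
      (any(!is.finite(expression_fold_changes)) || any(expression_fold_changes <= 0)))
    stopf("expression_fold_changes must be strictly positive")
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 length_distribution = length_distribution,
                 n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 n_samples = as.integer(n_samples),
                 mean_depth = mean_depth,
                 expression_fold_changes = expression_fold_changes,
                 rna_noise = isTRUE(rna_noise)),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(paste0("<fixture_spec> seed %d: %d reads; %d genomes x %d genes x %d samples; ",
                     "mean depth %g; RNA noise %s\n"),
              x$seed, x$n_reads, x$n_genomes, x$genes_per_genome, x$n_samples,
              x$mean_depth, if (x$rna_noise) "on" else "off"))
  invisible(x)
}

#' Write a synthetic FASTQ file
#'
#' Simulates `spec$n_reads` reads with lengths drawn from
#' `spec$length_distribution`, random ACGT sequence and constant quality,
#' under Illumina CASAVA >= 1.8 headers whose comment ends in the index
#' field (`1:N:0:<index>`) so that [detect_adapter_index()] can parse it.
#' A path ending in `.gz` is written gzip-compressed.
#'
#' @param spec A [fixture_spec()].
#' @param out_path Output file path (`.fastq` or `.fastq.gz`).
#' @param index Index sequence placed in every header.
#' @return The realized read-length histogram, an object of class
#'   `length_histogram` (named integer vector, length -> count), invisibly
#'   matching what [length_histogram()] returns on the written file.
#' @export
make_fastq <- function(spec, out_path, index = "ACGTACGT") {
  stopifnot(inherits(spec, "fixture_spec"))
  lens <- as.integer(names(spec$length_distribution))
  reads <- with_seed(spec$seed, {
    rl <- lens[sample.int(length(lens), spec$n_reads, replace = TRUE,
                          prob = spec$length_distribution)]
    seqs <- vapply(rl, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
    list(lengths = rl, seqs = seqs)
  })
  hdr <- sprintf("@SIM:1:FC1:1:1:%d:%d 1:N:0:%s",
                 seq_len(spec$n_reads), seq_len(spec$n_reads), index)
  qual <- strrep("I", reads$lengths)
  lines <- as.vector(rbind(hdr, reads$seqs, "+", qual))
  con <- if (grepl("\\.gz$", out_path)) gzfile(out_path, "wb") else file(out_path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  tab <- table(reads$lengths)
  hist <- stats::setNames(as.integer(tab), names(tab))
  invisible(structure(hist, class = "length_histogram"))
}

resolve_fold_changes <- function(fc, gene_ids) {
  n <- length(gene_ids)
  if (is.null(fc)) return(stats::setNames(rep(1, n), gene_ids))
  if (is.null(names(fc))) {
    if (length(fc) == 1L) return(stats::setNames(rep(fc, n), gene_ids))
    if (length(fc) != n)
      stopf("unnamed expression_fold_changes must have length 1 or %d", n)
    return(stats::setNames(as.numeric(fc), gene_ids))
  }
  unknown <- setdiff(names(fc), gene_ids)
  if (length(unknown))
    stopf("fold changes given for unknown gene(s): %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  out <- stats::setNames(rep(1, n), gene_ids)
  out[names(fc)] <- fc
  out
}

#' Generate paired synthetic DNA/RNA count tables with known ground truth
#'
#' Builds a gene universe of `n_genomes * genes_per_genome` genes with
#' random lengths, draws DNA counts as Poisson(`mean_depth`) per gene per
#' sample, and sets RNA counts to `fold * DNA` — exactly when
#' `rna_noise = FALSE`, or Poisson-resampled around that mean otherwise.
#' The first ten genes of every genome are registered as its single-copy
#' markers (one per COG in [marker_cogs()]) with fold change fixed at 1 so
#' they behave as constitutively expressed housekeeping genes; every gene
#' receives at least one KEGG KO annotation.
#'
#' @param spec A [fixture_spec()]; `genes_per_genome` must be >= 10.
#' @return A list with elements `dna` and `rna` ([gene_count_table()]s over
#'   the same gene universe), `markers` (a [marker_gene_map()]),
#'   `annotations` (an [annotation_map()] for KEGG_ko), and `fold_changes`
#'   (the resolved per-gene ground-truth multipliers).
#' @export
make_count_tables <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$genes_per_genome < 10L)
    stopf("genes_per_genome must be >= 10 to place the ten marker COGs (got %d)",
          spec$genes_per_genome)
  genome_ids <- sprintf("genome%02d", seq_len(spec$n_genomes))
  gene_ids <- as.vector(vapply(genome_ids, function(g)
    sprintf("%s_g%04d", g, seq_len(spec$genes_per_genome)),
    character(spec$genes_per_genome)))
  sample_ids <- sprintf("sample%02d", seq_len(spec$n_samples))
  n_genes <- length(gene_ids)

  fold <- resolve_fold_changes(spec$expression_fold_changes, gene_ids)
  # markers model constitutive housekeeping expression: force fold 1
  marker_idx <- as.vector(outer(seq_len(10L),
                                (seq_len(spec$n_genomes) - 1L) * spec$genes_per_genome, "+"))
  fold[marker_idx] <- 1

  gen <- with_seed(spec$seed, {
    lengths <- stats::setNames(sample(300:1500, n_genes, replace = TRUE), gene_ids)
    dna <- matrix(as.numeric(stats::rpois(n_genes * spec$n_samples, spec$mean_depth)),
                  nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    rna_mean <- dna * fold[gene_ids]
    rna <- if (spec$rna_noise)
      matrix(as.numeric(stats::rpois(length(rna_mean), rna_mean)),
             nrow = n_genes, dimnames = dimnames(dna))
    else rna_mean
    ko_pool <- sprintf("K%05d", sample(1:20000, max(4L, n_genes %/% 2)))
    relations <- lapply(seq_len(n_genes), function(i)
      unique(sample(ko_pool, sample(1:2, 1), replace = FALSE)))
    names(relations) <- gene_ids
    list(lengths = lengths, dna = dna, rna = rna, relations = relations)
  })

  gene_to_genome <- stats::setNames(rep(genome_ids, each = spec$genes_per_genome),
                                    gene_ids)
  entries <- lapply(genome_ids, function(g)
    stats::setNames(gene_ids[gene_to_genome == g][seq_len(10L)], marker_cogs()))
  names(entries) <- genome_ids

  list(dna = gene_count_table(gen$dna, gen$lengths, layer = "DNA"),
       rna = gene_count_table(gen$rna, gen$lengths, layer = "RNA"),
       markers = marker_gene_map(entries, gene_to_genome),
       annotations = annotation_map(gen$relations, database = "KEGG_ko"),
       fold_changes = fold)
}

#' Write a minimal GFF3 file for a set of gene lengths
#'
#' Lays the genes of a count table (or a named length vector) end to end on
#' one synthetic contig as CDS features whose `ID` attribute is the gene id
#' and whose 1-based inclusive coordinates reproduce the given lengths.
#' Useful for round-trip testing of [gene_lengths_from_gff()].
#'
#' @param lengths A [gene_count_table()] or a named vector of gene lengths
#'   (bp).
#' @param out_path Output GFF3 path.
#' @return `out_path`, invisibly.
#' @export
make_gff <- function(lengths, out_path) {
  if (inherits(lengths, "gene_count_table")) lengths <- lengths$lengths
  if (is.null(names(lengths)) || any(lengths <= 0))
    stopf("'lengths' must be a named vector of positive gene lengths")
  ends <- cumsum(as.integer(lengths))
  starts <- ends - as.integer(lengths) + 1L
  lines <- c("##gff-version 3",
             sprintf("contig1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=%s",
                     starts, ends, names(lengths)))
  writeLines(lines, out_path)
  invisible(out_path)
}
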