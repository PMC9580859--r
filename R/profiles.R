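# Normalization of per-gene read counts into abundance profiles (TPM or
# marker-gene units), the optional minimum-mapped-reads filter, gene-length
# extraction from GFF3, and the mappability ratio.

#' Extract gene lengths from a GFF3 file
#'
#' Reads the features of the requested type(s) and returns their lengths
#' computed from the 1-based inclusive GFF3 coordinates
#' (`end - start + 1`); strand is irrelevant for length. The gene
#' identifier is taken from the `ID` attribute. Duplicate IDs are an error
#' rather than silently merged, since merging would corrupt lengths.
#'
#' @param gff Path to a GFF3 file.
#' @param feature_types Feature types (column 3) to extract; default `CDS`.
#' @return Named integer vector: gene id -> length (bp).
#' @export
gene_lengths_from_gff <- function(gff, feature_types = "CDS") {
  if (!file.exists(gff)) stopf("GFF file not found: %s", gff)
  lines <- readLines(gff)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  ids <- character(0)
  lens <- integer(0)
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stopf("GFF line %d: expected 9 tab-separated columns, found %d", i, length(f))
    if (!f[3L] %in% feature_types) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end))
      stopf("GFF line %d: non-numeric coordinates", i)
    if (end < start)
      stopf("GFF line %d: end (%d) < start (%d)", i, end, start)
    m <- regmatches(f[9L], regexec("(^|;)ID=([^;]+)", f[9L]))[[1L]]
    if (length(m) < 3L || !nzchar(m[3L]))
      stopf("GFF line %d: feature has no ID attribute", i)
    id <- m[3L]
    if (id %in% ids)
      stopf("GFF line %d: duplicate feature ID '%s'", i, id)
    ids <- c(ids, id)
    lens <- c(lens, end - start + 1L)
  }
  stats::setNames(lens, ids)
}

#' Zero out counts below a minimum mapped-read threshold
#'
#' Entries strictly below `min_mapped_reads` are set to 0; entries equal to
#' the threshold are kept (an inclusive minimum). The default threshold of
#' 0 leaves the table unchanged; for deeply sequenced metagenomes
#' (> 10 million read pairs) a threshold of 10 is a sensible choice to
#' suppress spurious low-count alignments.
#'
#' @param t A [gene_count_table()].
#' @param min_mapped_reads Non-negative threshold.
#' @return A [gene_count_table()] with filtered counts.
#' @export
apply_min_reads_filter <- function(t, min_mapped_reads = 0) {
  stopifnot(inherits(t, "gene_count_table"))
  assert_scalar_number(min_mapped_reads, "min_mapped_reads", min = 0)
  t$counts[t$counts < min_mapped_reads] <- 0
  t
}

#' TPM-normalize a gene count table
#'
#' Computes, per sample, \eqn{TPM(i) = (n_i/l_i) / \sum_j (n_j/l_j) \times 10^6}
#' where \eqn{n_i} is the count of gene \eqn{i}, \eqn{l_i} its length in bp
#' and \eqn{j} ranges over the genes of the table, so every sample column
#' with any signal sums to one million. An all-zero sample column stays
#' all-zero ("nothing detected"), not missing ("no data").
#'
#' @param t A [gene_count_table()].
#' @return An `abundance_profile` with `normalization = "TPM"` and the
#'   layer of `t`.
#' @export
#' @examples
#' t <- gene_count_table(matrix(c(10, 20, 30), 3, 1,
#'                              dimnames = list(c("a", "b", "c"), "s1")),
#'                       c(a = 100, b = 100, c = 300))
#' tpm_normalize(t)$values  # 250000, 500000, 250000
tpm_normalize <- function(t) {
  stopifnot(inherits(t, "gene_count_table"))
  rates <- t$counts / t$lengths
  totals <- colSums(rates)
  vals <- sweep(rates, 2L, ifelse(totals > 0, totals, 1), "/") * 1e6
  vals[, totals == 0] <- 0
  new_abundance_profile(vals, normalization = "TPM", layer = t$layer)
}

genome_marker_rates <- function(rates, m, genomes) {
  # per genome: matrix of marker-gene rows present in the table
  lapply(genomes, function(g) {
    markers <- m$entries[[g]]
    if (is.null(markers) || length(markers) == 0L)
      stopf("genome '%s' has no registered marker genes", g)
    present <- intersect(markers, rownames(rates))
    if (!length(present))
      stopf("none of genome '%s's marker genes appear in the count table", g)
    rates[present, , drop = FALSE]
  })
}

#' Marker-gene-normalize a gene count table
#'
#' Divides each gene's length-normalized rate \eqn{n_i/l_i} by the median
#' rate of the ten universal single-copy marker genes of the gene's genome
#' in that sample, times \eqn{10^6}:
#' \eqn{MG(i) = (n_i/l_i) / M(MGs) \times 10^6}. The result reads as gene
#' abundance relative to the genome's per-cell (housekeeping) abundance.
#' If fewer than ten markers are present in the table the median is taken
#' over those available; if all of a genome's marker rates are zero in a
#' sample, that genome's values are missing (`NA`) for that sample — the
#' denominator carries no information there.
#'
#' @param t A [gene_count_table()] whose genes are all covered by `m`.
#' @param m A [marker_gene_map()].
#' @return An `abundance_profile` with `normalization = "MG"`.
#' @export
mg_normalize <- function(t, m) {
  stopifnot(inherits(t, "gene_count_table"), inherits(m, "marker_gene_map"))
  unmapped <- setdiff(rownames(t$counts), names(m$gene_to_genome))
  if (length(unmapped))
    stopf("gene(s) not mapped to a genome: %s",
          paste(utils::head(unmapped, 5), collapse = ", "))
  rates <- t$counts / t$lengths
  genome_of <- m$gene_to_genome[rownames(rates)]
  genomes <- unique(genome_of)
  marker_rates <- genome_marker_rates(rates, m, genomes)
  names(marker_rates) <- genomes
  vals <- rates
  for (g in genomes) {
    med <- apply(marker_rates[[g]], 2L, stats::median)
    rows <- genome_of == g
    denom <- ifelse(med > 0, med, NA_real_)
    vals[rows, ] <- sweep(rates[rows, , drop = FALSE], 2L, denom, "/") * 1e6
  }
  new_abundance_profile(vals, normalization = "MG", layer = t$layer)
}

#' Mappability ratio
#'
#' Fraction of sequencing inserts that aligned to the reference gene or
#' genome set. Numerator and denominator must be counted in the same unit
#' (both reads, or both read pairs).
#'
#' @param mapped_inserts Non-negative count of aligned inserts.
#' @param total_inserts Positive count of quality-filtered inserts.
#' @return Fraction in \[0, 1\].
#' @export
mappability <- function(mapped_inserts, total_inserts) {
  assert_scalar_number(mapped_inserts, "mapped_inserts", min = 0)
  assert_scalar_number(total_inserts, "total_inserts", min = 0, allow_zero = FALSE)
  if (mapped_inserts > total_inserts)
    stopf("mapped_inserts (%s) exceeds total_inserts (%s)",
          format(mapped_inserts), format(total_inserts))
  mapped_inserts / total_inserts
}
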