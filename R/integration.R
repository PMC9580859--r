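# Integration of DNA and RNA abundance profiles into gene-expression
# profiles: the RNA/DNA ratio separates per-gene expression change from
# community turnover (changes in member and gene abundance).

check_aligned <- function(a, b, what) {
  d1 <- c(setdiff(rownames(a), rownames(b)), setdiff(rownames(b), rownames(a)))
  d2 <- c(setdiff(colnames(a), colnames(b)), setdiff(colnames(b), colnames(a)))
  if (length(d1) || length(d2))
    stopf("DNA and RNA profiles disagree on %s: %s", what,
          paste(utils::head(unique(c(d1, d2)), 10), collapse = ", "))
}

#' Compute a gene-expression profile from paired DNA and RNA profiles
#'
#' Gene expression is the relative amount of RNA molecules per DNA copy of
#' a gene: entrywise `rna / dna` over matching normalized profiles (both
#' TPM or both MG). Where the DNA abundance is 0 the gene is absent from
#' the metagenome and the ratio is undefined, so the entry is missing
#' (`NA`) regardless of the RNA value; where DNA is positive and RNA is 0
#' the gene is present but silent and the entry is 0. Missing inputs
#' propagate to missing.
#'
#' @param dna,rna `abundance_profile`s over identical gene and sample sets
#'   with the same normalization scheme; `dna` must carry layer `"DNA"`
#'   and `rna` layer `"RNA"`.
#' @return An `expression_profile` with normalization `"TPM-ratio"` or
#'   `"MG-ratio"`.
#' @export
gene_expression <- function(dna, rna) {
  stopifnot(inherits(dna, "abundance_profile"), inherits(rna, "abundance_profile"))
  if (dna$layer != "DNA" || rna$layer != "RNA")
    stopf("expected a DNA-layer and an RNA-layer profile (got %s and %s)",
          dna$layer, rna$layer)
  if (dna$normalization != rna$normalization)
    stopf("profiles use different normalizations: %s vs %s",
          dna$normalization, rna$normalization)
  check_aligned(dna$values, rna$values, "genes/samples")
  d <- dna$values
  r <- rna$values[rownames(d), colnames(d), drop = FALSE]
  vals <- r / d
  vals[!is.na(d) & d == 0] <- NA_real_
  new_expression_profile(vals,
                         normalization = paste0(dna$normalization, "-ratio"),
                         provenance = c(dna = paste(dna$normalization, "DNA profile"),
                                        rna = paste(rna$normalization, "RNA profile")))
}

#' Normalize a gene-expression profile by marker-gene expression
#'
#' Divides each gene's expression by the median expression of its genome's
#' single-copy marker genes in that sample, yielding expression relative
#' to constitutively expressed housekeeping genes. The median is taken
#' over markers with non-missing expression; if none is available — or the
#' marker median is 0, leaving no informative denominator — the genome's
#' entries are missing in that sample.
#'
#' @param e An `expression_profile` with normalization `"TPM-ratio"`, all
#'   of whose genes are covered by `m`.
#' @param m A [marker_gene_map()].
#' @return An `expression_profile` with normalization `"MG-ratio"`.
#' @export
mg_normalized_expression <- function(e, m) {
  stopifnot(inherits(e, "expression_profile"), inherits(m, "marker_gene_map"))
  unmapped <- setdiff(rownames(e$values), names(m$gene_to_genome))
  if (length(unmapped))
    stopf("gene(s) not mapped to a genome: %s",
          paste(utils::head(unmapped, 5), collapse = ", "))
  vals <- e$values
  genome_of <- m$gene_to_genome[rownames(vals)]
  for (g in unique(genome_of)) {
    markers <- m$entries[[g]]
    if (is.null(markers) || length(markers) == 0L)
      stopf("genome '%s' has no registered marker genes", g)
    present <- intersect(markers, rownames(vals))
    if (!length(present))
      stopf("none of genome '%s's marker genes appear in the expression profile", g)
    med <- apply(vals[present, , drop = FALSE], 2L, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) NA_real_ else stats::median(x)
    })
    med[!is.na(med) & med == 0] <- NA_real_
    rows <- genome_of == g
    vals[rows, ] <- sweep(e$values[rows, , drop = FALSE], 2L, med, "/")
  }
  new_expression_profile(vals, normalization = "MG-ratio",
                         provenance = e$provenance)
}

#' Count genes expressed in at least one sample
#'
#' A gene counts as expressed if it has a defined (non-missing), strictly
#' positive expression entry in at least one sample.
#'
#' @param e An `expression_profile`.
#' @return Integer count.
#' @export
count_expressed_genes <- function(e) {
  stopifnot(inherits(e, "expression_profile"))
  sum(apply(e$values > 0, 1L, function(x) any(x, na.rm = TRUE)))
}
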