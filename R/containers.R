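#' Universal single-copy marker-gene COG identifiers
#'
#' The ten universal single-copy phylogenetic marker-gene orthologous groups
#' used for marker-gene (MG) normalization. These housekeeping genes are
#' present in a single copy in essentially all bacterial and archaeal
#' genomes, so the median of their length-normalized abundances estimates a
#' genome's per-cell abundance in a sample.
#'
#' @return Character vector of ten COG identifiers.
#' @export
#' @examples
#' marker_cogs()
marker_cogs <- function() {
  c("COG0012", "COG0016", "COG0018", "COG0172", "COG0215",
    "COG0495", "COG0525", "COG0533", "COG0541", "COG0552")
}

#' Construct a gene count table
#'
#' A genes x samples matrix of mapped-read counts together with per-gene
#' lengths (bp) and the omics layer the counts come from. Counts may be
#' fractional: proportionally shared multi-mapper counts produced by external
#' profilers are accepted as-is.
#'
#' @param counts Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids); non-negative and finite.
#' @param lengths Named numeric vector of gene lengths in bp covering every
#'   gene in `counts`; strictly positive.
#' @param layer `"DNA"` (metagenome) or `"RNA"` (metatranscriptome).
#' @return An object of class `gene_count_table`.
#' @export
gene_count_table <- function(counts, lengths, layer = c("DNA", "RNA")) {
  layer <- match.arg(layer)
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stopf("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("'counts' must have gene rownames and sample colnames")
  if (anyNA(counts) || any(!is.finite(counts)))
    stopf("counts must be finite and non-missing")
  if (any(counts < 0)) stopf("counts must be non-negative")
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stopf("no length for gene(s): %s", paste(utils::head(missing_len, 5), collapse = ", "))
  lengths <- lengths[rownames(counts)]
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stopf("gene lengths must be strictly positive")
  structure(list(counts = counts, lengths = lengths, layer = layer),
            class = "gene_count_table")
}

#' @export
print.gene_count_table <- function(x, ...) {
  cat(sprintf("<gene_count_table> %s layer: %d genes x %d samples\n",
              x$layer, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  gene length range: %d-%d bp; total counts: %.1f\n",
              min(x$lengths), max(x$lengths), sum(x$counts)))
  invisible(x)
}

new_abundance_profile <- function(values, normalization, layer) {
  structure(list(values = values, normalization = normalization, layer = layer),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> %s-normalized %s layer: %d genes x %d samples (%d missing cells)\n",
              x$normalization, x$layer, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

new_expression_profile <- function(values, normalization, provenance) {
  structure(list(values = values, normalization = normalization,
                 provenance = provenance),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s: %d genes x %d samples (%d missing cells)\n",
              x$normalization, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat(sprintf("  from: %s / %s\n", x$provenance[["rna"]], x$provenance[["dna"]]))
  invisible(x)
}

#' Construct a marker-gene map
#'
#' Records which gene in each genome carries each of the ten universal
#' single-copy marker COGs (see [marker_cogs()]), and which genome every
#' gene belongs to. Both relations are needed for marker-gene normalization.
#'
#' @param entries Named list, one element per genome id; each element a
#'   named character vector mapping COG id (names, drawn from
#'   [marker_cogs()]) to the gene id carrying it. At most ten markers per
#'   genome.
#' @param gene_to_genome Named character vector mapping every gene id to its
#'   genome id. Must cover the marker genes.
#' @return An object of class `marker_gene_map`.
#' @export
marker_gene_map <- function(entries, gene_to_genome) {
  if (!is.list(entries) || is.null(names(entries)))
    stopf("'entries' must be a named list keyed by genome id")
  for (g in names(entries)) {
    e <- entries[[g]]
    if (length(e) > 10L) stopf("genome '%s' has more than 10 markers", g)
    bad <- setdiff(names(e), marker_cogs())
    if (length(bad))
      stopf("genome '%s': unknown marker COG id(s): %s", g, paste(bad, collapse = ", "))
    missing <- setdiff(e, names(gene_to_genome))
    if (length(missing))
      stopf("marker gene(s) absent from gene_to_genome: %s", paste(missing, collapse = ", "))
  }
  structure(list(entries = entries, gene_to_genome = gene_to_genome),
            class = "marker_gene_map")
}

#' @export
print.marker_gene_map <- function(x, ...) {
  cat(sprintf("<marker_gene_map> %d genomes, %d genes mapped, %d marker entries\n",
              length(x$entries), length(x$gene_to_genome),
              sum(lengths(x$entries))))
  invisible(x)
}

#' Construct a gene-to-function annotation map
#'
#' @param relations Named list mapping gene id to a character vector of
#'   function identifiers in `database`. Genes may be absent (unannotated).
#' @param database Annotation database the function identifiers come from.
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(relations,
                           database = c("eggNOG", "KEGG_ko", "KEGG_Pathway",
                                        "KEGG_Module", "dbCAN.mod",
                                        "dbCAN.enzclass", "Pfam")) {
  database <- match.arg(database)
  if (!is.list(relations) || (length(relations) && is.null(names(relations))))
    stopf("'relations' must be a named list keyed by gene id")
  fun_ids <- unlist(relations, use.names = FALSE)
  if (any(!nzchar(fun_ids))) stopf("function ids must be non-empty strings")
  structure(list(relations = relations, database = database),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %s: %d annotated genes, %d distinct functions\n",
              x$database, length(x$relations),
              length(unique(unlist(x$relations, use.names = FALSE)))))
  invisible(x)
}

new_function_profile <- function(values, database, layer) {
  structure(list(values = values, database = database, layer = layer),
            class = "function_profile")
}

#' @export
print.function_profile <- function(x, ...) {
  cat(sprintf("<function_profile> %s (%s layer): %d functions x %d samples\n",
              x$database, x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a taxa abundance profile
#'
#' @param values Numeric matrix, taxa as rows, samples as columns,
#'   non-negative.
#' @param taxonomy Data frame with one row per taxon (rownames matching
#'   `values`), carrying rank annotation columns such as `genus` and
#'   `species`.
#' @param form Whether values are raw `"count"`s, `"relative"` abundances
#'   (columns sum to 1) or `"percent"` (columns sum to 100).
#' @return An object of class `taxa_profile`.
#' @export
taxa_profile <- function(values, taxonomy, form = c("count", "relative", "percent")) {
  form <- match.arg(form)
  values <- as.matrix(values)
  if (any(values < 0) || anyNA(values)) stopf("taxa abundances must be non-negative")
  if (!is.data.frame(taxonomy) || !identical(rownames(taxonomy), rownames(values)))
    stopf("'taxonomy' must be a data.frame with rownames matching the value matrix")
  target <- c(count = NA_real_, relative = 1, percent = 100)[[form]]
  if (!is.na(target)) {
    cs <- colSums(values)
    if (any(abs(cs - target) > 1e-9 * max(1, target)))
      stopf("columns of a %s-form profile must sum to %s", form, target)
  }
  structure(list(values = values, taxonomy = taxonomy, form = form),
            class = "taxa_profile")
}

#' @export
print.taxa_profile <- function(x, ...) {
  cat(sprintf("<taxa_profile> %s form: %d taxa x %d samples (ranks: %s)\n",
              x$form, nrow(x$values), ncol(x$values),
              paste(names(x$taxonomy), collapse = ", ")))
  invisible(x)
}

profile_values <- function(p) {
  if (inherits(p, c("abundance_profile", "expression_profile",
                    "function_profile", "taxa_profile"))) p$values
  else if (is.matrix(p)) p
  else stopf("expected a profile object or a matrix")
}
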