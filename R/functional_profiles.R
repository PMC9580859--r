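# Aggregation of gene-level profiles into function-level profiles per
# annotation database, and overlap summaries between two functional
# profiles (e.g. MAG-based vs gene-catalog-based references).

#' Aggregate a gene profile into a function profile
#'
#' Groups genes into functions using an annotation map and sums their
#' values per sample. A gene annotated with several functions contributes
#' its full value to each of them (no fractional splitting); unannotated
#' genes are dropped. Missing gene entries are treated as absent from the
#' sum, and a function whose annotated genes are all missing in a sample
#' is missing there.
#'
#' @param p An `abundance_profile`, `expression_profile` or plain genes x
#'   samples matrix.
#' @param a An [annotation_map()] whose domain overlaps the profile genes.
#' @return A `function_profile` (functions x samples) tagged with the
#'   annotation database and the layer of `p` (`"expression"` for
#'   expression profiles).
#' @export
aggregate_functions <- function(p, a) {
  stopifnot(inherits(a, "annotation_map"))
  if (!length(a$relations)) stopf("annotation map is empty")
  vals <- profile_values(p)
  layer <- if (inherits(p, "expression_profile")) "expression"
           else p$layer %||% "DNA"
  genes <- intersect(rownames(vals), names(a$relations))
  if (!length(genes))
    stopf("no profile gene is covered by the annotation map")
  # invert gene -> functions into function -> genes
  rel <- a$relations[genes]
  fun_of <- data.frame(gene = rep(genes, lengths(rel)),
                       fun = unlist(rel, use.names = FALSE))
  funs <- sort(unique(fun_of$fun))
  out <- matrix(NA_real_, nrow = length(funs), ncol = ncol(vals),
                dimnames = list(funs, colnames(vals)))
  by_fun <- split(fun_of$gene, fun_of$fun)
  for (f in funs) {
    sub <- vals[by_fun[[f]], , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0L] <- NA_real_
    out[f, ] <- s
  }
  new_function_profile(out, database = a$database, layer = layer)
}

#' Functions detected in a profile
#'
#' A function is detected if it has a defined (non-missing), strictly
#' positive value in at least one sample.
#'
#' @param p A `function_profile`.
#' @return Character vector of detected function ids.
#' @export
detected_features <- function(p) {
  stopifnot(inherits(p, "function_profile"))
  hit <- apply(p$values > 0, 1L, function(x) any(x, na.rm = TRUE))
  rownames(p$values)[hit]
}

#' Percentage of a feature union, rounded as reported
#'
#' `100 * count / n_union` rounded half-up to one decimal — the rounding
#' used throughout [overlap_summary()] so printed percentages match
#' published tables.
#'
#' @param count Feature count (numerator).
#' @param n_union Union size (denominator, positive).
#' @return Percentage with one decimal.
#' @export
#' @examples
#' overlap_percent(4651, 7217)  # 64.4
overlap_percent <- function(count, n_union) {
  assert_scalar_number(count, "count", min = 0)
  assert_scalar_number(n_union, "n_union", min = 0, allow_zero = FALSE)
  round_half_up(100 * count / n_union, 1)
}

#' Summarize the overlap between two detected-feature sets
#'
#' Reports the cardinalities of two feature sets (e.g. KEGG KOs detected
#' against a MAG reference vs against a gene catalog), their intersection
#' and union, and shared/unique percentages of the union rounded half-up
#' to one decimal. With two empty sets the counts are zero and the
#' percentages undefined (`NA`).
#'
#' @param a,b Character vectors of feature ids (duplicates ignored).
#' @return An object of class `overlap_summary` with fields `n_a`, `n_b`,
#'   `n_shared`, `n_union`, `pct_shared`, `pct_unique_a`, `pct_unique_b`.
#' @export
overlap_summary <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  n_shared <- length(intersect(a, b))
  n_union <- length(union(a, b))
  pct <- function(x) if (n_union == 0L) NA_real_ else overlap_percent(x, n_union)
  structure(list(n_a = length(a), n_b = length(b),
                 n_shared = n_shared, n_union = n_union,
                 pct_shared = pct(n_shared),
                 pct_unique_a = pct(length(a) - n_shared),
                 pct_unique_b = pct(length(b) - n_shared)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> |A| = %d, |B| = %d, union %d\n",
              x$n_a, x$n_b, x$n_union))
  cat(sprintf("  shared: %d (%.1f%%); unique to A: %d (%.1f%%); unique to B: %d (%.1f%%)\n",
              x$n_shared, x$pct_shared,
              x$n_a - x$n_shared, x$pct_unique_a,
              x$n_b - x$n_shared, x$pct_unique_b))
  invisible(x)
}
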