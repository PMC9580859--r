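# Assembly-free community summaries: relative abundance, top-genus tables,
# Bray-Curtis dissimilarity and principal coordinate analysis.

#' Convert a count-form taxa profile to relative abundance
#'
#' Divides each sample column by its sum so columns sum to 1.
#'
#' @param p A [taxa_profile()] in count form.
#' @return A [taxa_profile()] in relative form.
#' @export
relative_abundance <- function(p) {
  stopifnot(inherits(p, "taxa_profile"))
  cs <- colSums(p$values)
  zero <- cs == 0
  if (any(zero))
    stopf("cannot normalize all-zero sample column(s): %s",
          paste(colnames(p$values)[zero], collapse = ", "))
  taxa_profile(sweep(p$values, 2L, cs, "/"), p$taxonomy, form = "relative")
}

#' Most abundant taxa at a rank, with an "other" remainder
#'
#' Sums abundance to the requested taxonomic rank, ranks the resulting
#' taxa by their mean (or median/max) relative abundance across samples,
#' and returns the top `k` plus an `"other"` row holding the remainder so
#' column sums are preserved exactly. With `k` at or above the number of
#' distinct taxa, all are returned and no `"other"` row is added.
#'
#' @param p A [taxa_profile()] in relative (or percent) form with the rank
#'   annotated in its taxonomy table.
#' @param rank Taxonomy column to aggregate to (default `"genus"`).
#' @param k Number of top taxa to keep (default 15).
#' @param stat Ranking statistic across samples; `"mean"` by default.
#' @return A [taxa_profile()] over at most `k + 1` rank-level taxa.
#' @export
top_taxa <- function(p, rank = "genus", k = 15L, stat = c("mean", "median", "max")) {
  stopifnot(inherits(p, "taxa_profile"))
  stat <- match.arg(stat)
  assert_scalar_number(k, "k", min = 1)
  if (!rank %in% names(p$taxonomy))
    stopf("taxonomy has no '%s' rank annotation", rank)
  agg <- rowsum(p$values, group = p$taxonomy[[rank]])
  score <- switch(stat,
                  mean = rowMeans(agg),
                  median = apply(agg, 1L, stats::median),
                  max = apply(agg, 1L, max))
  ord <- order(score, decreasing = TRUE)
  top <- agg[utils::head(ord, k), , drop = FALSE]
  if (nrow(agg) > k) {
    other <- colSums(agg) - colSums(top)
    # clamp tiny negative residue from floating-point cancellation
    other[other < 0 & other > -1e-12] <- 0
    top <- rbind(top, other = other)
  }
  tax <- data.frame(row.names = rownames(top))
  tax[[rank]] <- rownames(top)
  taxa_profile(top, tax, form = p$form)
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computes \eqn{d(u, v) = 1 - 2\sum_i \min(u_i, v_i) / (\sum_i u_i + \sum_i v_i)}
#' between every pair of sample columns. Missing entries are treated as 0
#' (the dissimilarity is undefined on missing data and ordination needs a
#' complete matrix); a pair of all-zero columns gets distance 0.
#'
#' @param p A `taxa_profile`, `function_profile`, `abundance_profile`,
#'   `expression_profile` or plain non-negative matrix with samples as
#'   columns.
#' @return Symmetric samples x samples matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
bray_curtis <- function(p) {
  vals <- profile_values(p)
  vals[is.na(vals)] <- 0
  if (any(vals < 0)) stopf("Bray-Curtis requires non-negative values")
  n <- ncol(vals)
  cs <- colSums(vals)
  d <- matrix(0, n, n, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      tot <- cs[i] + cs[j]
      d[i, j] <- d[j, i] <-
        if (tot == 0) 0 else 1 - 2 * sum(pmin(vals[, i], vals[, j])) / tot
    }
  }
  d
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the doubly centered matrix of squared
#' distances is eigendecomposed and coordinates are eigenvectors scaled by
#' the square roots of the positive eigenvalues (negative eigenvalues,
#' which arise for non-Euclidean dissimilarities such as Bray-Curtis, are
#' excluded from both the coordinates and the variance-explained
#' denominator; no Cailliez/Lingoes correction is applied). Each axis's
#' sign is fixed so its largest-magnitude coordinate is positive, making
#' ordinations reproducible across platforms.
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @param n_axes Number of coordinate axes requested (default 2). If fewer
#'   positive eigenvalues exist, the available axes are returned with a
#'   warning.
#' @return An object of class `pcoa_result`: `points` (samples x axes),
#'   `eigenvalues` (all, descending) and `variance_explained` (per
#'   returned axis, as a fraction of the positive-eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stopf("'d' must be a square distance matrix")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 0)) stopf("distance matrix diagonal must be zero")
  assert_scalar_number(n_axes, "n_axes", min = 1)
  n <- nrow(d)
  # cmdscale warns whenever rank < n - 1; low-rank configurations are
  # expected here and handled below, so silence that internal warning
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig), 1e-300) * sqrt(.Machine$double.eps)
  n_pos <- sum(eig > tol)
  if (n_axes > n_pos) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                    n_pos, n_pos), call. = FALSE)
    n_axes <- n_pos
  }
  if (n_axes == 0L) {
    # all samples coincide: no informative axes
    pts <- matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(d), NULL))
    return(structure(list(points = pts,
                          eigenvalues = sort(eig, decreasing = TRUE),
                          variance_explained = numeric(0)),
                     class = "pcoa_result"))
  }
  pts <- fit$points[, seq_len(n_axes), drop = FALSE]
  for (a in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, a]))
    if (pts[i, a] < 0) pts[, a] <- -pts[, a]
  }
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  rownames(pts) <- rownames(d)
  structure(list(points = pts,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 variance_explained = eig[seq_len(n_axes)] / sum(eig[eig > tol])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' @export
#' @importFrom graphics text
plot.pcoa_result <- function(x, axes = c(1L, 2L), labels = rownames(x$points), ...) {
  if (ncol(x$points) < max(axes))
    stopf("result has only %d axis/axes", ncol(x$points))
  ve <- 100 * x$variance_explained[axes]
  plot(x$points[, axes[1L]], x$points[, axes[2L]],
       xlab = sprintf("PCo%d (%.1f%%)", axes[1L], ve[1L]),
       ylab = sprintf("PCo%d (%.1f%%)", axes[2L], ve[2L]), ...)
  if (!is.null(labels))
    text(x$points[, axes[1L]], x$points[, axes[2L]], labels = labels,
         pos = 3, cex = 0.7)
  invisible(x)
}
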