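# shared generators for property-style tests

random_histogram <- function(max_lengths = 10L) {
  n <- sample.int(max_lengths, 1L)
  lens <- sort(sample(20:250, n))
  setNames(sample.int(500L, n, replace = TRUE), lens)
}

# independent oracle: scan every observed length, keep the largest whose
# retained fraction meets the target, then apply the floor
cutoff_by_scan <- function(hist, retain = 0.95, floor_bp = 50L) {
  lens <- as.integer(names(hist))
  total <- sum(hist)
  ok <- vapply(lens, function(L) sum(hist[lens >= L]) / total >= retain, logical(1))
  max(max(lens[ok]), floor_bp)
}

random_mag_records <- function(n, n_clusters = 5L, tie_pairs = 0L) {
  longest <- sample(1e5:2e6, n)
  n50 <- pmax(1L, as.integer(longest * runif(n, 0.1, 1)))
  n_contigs <- sample(1:300, n, replace = TRUE)
  rec <- data.frame(
    mag_id = sprintf("mag%03d", seq_len(n)),
    completeness = runif(n, 50, 100),
    contamination = runif(n, 0, 10),
    n_contigs = n_contigs,
    longest_contig_bp = longest,
    n50_bp = n50,
    l50 = pmax(1L, as.integer(n_contigs * runif(n, 0.05, 1))),
    cluster_id = sample(sprintf("cl%02d", seq_len(n_clusters)), n, replace = TRUE))
  if (tie_pairs > 0L) {
    # duplicate some rows under new ids so ties genuinely occur
    dup <- rec[sample.int(n, tie_pairs), , drop = FALSE]
    dup$mag_id <- paste0(dup$mag_id, "_tie")
    rec <- rbind(rec, dup)
  }
  rec
}

random_count_table <- function(n_genes = NULL, n_samples = NULL, layer = "DNA") {
  if (is.null(n_genes)) n_genes <- sample(2:30, 1L)
  if (is.null(n_samples)) n_samples <- sample(1:6, 1L)
  genes <- sprintf("g%03d", seq_len(n_genes))
  counts <- matrix(rpois(n_genes * n_samples, 40), n_genes,
                   dimnames = list(genes, sprintf("s%02d", seq_len(n_samples))))
  gene_count_table(counts, setNames(sample(200:2000, n_genes, replace = TRUE), genes),
                   layer = layer)
}

# independent oracle for TPM: explicit double loop over genes and samples
tpm_by_loops <- function(t) {
  out <- t$counts * NA_real_
  for (s in seq_len(ncol(t$counts))) {
    denom <- 0
    for (g in seq_len(nrow(t$counts)))
      denom <- denom + t$counts[g, s] / t$lengths[g]
    for (g in seq_len(nrow(t$counts)))
      out[g, s] <- if (denom > 0) (t$counts[g, s] / t$lengths[g]) / denom * 1e6 else 0
  }
  out
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b), na.rm = TRUE), tol)
}
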