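paired_profiles <- function(dna_counts, rna_counts, lengths) {
  genes <- names(lengths)
  dn <- gene_count_table(matrix(dna_counts, length(genes), 1,
                                dimnames = list(genes, "s1")), lengths, "DNA")
  rn <- gene_count_table(matrix(rna_counts, length(genes), 1,
                                dimnames = list(genes, "s1")), lengths, "RNA")
  list(dna = tpm_normalize(dn), rna = tpm_normalize(rn))
}

test_that("gene expression is RNA over DNA with zero-DNA entries missing", {
  dna <- metaexpress:::new_abundance_profile(
    matrix(c(1000, 0, 2000), 3, 1, dimnames = list(c("a", "b", "c"), "s1")),
    "TPM", "DNA")
  rna <- metaexpress:::new_abundance_profile(
    matrix(c(2000, 500, 0), 3, 1, dimnames = list(c("a", "b", "c"), "s1")),
    "TPM", "RNA")
  e <- gene_expression(dna, rna)
  expect_equal(unname(e$values[, 1]), c(2, NA, 0))
  expect_identical(e$normalization, "TPM-ratio")
  expect_identical(count_expressed_genes(e), 1L)
})

test_that("gene expression validates alignment and normalization", {
  p <- paired_profiles(c(10, 20), c(10, 20), c(a = 100, b = 100))
  bad_rna <- p$rna
  rownames(bad_rna$values) <- c("a", "zz")
  expect_error(gene_expression(p$dna, bad_rna), "zz")
  expect_error(gene_expression(p$rna, p$dna), "DNA-layer")
  mg_rna <- p$rna
  mg_rna$normalization <- "MG"
  expect_error(gene_expression(p$dna, mg_rna), "different normalizations")
})

test_that("noiseless fixtures return planted fold changes exactly (MG ratio)", {
  n_genes <- 30L
  fold <- rep(c(1, 2, 0.5), each = 10)
  spec <- fixture_spec(seed = 13, n_genomes = 2, genes_per_genome = n_genes,
                       n_samples = 3, mean_depth = 80,
                       expression_fold_changes = rep(fold, 2), rna_noise = FALSE)
  ft <- make_count_tables(spec)
  # marker genes are planted at fold 1, so the marker-median denominator is
  # identical in DNA and RNA and cancels: MG-ratio expression = fold, exactly
  e <- gene_expression(mg_normalize(ft$dna, ft$markers),
                       mg_normalize(ft$rna, ft$markers))
  defined <- !is.na(e$values)
  want <- matrix(ft$fold_changes, nrow(e$values), ncol(e$values))
  expect_matrix_equal(e$values[defined], want[defined], tol = 1e-12)
})

test_that("TPM-ratio expression recovers folds up to a per-sample constant", {
  # TPM renormalizes each layer to 1e6, so the compositional factor
  # sum(d/l)/sum(f*d/l) multiplies every gene's expression in a sample
  fold <- rep(c(1, 2, 0.5), each = 10)
  spec <- fixture_spec(seed = 13, n_genomes = 1, genes_per_genome = 30,
                       n_samples = 3, mean_depth = 80,
                       expression_fold_changes = fold, rna_noise = FALSE)
  ft <- make_count_tables(spec)
  e <- gene_expression(tpm_normalize(ft$dna), tpm_normalize(ft$rna))
  expressed <- rowSums(ft$dna$counts > 0) == ncol(ft$dna$counts)
  ratio <- e$values[expressed, ] / ft$fold_changes[expressed]
  for (s in seq_len(ncol(ratio)))
    expect_lt(diff(range(ratio[, s])), 1e-9)
})

test_that("single-genome joint DNA/RNA scaling leaves TPM-ratio expression unchanged", {
  spec <- fixture_spec(seed = 17, n_genomes = 1, genes_per_genome = 15,
                       n_samples = 2, mean_depth = 60, rna_noise = FALSE,
                       expression_fold_changes = runif(15, 0.5, 2))
  ft <- make_count_tables(spec)
  base <- gene_expression(tpm_normalize(ft$dna), tpm_normalize(ft$rna))$values
  for (k in c(0.25, 8)) {
    d2 <- ft$dna; d2$counts <- d2$counts * k
    r2 <- ft$rna; r2$counts <- r2$counts * k
    v <- gene_expression(tpm_normalize(d2), tpm_normalize(r2))$values
    expect_matrix_equal(v, base, tol = 1e-9)
  }
})

test_that("expression error shrinks with sequencing depth under Poisson noise", {
  mare <- vapply(c(10, 200), function(depth) {
    spec <- fixture_spec(seed = 19, n_genomes = 1, genes_per_genome = 500,
                         n_samples = 2, mean_depth = depth,
                         expression_fold_changes = rep(c(0.5, 1, 2), length.out = 500),
                         rna_noise = TRUE)
    ft <- make_count_tables(spec)
    est <- rowSums(ft$rna$counts) / pmax(rowSums(ft$dna$counts), 1)
    median(abs(est - ft$fold_changes) / ft$fold_changes)
  }, numeric(1))
  expect_lt(mare[2], mare[1])
})

test_that("MG-normalized expression matches a brute-force per-genome division", {
  spec <- fixture_spec(seed = 23, n_genomes = 3, genes_per_genome = 12,
                       n_samples = 3, mean_depth = 70)
  ft <- make_count_tables(spec)
  e <- gene_expression(tpm_normalize(ft$dna), tpm_normalize(ft$rna))
  em <- mg_normalized_expression(e, ft$markers)
  for (g in names(ft$markers$entries)) {
    markers <- ft$markers$entries[[g]]
    rows <- names(which(ft$markers$gene_to_genome == g))
    for (s in colnames(e$values)) {
      mexp <- e$values[markers, s]
      med <- if (all(is.na(mexp))) NA_real_ else median(mexp, na.rm = TRUE)
      if (!is.na(med) && med == 0) med <- NA_real_
      expect_equal(unname(em$values[rows, s]), unname(e$values[rows, s] / med))
    }
  }
})

test_that("uniform expression within a genome normalizes to 1 everywhere", {
  genes <- sprintf("g%02d", 1:12)
  vals <- matrix(3.7, 12, 2, dimnames = list(genes, c("s1", "s2")))
  e <- metaexpress:::new_expression_profile(vals, "TPM-ratio",
                                            c(dna = "d", rna = "r"))
  m <- marker_gene_map(list(G = setNames(genes[1:10], marker_cogs())),
                       setNames(rep("G", 12), genes))
  em <- mg_normalized_expression(e, m)
  expect_true(all(em$values == 1))
  # the marker whose expression sits at the genome median maps to exactly 1
  vals2 <- vals
  vals2[, 1] <- seq(0.5, 6, length.out = 12)
  e2 <- metaexpress:::new_expression_profile(vals2, "TPM-ratio",
                                             c(dna = "d", rna = "r"))
  em2 <- mg_normalized_expression(e2, m)
  med_gene <- median(vals2[genes[1:10], 1])
  expect_equal(max(abs(sort(em2$values[genes[1:10], 1]) -
                         sort(vals2[genes[1:10], 1] / med_gene))), 0)
})

test_that("expressed-gene counting follows the at-least-one-sample rule", {
  vals <- matrix(NA_real_, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  e <- metaexpress:::new_expression_profile(vals, "TPM-ratio", c(dna = "d", rna = "r"))
  expect_identical(count_expressed_genes(e), 0L)
  vals["a", 1] <- 1.5
  vals["b", ] <- 0
  e$values <- vals
  expect_identical(count_expressed_genes(e), 1L)
})

test_that("planted silent genes are excluded from the expressed count", {
  spec <- fixture_spec(seed = 29, n_genomes = 1, genes_per_genome = 40,
                       n_samples = 3, mean_depth = 60, rna_noise = FALSE)
  ft <- make_count_tables(spec)
  silent <- rownames(ft$rna$counts)[31:40]
  ft$rna$counts[silent, ] <- 0
  e <- gene_expression(tpm_normalize(ft$dna), tpm_normalize(ft$rna))
  n_dna_detected <- sum(rowSums(ft$dna$counts > 0) > 0)
  expect_identical(count_expressed_genes(e),
                   n_dna_detected - length(silent))
})
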