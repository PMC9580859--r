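# Quality filtering, scoring and per-cluster representative selection for
# metagenome-assembled genomes (MAGs) after external ANI clustering.

mag_required_cols <- c("mag_id", "completeness", "contamination", "n_contigs",
                       "longest_contig_bp", "n50_bp", "l50", "cluster_id")

validate_mag_records <- function(records, need_cluster = TRUE) {
  if (!is.data.frame(records)) stopf("MAG records must be a data.frame")
  need <- mag_required_cols
  if (!need_cluster) need <- setdiff(need, "cluster_id")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stopf("MAG records missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(records$mag_id))
    stopf("duplicate mag_id values in MAG records")
  with(records, {
    if (any(completeness < 0 | completeness > 100))
      stopf("completeness must be a percentage in [0, 100]")
    if (any(contamination < 0)) stopf("contamination must be >= 0")
    if (any(longest_contig_bp < n50_bp))
      stopf("longest_contig_bp must be >= n50_bp")
    if (any(l50 > n_contigs)) stopf("l50 cannot exceed n_contigs")
  })
  invisible(records)
}

#' Filter MAGs to high quality
#'
#' Keeps genomes with completeness strictly above `completeness_min` and
#' contamination strictly below `contamination_max`, preserving input
#' order. The default thresholds are completeness > 90% and
#' contamination < 5%; a stricter completeness > 95% screen is obtained by
#' setting `completeness_min = 95`.
#'
#' @param records Data frame of MAG records with columns `mag_id`,
#'   `completeness`, `contamination`, `n_contigs`, `longest_contig_bp`,
#'   `n50_bp`, `l50` and (for downstream selection) `cluster_id`.
#' @param completeness_min Completeness threshold (percent, exclusive).
#' @param contamination_max Contamination threshold (percent, exclusive).
#' @return The retained rows of `records` (possibly zero rows).
#' @export
filter_hq_mags <- function(records, completeness_min = 90, contamination_max = 5) {
  validate_mag_records(records, need_cluster = FALSE)
  keep <- records$completeness > completeness_min &
    records$contamination < contamination_max
  records[keep, , drop = FALSE]
}

#' Score MAG assembly and genome quality
#'
#' Computes, per genome,
#' \deqn{assembly = \log_{10}(longest/\#contigs) + \log_{10}(N50/L50)}
#' \deqn{genome = completeness - 2 \times contamination}
#' \deqn{final = 0.1 \times genome + assembly}
#' so that assembly contiguity dominates and completeness/contamination act
#' as a weighted tie-breaker between similarly contiguous genomes.
#'
#' @inheritParams filter_hq_mags
#' @return `records` with columns `assembly_score`, `genome_score` and
#'   `final_score` appended.
#' @export
#' @examples
#' rec <- data.frame(mag_id = "m1", completeness = 100, contamination = 0,
#'                   n_contigs = 1, longest_contig_bp = 1e6, n50_bp = 1e6,
#'                   l50 = 1, cluster_id = "c1")
#' score_mags(rec)$final_score  # 0.1 * 100 + 12 = 22
score_mags <- function(records) {
  validate_mag_records(records, need_cluster = FALSE)
  with(records, {
    if (any(n_contigs <= 0 | longest_contig_bp <= 0 | n50_bp <= 0 | l50 <= 0))
      stopf("assembly statistics must be strictly positive (log10 domain)")
  })
  records$assembly_score <- log10(records$longest_contig_bp / records$n_contigs) +
    log10(records$n50_bp / records$l50)
  records$genome_score <- records$completeness - 2 * records$contamination
  records$final_score <- 0.1 * records$genome_score + records$assembly_score
  records
}

#' Select one representative MAG per ANI cluster
#'
#' Within each `cluster_id`, picks the genome with the highest final score
#' (see [score_mags()]); ties go to the lexicographically smallest
#' `mag_id`, making dereplication deterministic.
#'
#' @inheritParams filter_hq_mags
#' @return Data frame with one row per cluster (`cluster_id`, `mag_id`,
#'   `final_score`), sorted by `cluster_id`. Empty input yields zero rows.
#' @export
select_representatives <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(cluster_id = character(0), mag_id = character(0),
                      final_score = numeric(0)))
  validate_mag_records(records, need_cluster = TRUE)
  scored <- score_mags(records)
  picks <- lapply(split(scored, scored$cluster_id), function(cl) {
    best <- cl[cl$final_score == max(cl$final_score), , drop = FALSE]
    best[order(best$mag_id), , drop = FALSE][1L, c("cluster_id", "mag_id", "final_score")]
  })
  out <- do.call(rbind, picks[sort(names(picks))])
  rownames(out) <- NULL
  out
}
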