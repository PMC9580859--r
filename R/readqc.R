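# Read quality-control estimators applied before external trimming:
# the minimum-read-length cutoff and the adapter-index heuristic.

read_fastq_lines <- function(fastq) {
  if (!file.exists(fastq)) stopf("FASTQ file not found: %s", fastq)
  con <- gzfile(fastq, "rt")   # gzfile transparently reads plain text too
  on.exit(close(con))
  readLines(con)
}

#' Tabulate the read-length distribution of a FASTQ file
#'
#' Scans every record of a (optionally gzipped) FASTQ file and counts reads
#' per length, the input to [estimate_min_length_cutoff()].
#'
#' @param fastq Path to a FASTQ or FASTQ.gz file.
#' @return An object of class `length_histogram`: a named integer vector
#'   mapping read length (bp) to read count, in increasing length order.
#'   An empty file yields an empty histogram.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' make_fastq(fixture_spec(seed = 1, n_reads = 50,
#'                         length_distribution = c("75" = 0.4, "100" = 0.6)), fq)
#' length_histogram(fq)
length_histogram <- function(fastq) {
  lines <- read_fastq_lines(fastq)
  n <- length(lines)
  if (n %% 4L != 0L)
    stopf("malformed FASTQ: %d lines is not a multiple of 4; record %d is truncated (%s)",
          n, n %/% 4L + 1L, fastq)
  if (n == 0L)
    return(structure(stats::setNames(integer(0), character(0)),
                     class = "length_histogram"))
  headers <- lines[seq(1L, n, by = 4L)]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad))
    stopf("malformed FASTQ: record %d header does not start with '@'", bad[1L])
  tab <- table(nchar(lines[seq(2L, n, by = 4L)], type = "bytes"))
  structure(stats::setNames(as.integer(tab), names(tab)),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> %d reads over %d distinct lengths\n",
              sum(x), length(x)))
  if (length(x))
    print(stats::setNames(as.integer(x), paste0(names(x), "bp")))
  invisible(x)
}

as_length_histogram <- function(hist) {
  if (inherits(hist, "length_histogram")) return(hist)
  if (is.null(names(hist))) stopf("histogram must map read length to count")
  structure(stats::setNames(as.integer(hist), names(hist)),
            class = "length_histogram")
}

#' Estimate the minimum read-length cutoff retaining a given read fraction
#'
#' Returns the largest length `L` such that the fraction of reads of length
#' `>= L` is at least `retain_fraction` — i.e. the most stringent MINLEN
#' value an external trimmer can apply while keeping the predefined
#' percentage of reads (default 95%). Cutoffs below `floor_bp` are raised
#' to `floor_bp` (default 50 bp) so very short read sets still get a
#' usable minimum length.
#'
#' Retained fraction only changes at observed read lengths, so candidate
#' cutoffs are the observed lengths; the minimum observed length always
#' retains 100% of reads, so a solution exists for any non-empty histogram.
#'
#' @param hist A `length_histogram` (or named count vector).
#' @param retain_fraction Fraction of reads to retain, in (0, 1].
#' @param floor_bp Lower bound on the returned cutoff, in bp.
#' @return Integer cutoff in bp.
#' @export
#' @examples
#' estimate_min_length_cutoff(c("40" = 5, "100" = 95))  # -> 100
#' estimate_min_length_cutoff(c("30" = 100))            # -> 50 (floor)
estimate_min_length_cutoff <- function(hist, retain_fraction = 0.95, floor_bp = 50L) {
  hist <- as_length_histogram(hist)
  if (!length(hist) || sum(hist) < 1L)
    stopf("cannot estimate a length cutoff from an empty histogram")
  assert_scalar_number(retain_fraction, "retain_fraction", min = 0, allow_zero = FALSE)
  if (retain_fraction > 1) stopf("'retain_fraction' must be in (0, 1]")
  assert_scalar_number(floor_bp, "floor_bp", min = 1)
  lens <- as.integer(names(hist))
  counts <- as.numeric(hist)
  ord <- order(lens, decreasing = TRUE)
  # fraction of reads with length >= lens[ord] via cumulative sum from the top
  frac_at_least <- cumsum(counts[ord]) / sum(counts)
  ok <- frac_at_least >= retain_fraction
  cutoff <- max(lens[ord][ok])
  max(cutoff, as.integer(floor_bp))
}

parse_header_index <- function(headers) {
  # index = final colon-separated token of the comment (after first whitespace)
  comment <- sub("^\\S+\\s*", "", headers)
  idx <- sub(".*:", "", comment)
  idx[!nzchar(comment) | !nzchar(idx)] <- NA_character_
  idx
}

#' Detect the sequencing adapter index from FASTQ headers
#'
#' Reads the first `n_headers` record headers (default 10,000) and reports
#' the most abundant index — the final colon-separated field of the header
#' comment under the Illumina CASAVA >= 1.8 convention, e.g. the `ACGTACGT`
#' in `@M01:1:FC:1:1:1:1 1:N:0:ACGTACGT`. Ties are broken by the
#' lexicographically smallest index so the call is deterministic.
#'
#' @param fastq Path to a FASTQ or FASTQ.gz file.
#' @param n_headers Maximum number of headers to scan.
#' @return An object of class `index_call` with fields `index_sequence`,
#'   `support` (headers carrying it) and `n_headers_scanned`.
#' @export
detect_adapter_index <- function(fastq, n_headers = 10000L) {
  assert_scalar_number(n_headers, "n_headers", min = 1)
  lines <- read_fastq_lines(fastq)
  n <- length(lines)
  if (n %% 4L != 0L)
    stopf("malformed FASTQ: %d lines is not a multiple of 4; record %d is truncated (%s)",
          n, n %/% 4L + 1L, fastq)
  headers <- lines[seq(1L, n, by = 4L)]
  headers <- utils::head(headers, n_headers)
  if (!length(headers)) stopf("no records to scan in %s", fastq)
  idx <- parse_header_index(sub("^@", "", headers))
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stopf("no parseable index field in the first %d header(s) of %s",
          length(headers), fastq)
  tab <- table(idx)
  best <- sort(names(tab)[tab == max(tab)])[1L]
  structure(list(index_sequence = best,
                 support = as.integer(tab[[best]]),
                 n_headers_scanned = length(headers)),
            class = "index_call")
}

#' @export
print.index_call <- function(x, ...) {
  cat(sprintf("<index_call> %s (%d of %d headers)\n",
              x$index_sequence, x$support, x$n_headers_scanned))
  invisible(x)
}
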