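# Peak set helpers: canonical ids, parsing, BED3 I/O.
# Canonical peak id is "chrom:start-end" in 0-based half-open (BED)
# coordinates, the 10x cellranger-atac dialect; "chrom_start_end" is
# accepted on input.

#' Canonical peak ids for a set of intervals
#'
#' @param peaks `GRanges`.
#' @return Character vector `"chrom:start-end"` (BED coordinates).
#' @export
peak_id <- function(peaks) {
  stopifnot(is(peaks, "GRanges"))
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(peaks)),
          GenomicRanges::start(peaks) - 1L, GenomicRanges::end(peaks))
}

#' Parse peak id strings into intervals
#'
#' Accepts both the colon-dash (`chr1:100-600`) and underscore
#' (`chr1_100_600`) dialects; coordinates are BED-style 0-based half-open.
#'
#' @param ids Character vector of peak ids.
#' @return `GRanges` named by the canonical id.
#' @export
parse_peak_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+?)[:_](\\d+)[-_](\\d+)$", ids))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) stop("unparseable peak id at position ", bad[1],
                        ": '", ids[bad[1]], "'")
  chrom <- vapply(m, `[`, character(1), 2L)
  s0 <- as.integer(vapply(m, `[`, character(1), 3L))
  e0 <- as.integer(vapply(m, `[`, character(1), 4L))
  if (any(e0 <= s0)) stop("peak id with end <= start: ",
                          ids[which(e0 <= s0)[1]])
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0))
  names(gr) <- peak_id(gr)
  gr
}

#' Read peaks from a BED3 file
#'
#' @param path BED3 file (chrom, start, end; 0-based half-open).
#' @return `GRanges` named by canonical peak id, in file order.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  s0 <- suppressWarnings(as.integer(df[[2]]))
  e0 <- suppressWarnings(as.integer(df[[3]]))
  bad <- which(is.na(s0) | is.na(e0) | e0 <= s0 | s0 < 0L)
  if (length(bad)) stop("malformed BED coordinates at line ", bad[1])
  gr <- GenomicRanges::GRanges(as.character(df[[1]]),
                               IRanges::IRanges(s0 + 1L, e0))
  names(gr) <- peak_id(gr)
  gr
}

# 0-based center of an interval (may be half-integral)
.peak_center <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}

# 0-based TSS position of a gene: genomic start for '+', last base for '-'
.tss_position <- function(genes, strand_aware = TRUE) {
  s0 <- GenomicRanges::start(genes) - 1
  if (!strand_aware) return(s0)
  neg <- as.character(GenomicRanges::strand(genes)) == "-"
  s0[neg] <- GenomicRanges::end(genes)[neg] - 1
  s0
}
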