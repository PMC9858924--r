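# Functional labeling of peaks against the genomic model.
#
# Each peak gets exactly one of four labels, in strict precedence:
#   prom  - a promoter-labeled region is contained in the peak (literal
#           mode) or intersects it (relaxed mode), OR the peak covers some
#           gene's TSS region;
#   enhD  - same test against distal-enhancer regions, and no prom;
#   exon  - the peak is contained in (literal) / intersects (relaxed) an
#           exon of some gene;
#   empty - none of the above.
#
# The TSS clause always requires full coverage of the (tiny) TSS region:
# "peak inside a 2-base TSS" is unsatisfiable, so coverage is the only
# sensible containment reading there.

PEAK_LABELS <- c("prom", "enhD", "exon", "empty")

#' Pairwise interval overlap test
#'
#' `literal_containment` is true iff `a` lies within `b` on the same
#' chromosome (`start(a) >= start(b)` and `end(a) <= end(b)`);
#' `any_overlap` is true iff the intersection is at least 1 bp.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @param mode `"literal_containment"` or `"any_overlap"`.
#' @return Logical vector.
#' @export
overlaps <- function(a, b, mode = c("literal_containment", "any_overlap")) {
  mode <- match.arg(mode)
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  if (mode == "literal_containment") {
    same &
      GenomicRanges::start(a) >= GenomicRanges::start(b) &
      GenomicRanges::end(a) <= GenomicRanges::end(b)
  } else {
    same &
      GenomicRanges::start(a) <= GenomicRanges::end(b) &
      GenomicRanges::start(b) <= GenomicRanges::end(a)
  }
}

#' Label peaks against a genome annotation
#'
#' Assigns each peak one of `prom`, `enhD`, `exon`, `empty` with strict
#' precedence (see the rules above). Peaks covering a gene's TSS are
#' recorded per peak in `tss_hits`; those drive the gene association of
#' promoter peaks in [build_gene_promoter_map()].
#'
#' @param peaks `GRanges` of peaks (names become peak ids; canonical ids
#'   are derived when names are absent).
#' @param annotation A [gene_annotation()].
#' @param mode Overlap semantics for the region and exon clauses:
#'   `"literal_containment"` (default; region inside peak, peak inside
#'   exon) or `"any_overlap"`.
#' @param tss_width,strand_aware TSS model, see [derive_tss()].
#' @return An object of class `labeled_peaks`: list with `peaks`
#'   (`GRanges`), `labels` (factor over the four labels), and `tss_hits`
#'   (list of gene-id character vectors, one per peak).
#' @export
label_peaks <- function(peaks, annotation,
                        mode = c("literal_containment", "any_overlap"),
                        tss_width = 2L, strand_aware = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(peaks, "GRanges"), inherits(annotation, "gene_annotation"))
  if (is.null(names(peaks))) names(peaks) <- peak_id(peaks)
  if (anyDuplicated(names(peaks))) stop("duplicated peak ids")
  n <- length(peaks)
  type <- if (mode == "literal_containment") "within" else "any"
  labels <- rep("empty", n)
  tss_hits <- rep(list(character(0)), n)

  genes <- annotation$genes
  regions <- annotation$regions
  if (length(genes) == 0L && length(regions) == 0L) {
    warning("empty annotation: all peaks labeled 'empty'")
  }
  # TSS coverage: always full containment of the TSS region in the peak
  if (length(genes)) {
    tss <- derive_tss(genes, tss_width = tss_width, strand_aware = strand_aware)
    ht <- GenomicRanges::findOverlaps(tss, peaks, type = "within",
                                      ignore.strand = TRUE)
    if (length(ht)) {
      sp <- split(genes$gene_id[S4Vectors::queryHits(ht)],
                  S4Vectors::subjectHits(ht))
      tss_hits[as.integer(names(sp))] <- lapply(sp, as.character)
    }
  }
  covers_tss <- lengths(tss_hits) > 0L
  has_region <- function(lab) {
    r <- regions[regions$label == lab]
    out <- logical(n)
    if (length(r)) {
      h <- GenomicRanges::findOverlaps(r, peaks, type = type,
                                       ignore.strand = TRUE)
      out[unique(S4Vectors::subjectHits(h))] <- TRUE
    }
    out
  }
  in_prom_region <- has_region("promoter")
  in_enh_region <- has_region("enhancer_distal")
  in_exon <- logical(n)
  if (length(genes)) {
    ex <- unlist(annotation$exons, use.names = FALSE)
    if (length(ex)) {
      he <- GenomicRanges::findOverlaps(peaks, ex, type = type,
                                        ignore.strand = TRUE)
      in_exon[unique(S4Vectors::queryHits(he))] <- TRUE
    }
  }
  labels[in_exon] <- "exon"
  labels[in_enh_region] <- "enhD"
  labels[in_prom_region | covers_tss] <- "prom"
  structure(list(peaks = peaks,
                 labels = factor(labels, levels = PEAK_LABELS),
                 tss_hits = tss_hits),
            class = "labeled_peaks")
}

#' @export
print.labeled_peaks <- function(x, ...) {
  cat("labeled_peaks:", length(x$peaks), "peaks\n")
  print(label_summary(x))
  invisible(x)
}

#' Per-label peak counts
#'
#' @param lps A `labeled_peaks` object.
#' @return Named integer vector with counts for `prom`, `enhD`, `exon`,
#'   `empty` and `total`; counts sum to the number of peaks.
#' @export
label_summary <- function(lps) {
  stopifnot(inherits(lps, "labeled_peaks"))
  counts <- table(lps$labels)
  out <- c(as.integer(counts), length(lps$peaks))
  names(out) <- c(names(counts), "total")
  out
}

#' Write labeled peaks as BED
#'
#' BED6+2: chrom, start, end, peak id, score 0, strand '.', label, and a
#' comma-separated list of gene ids whose TSS the peak covers.
#'
#' @param lps A `labeled_peaks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_peaks <- function(lps, path) {
  stopifnot(inherits(lps, "labeled_peaks"))
  p <- lps$peaks
  lines <- paste(as.character(GenomicRanges::seqnames(p)),
                 GenomicRanges::start(p) - 1L, GenomicRanges::end(p),
                 names(p), 0L, ".",
                 as.character(lps$labels),
                 vapply(lps$tss_hits, function(g)
                   if (length(g)) paste(g, collapse = ",") else ".",
                   character(1)),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
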