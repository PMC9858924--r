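# Genomic model: protein-coding genes (body + merged exons + TSS) and
# labeled regulatory regions (promoter / distal enhancer tracks).
#
# Internally everything lives in GenomicRanges (1-based, closed). All disk
# formats in the BED family (and the canonical peak id "chr:start-end") are
# 0-based half-open and are converted at the boundary.

#' Assemble a genome annotation
#'
#' Container binding the gene model (gene bodies with strand and biotype,
#' merged exon sets) to a labeled regulatory-region track. This is the
#' annotation object consumed by [label_peaks()] and [gagam()].
#'
#' @param genes `GRanges` of gene bodies with metadata columns `gene_id`
#'   (unique), `gene_name` and `biotype`, and strand `+` or `-`.
#' @param exons `GRangesList` of exon intervals, one element per gene, named
#'   by `gene_id`. Exons of all transcripts of a gene must already be merged
#'   (see [load_gene_annotation()]); each exon must fall inside the gene body.
#' @param regions `GRanges` of regulatory regions with a metadata column
#'   `label` in `promoter`, `enhancer_distal`, `other`, or `NULL` for none.
#' @return An object of class `gene_annotation` with elements `genes`,
#'   `exons`, `regions`.
#' @seealso [load_gene_annotation()], [load_regulatory_tracks()]
#' @export
gene_annotation <- function(genes, exons, regions = NULL) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"))
  ids <- genes$gene_id
  if (is.null(ids) || anyNA(ids)) stop("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(ids)) stop("gene_id values must be unique")
  if (is.null(genes$gene_name)) genes$gene_name <- ids
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (length(ids) && !all(ids %in% names(exons)))
    stop("every gene needs a named exon set in 'exons'")
  if (length(ids)) exons <- exons[ids]
  ok <- vapply(seq_along(ids), function(i) {
    e <- exons[[i]]
    length(e) > 0L &&
      all(as.character(GenomicRanges::seqnames(e)) ==
            as.character(GenomicRanges::seqnames(genes[i]))) &&
      all(GenomicRanges::start(e) >= GenomicRanges::start(genes[i])) &&
      all(GenomicRanges::end(e) <= GenomicRanges::end(genes[i]))
  }, logical(1))
  if (!all(ok)) stop("exons must be non-empty and contained in their gene body: ",
                     paste(ids[!ok], collapse = ", "))
  if (is.null(regions)) {
    regions <- GenomicRanges::GRanges(label = character(0))
  }
  if (is.null(regions$label)) stop("regions must carry a 'label' metadata column")
  regions$label <- as.character(regions$label)
  bad <- setdiff(unique(regions$label), c("promoter", "enhancer_distal", "other"))
  if (length(bad)) stop("unknown region labels: ", paste(bad, collapse = ", "))
  structure(list(genes = genes, exons = exons, regions = regions),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  tab <- table(factor(x$regions$label, c("promoter", "enhancer_distal", "other")))
  cat(sprintf("gene_annotation: %d genes (%d merged exons) on %d sequence(s)\n",
              length(x$genes), sum(lengths(x$exons)),
              length(unique(as.character(GenomicRanges::seqnames(x$genes))))))
  cat(sprintf("regulatory regions: %d promoter, %d enhancer_distal, %d other\n",
              tab[["promoter"]], tab[["enhancer_distal"]], tab[["other"]]))
  invisible(x)
}

#' Load a gene annotation from GTF or BED12
#'
#' Reads a gene model and restricts it to the requested biotypes (by default
#' protein-coding genes only: pseudogenes, miRNA, lncRNA and similar are
#' dropped because they do not code for the mRNA products measured in
#' transcriptomic experiments). Exons of all transcripts of a gene are merged
#' into a single flat, non-overlapping exon list; one promoter per gene is
#' assumed throughout (alternative promoters are not modeled).
#'
#' @param path File path of the annotation.
#' @param format `"gtf"` or `"bed12"`. GTF needs `exon` features carrying a
#'   `gene_id` and a `gene_biotype`/`gene_type` attribute. BED12 carries no
#'   biotype; records are taken at face value as protein-coding.
#' @param biotype_whitelist Character vector of biotypes to keep.
#' @return A list with `genes` (`GRanges`) and `exons` (`GRangesList`).
#'   Genes with zero exon records are skipped with a warning.
#' @export
load_gene_annotation <- function(path, format = c("gtf", "bed12"),
                                 biotype_whitelist = "protein_coding") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gtf") .load_genes_gtf(path, biotype_whitelist)
  else .load_genes_bed12(path)
}

.load_genes_gtf <- function(path, biotype_whitelist) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  btcol <- intersect(c("gene_biotype", "gene_type", "biotype"), names(mc))
  if (!length(btcol)) stop("GTF carries no gene_biotype/gene_type attribute")
  bt <- as.character(mc[[btcol[1]]])
  gid <- as.character(gr$gene_id)
  if (anyNA(gid)) stop("GTF records without gene_id")
  ex <- gr[gr$type == "exon"]
  gn <- gr[gr$type == "gene"]
  if (length(gn)) {
    genes <- GenomicRanges::granges(gn)
    genes$gene_id <- as.character(gn$gene_id)
    nm <- if (!is.null(gn$gene_name)) as.character(gn$gene_name) else genes$gene_id
    genes$gene_name <- ifelse(is.na(nm), genes$gene_id, nm)
    genes$biotype <- bt[as.vector(gr$type == "gene")]
  } else { # no gene feature rows: derive bodies from exon extent
    sp <- S4Vectors::split(GenomicRanges::granges(ex), as.character(ex$gene_id))
    genes <- unlist(range(sp))
    genes$gene_id <- names(genes)
    genes$gene_name <- genes$gene_id
    first_bt <- tapply(bt[as.vector(gr$type == "exon")],
                       as.character(ex$gene_id), `[`, 1L)
    genes$biotype <- as.character(first_bt[genes$gene_id])
    names(genes) <- NULL
    # body strand: from the exon entries
    st <- tapply(as.character(GenomicRanges::strand(ex)),
                 as.character(ex$gene_id), `[`, 1L)
    GenomicRanges::strand(genes) <- as.character(st[genes$gene_id])
  }
  genes <- genes[genes$biotype %in% biotype_whitelist]
  has_exon <- genes$gene_id %in% unique(as.character(ex$gene_id))
  if (any(!has_exon)) {
    warning(sum(!has_exon), " gene(s) without exon records skipped")
    genes <- genes[has_exon]
  }
  if (!length(genes)) stop("no gene left after biotype filtering")
  ex <- ex[as.character(ex$gene_id) %in% genes$gene_id]
  exons <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(ex),
                     factor(as.character(ex$gene_id), levels = genes$gene_id)))
  list(genes = genes, exons = exons)
}

.load_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("BED12 input lacks block (exon) columns")
  ids <- as.character(gr$name)
  if (anyNA(ids) || anyDuplicated(ids)) stop("BED12 names must be unique gene ids")
  genes <- GenomicRanges::granges(gr)
  genes$gene_id <- ids
  genes$gene_name <- ids
  genes$biotype <- "protein_coding"
  # blocks are 1-based ranges relative to the record start
  exl <- lapply(seq_along(gr), function(i) {
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(gr[i])),
      IRanges::shift(gr$blocks[[i]], GenomicRanges::start(gr[i]) - 1L),
      strand = as.character(GenomicRanges::strand(gr[i])))
  })
  exons <- GenomicRanges::reduce(GenomicRanges::GRangesList(exl))
  names(exons) <- ids
  list(genes = genes, exons = exons)
}

#' Transcription start sites
#'
#' The TSS is modeled as a small fixed-width region (default 2 bases, the
#' first two bases of the first exon) at the transcription-directional start
#' of the gene body: the left edge for `+` genes, the right edge for `-`
#' genes. With `strand_aware = FALSE` the left edge is used for every gene,
#' reproducing a strand-blind `(start, start+1)` reading.
#'
#' @param genes `GRanges` of gene bodies or a `gene_annotation`.
#' @param tss_width Width of the TSS region in bp (default 2).
#' @param strand_aware Anchor at the 5' end of the transcript (default) or
#'   always at the genomic start.
#' @return `GRanges`, one TSS region per gene, metadata preserved.
#' @export
derive_tss <- function(genes, tss_width = 2L, strand_aware = TRUE) {
  g <- if (inherits(genes, "gene_annotation")) genes$genes else genes
  stopifnot(is(g, "GRanges"), tss_width >= 1L)
  GenomicRanges::resize(g, width = as.integer(tss_width), fix = "start",
                        ignore.strand = !strand_aware)
}

#' Promoter-window (enlarged gene body) per gene
#'
#' The gene body extended upstream of the TSS by `upstream_bp` (default
#' 500 bp, an estimate of the mean peak length). Used to associate
#' promoter-labeled peaks with genes. Strand-aware by default: `+` genes
#' extend to lower coordinates, `-` genes to higher ones; coordinates are
#' clipped at the chromosome start.
#'
#' @inheritParams derive_tss
#' @param upstream_bp Non-negative extension upstream of the TSS, in bp.
#' @return `GRanges` of enlarged gene bodies, metadata preserved.
#' @export
derive_promoter_window <- function(genes, upstream_bp = 500L, strand_aware = TRUE) {
  g <- if (inherits(genes, "gene_annotation")) genes$genes else genes
  stopifnot(is(g, "GRanges"), upstream_bp >= 0)
  out <- GenomicRanges::resize(g, width = GenomicRanges::width(g) + as.integer(upstream_bp),
                               fix = "end", ignore.strand = !strand_aware)
  # clip at position 1 without touching the end
  too_low <- GenomicRanges::start(out) < 1L
  if (any(too_low)) {
    GenomicRanges::ranges(out)[too_low] <- IRanges::IRanges(
      1L, GenomicRanges::end(out)[too_low])
  }
  out
}

#' Default regulatory-track label map
#'
#' Maps ENCODE cCRE track labels to the internal closed label set. Both the
#' UCSC display labels (`prom`, `enhD`) and the registry labels (`PLS`,
#' `dELS`) are covered; anything else (CTCF-only, proximal enhancers, ...)
#' becomes `"other"` and never produces a peak label.
#'
#' @return Named character vector, track label -> internal label.
#' @export
default_label_map <- function() {
  c(prom = "promoter", PLS = "promoter",
    enhD = "enhancer_distal", dELS = "enhancer_distal")
}

#' Load a regulatory-region track from labeled BED
#'
#' Reads a BED-like file whose `label_column` carries a functional label
#' (ENCODE cCRE style). Labels are mapped through `label_map`; unmapped
#' labels become `"other"`. Chromosome names pass through verbatim.
#'
#' @param path BED file path (0-based half-open coordinates).
#' @param label_column 1-based column index of the label.
#' @param label_map Named character vector mapping track labels to
#'   `promoter` / `enhancer_distal` (see [default_label_map()]).
#' @return `GRanges` with a `label` metadata column.
#' @export
load_regulatory_tracks <- function(path, label_column = 10L,
                                   label_map = default_label_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(nzchar(lines)))
    return(GenomicRanges::GRanges(label = character(0)))
  df <- tryCatch(utils::read.table(path, header = FALSE, sep = "",
                                   stringsAsFactors = FALSE,
                                   comment.char = "#"),
                 error = function(e) stop("cannot parse BED file: ",
                                          conditionMessage(e)))
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  if (label_column > ncol(df)) stop("label_column ", label_column,
                                    " exceeds the ", ncol(df), " columns present")
  s0 <- suppressWarnings(as.integer(df[[2]]))
  e0 <- suppressWarnings(as.integer(df[[3]]))
  bad <- which(is.na(s0) | is.na(e0) | e0 <= s0 | s0 < 0L)
  if (length(bad)) stop("malformed coordinates at line ", bad[1])
  raw <- as.character(df[[label_column]])
  lab <- unname(label_map[raw])
  lab[is.na(lab)] <- "other"
  gr <- GenomicRanges::GRanges(as.character(df[[1]]),
                               IRanges::IRanges(s0 + 1L, e0))
  gr$label <- lab
  gr
}

#' Write the gene model as BED12
#'
#' Serializes genes and their merged exon structure as BED12 (one record per
#' gene, exons as blocks) for inspection or round-tripping through
#' [load_gene_annotation()].
#'
#' @param annotation A `gene_annotation` or a list with `genes` and `exons`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_bed12 <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons[genes$gene_id]
  lines <- vapply(seq_along(genes), function(i) {
    g <- genes[i]
    e <- sort(exons[[i]])
    s0 <- GenomicRanges::start(g) - 1L
    sizes <- GenomicRanges::width(e)
    starts <- GenomicRanges::start(e) - 1L - s0
    paste(as.character(GenomicRanges::seqnames(g)), s0, GenomicRanges::end(g),
          g$gene_id, 0L, as.character(GenomicRanges::strand(g)),
          s0, GenomicRanges::end(g), "0",
          length(e),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
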